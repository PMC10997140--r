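#' Bundle specification for the synthetic phantom
#'
#' A tract bundle is a tube of streamlines around a parametric centreline.
#' `roi_stations` give the arc-length fractions at which the bundle's
#' waypoint ROI(s) sit (the corticospinal-tract-style two-ROI topology uses
#' two stations; every other tract one). A `csv_fraction` of the bundle's
#' streamlines is rerouted after its last ROI station to terminate within
#' the seed-selection distance of the CSv blob, emulating tract fibres that
#' turn towards the seed region.
#'
#' @param name tract label: one of `SLF_I, SLF_II, SLF_III, CINGULUM,
#'   CALLOSAL, AF, CST, OTHER`
#' @param centreline m x 3 matrix of world points (mm) tracing the bundle
#' @param radius tube radius in mm (> 0)
#' @param n_streamlines streamlines to realise (>= 0)
#' @param roi_stations arc-length fractions in (0, 1), one per waypoint ROI
#' @param csv_fraction fraction of streamlines rerouted to terminate near
#'   the CSv blob
#' @param exit_fraction arc-length fraction at which rerouted streamlines
#'   leave the tube (default: just past the last ROI station)
#' @export
bundle_spec <- function(name, centreline, radius = 3, n_streamlines = 100,
                        roi_stations = 0.5, csv_fraction = 0.3,
                        exit_fraction = NULL) {
  valid <- c("SLF_I", "SLF_II", "SLF_III", "CINGULUM", "CALLOSAL", "AF",
             "CST", "OTHER")
  if (!name %in% valid)
    stop("bundle name must be one of: ", paste(valid, collapse = ", "), call. = FALSE)
  centreline <- as_points(centreline)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (n_streamlines < 0) stop("n_streamlines must be >= 0", call. = FALSE)
  stopifnot(all(roi_stations > 0 & roi_stations < 1),
            csv_fraction >= 0, csv_fraction <= 1)
  if (is.null(exit_fraction))
    exit_fraction <- min(max(roi_stations) + 0.15, 0.9)
  structure(list(name = name, centreline = centreline, radius = radius,
                 n_streamlines = as.integer(n_streamlines),
                 roi_stations = sort(roi_stations),
                 csv_fraction = csv_fraction, exit_fraction = exit_fraction),
            class = "bundle_spec")
}

#' Default seven-bundle layout
#'
#' Seven geometrically separated bundles in the left half of the grid (the
#' callosal arc crossing the mid-sagittal plane), coarsely mimicking the
#' anatomy: an anterior-posterior cingulum adjacent to the CSv blob, three
#' stacked anterior-posterior SLF branches, a left-right callosal arc
#' crossing x = 0, an inferior-superior arcuate stand-in, and an
#' inferior-superior corticospinal bundle with the two-ROI topology.
#'
#' @param n_streamlines streamlines per bundle
#' @param radius tube radius (mm)
#' @param csv_fraction rerouted fraction per bundle
#' @return list of [bundle_spec()]
#' @export
default_bundles <- function(n_streamlines = 100, radius = 3, csv_fraction = 0.3) {
  line <- function(a, b) rbind(a, b)
  list(
    bundle_spec("SLF_I",    line(c(-22, -30, 26), c(-22, 30, 26)),
                radius, n_streamlines, 0.5, csv_fraction),
    bundle_spec("SLF_II",   line(c(-32, -30, 10), c(-32, 30, 10)),
                radius, n_streamlines, 0.5, csv_fraction),
    bundle_spec("SLF_III",  line(c(-32, -30, -14), c(-32, 30, -14)),
                radius, n_streamlines, 0.5, csv_fraction),
    bundle_spec("CINGULUM", line(c(-8, -30, 8), c(-8, 30, 8)),
                radius, n_streamlines, 0.5, csv_fraction),
    bundle_spec("CALLOSAL", line(c(30, 16, 18), c(-30, 16, 18)),
                radius, n_streamlines, 0.5, csv_fraction),
    bundle_spec("AF",       line(c(-30, -24, -26), c(-30, -24, 22)),
                radius, n_streamlines, 13 / 24, csv_fraction),
    bundle_spec("CST",      line(c(-14, -10, -30), c(-14, -10, 26)),
                radius, n_streamlines, c(3 / 28, 12 / 28), csv_fraction)
  )
}

#' Phantom specification
#'
#' Defines the ground-truth scene: grid geometry, bundles, CSv seed-blob
#' centres per hemisphere, signal-model constants and the noise level. The
#' grid is centred on the world origin so left/right correspond to negative/
#' positive world x.
#'
#' @param grid_shape voxel triple
#' @param voxel_size isotropic voxel size (mm)
#' @param bundles list of [bundle_spec()]
#' @param csv_centres named list (`left`, `right`) of world points (mm)
#' @param snr signal-to-noise ratio (`Inf` = noiseless)
#' @param seed integer seed controlling every stochastic element
#' @param csv_size CSv blob edge length in voxels (default 3, i.e. 3x3x3)
#' @param f_iso_wm free-water volume fraction inside bundle voxels
#' @param d_ax axial (stick) diffusivity, mm^2/s
#' @param d_iso free-water diffusivity, mm^2/s
#' @param S0 baseline (b = 0) signal
#' @param noise_model `"rician"` (magnitude MR) or `"gaussian"`
#' @param csv_capture_mm rerouted endpoints are sampled within this radius
#'   of the CSv blob's central voxel centre; must stay below the selection
#'   distance so rerouted streamlines are selectable by construction
#' @param csv_target hemisphere whose CSv blob receives rerouted endpoints
#' @export
phantom_spec <- function(grid_shape = c(41, 41, 41), voxel_size = 2,
                         bundles = default_bundles(),
                         csv_centres = list(left = c(-8, -10, 16),
                                            right = c(8, -10, 16)),
                         snr = Inf, seed = 1, csv_size = 3, f_iso_wm = 0.2,
                         d_ax = 1e-3, d_iso = 3e-3, S0 = 100,
                         noise_model = c("rician", "gaussian"),
                         csv_capture_mm = 2.5, csv_target = "left") {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0,
            snr > 0, f_iso_wm >= 0, f_iso_wm < 1, d_ax > 0, d_iso > 0,
            S0 > 0, csv_size >= 1, csv_capture_mm > 0,
            csv_target %in% names(csv_centres))
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size = voxel_size, bundles = bundles,
                         csv_centres = csv_centres, snr = snr,
                         seed = as.integer(seed), csv_size = as.integer(csv_size),
                         f_iso_wm = f_iso_wm, d_ax = d_ax, d_iso = d_iso,
                         S0 = S0, noise_model = noise_model,
                         csv_capture_mm = csv_capture_mm,
                         csv_target = csv_target),
                    class = "phantom_spec")
  grid <- phantom_grid(spec)
  half <- (spec$grid_shape - 1) / 2 * voxel_size
  inside <- function(p) all(abs(p) <= half + 1e-9)
  for (b in bundles)
    if (!all(apply(b$centreline, 1, inside)))
      stop("bundle '", b$name, "' centreline lies outside the grid", call. = FALSE)
  for (p in csv_centres)
    if (!inside(p)) stop("csv centre outside the grid", call. = FALSE)
  spec
}

phantom_grid <- function(spec) {
  aff <- diag(c(rep(spec$voxel_size, 3), 1))
  aff[1:3, 4] <- -(spec$grid_shape - 1) / 2 * spec$voxel_size
  volume_grid(array(0, dim = spec$grid_shape), aff)
}

## axis-aligned waypoint ROI box for one station of a bundle
roi_box_mask <- function(spec, grid, bundle, station) {
  cl <- densify_centreline(bundle$centreline, 1)
  s <- cumsum(c(0, sqrt(rowSums(diff(cl)^2))))
  at <- station * s[length(s)]
  idx <- which.min(abs(s - at))
  centre <- cl[idx, ]
  tangent <- cl[min(idx + 1, nrow(cl)), ] - cl[max(idx - 1, 1), ]
  along <- which.max(abs(tangent))
  half <- rep(bundle$radius + 2, 3)
  half[along] <- 3
  box_mask(grid, centre, half)
}

box_mask <- function(grid, centre, half) {
  shp <- grid_shape(grid)
  ctr <- voxel_to_world(grid, as.matrix(expand.grid(i = 0:(shp[1] - 1),
                                                    j = 0:(shp[2] - 1),
                                                    k = 0:(shp[3] - 1))))
  keep <- abs(ctr[, 1] - centre[1]) <= half[1] &
    abs(ctr[, 2] - centre[2]) <= half[2] &
    abs(ctr[, 3] - centre[3]) <= half[3]
  array(keep, dim = shp)
}

densify_centreline <- function(cl, step) {
  if (nrow(cl) == 2 || max(sqrt(rowSums(diff(cl)^2))) > step)
    resample_streamline(cl, step) else cl
}

#' Generate a ground-truth phantom
#'
#' Realises a [phantom_spec()] as: labelled truth streamlines (tube bundles
#' with a rerouted CSv-terminating fraction), per-hemisphere CSv masks,
#' waypoint ROI masks, a per-voxel stick orientation field with volume
#' fractions, a white-matter mask, and simulated diffusion signal.
#' Deterministic given the spec's seed. Errors if any two bundles' waypoint
#' ROIs come closer than two voxel widths (the phantom must be unambiguous)
#' and, with `check = TRUE`, verifies that every truth streamline crosses
#' all of its own bundle's ROIs and no other bundle's.
#'
#' @param spec a [phantom_spec()]
#' @param gtab a [gradient_table()] for the simulated signal
#' @param check run the by-construction ROI-crossing audit (default TRUE)
#' @return An object of class `csv_phantom`.
#' @export
generate_phantom <- function(spec, gtab = default_gradient_table(),
                             check = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)

  ## waypoint ROIs
  rois <- list()
  roi_owner <- character()
  for (b in spec$bundles) {
    nms <- if (length(b$roi_stations) == 1) b$name
      else paste(b$name, c("inferior", "superior"), sep = "_")
    for (q in seq_along(b$roi_stations)) {
      rois[[nms[q]]] <- binary_mask(roi_box_mask(spec, grid, b, b$roi_stations[q]),
                                    grid$affine, name = nms[q])
      roi_owner[nms[q]] <- b$name
    }
  }
  sep <- roi_separation_masks(rois, roi_owner)
  if (sep <= 2 * spec$voxel_size)
    stop("waypoint ROIs of different bundles are closer than 2 voxel widths (",
         signif(sep, 3), " mm); phantom would be ambiguous", call. = FALSE)

  ## CSv masks
  csv_masks <- lapply(names(spec$csv_centres), function(h) {
    ctr_vox <- drop(world_to_voxel(grid, spec$csv_centres[[h]]))
    r <- (spec$csv_size - 1) / 2
    lo <- floor(ctr_vox - r); hi <- floor(ctr_vox + r)
    m <- array(FALSE, dim = spec$grid_shape)
    m[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- TRUE
    binary_mask(m, grid$affine, name = paste0("CSv_", h), hemisphere = h)
  })
  names(csv_masks) <- names(spec$csv_centres)

  csv_anchor <- drop(voxel_to_world(
    grid, world_to_voxel(grid, spec$csv_centres[[spec$csv_target]])))

  truth <- withr::with_seed(spec$seed,
    generate_truth_streamlines(spec, csv_anchor))

  ofield <- orientation_field(spec, grid, truth)
  wm_mask <- binary_mask(ofield$stick_mask, grid$affine, name = "wm",
                         hemisphere = "midline", allow_empty = TRUE)
  wm_mask$hemisphere <- "midline"

  phantom <- structure(list(
    spec = spec, grid = grid, truth_streamlines = truth,
    csv_masks = csv_masks, waypoint_rois = rois, roi_owner = roi_owner,
    tract_definitions = phantom_tract_definitions(spec, roi_owner),
    orientation_field = ofield, wm_mask = wm_mask, gtab = gtab,
    signal = NULL), class = "csv_phantom")
  phantom$signal <- simulate_dwi(phantom, gtab, snr = spec$snr,
                                 seed = spec$seed + 1L)
  if (check) check_phantom_truth(phantom)
  phantom
}

#' @export
print.csv_phantom <- function(x, ...) {
  cat("<csv_phantom> ", paste(x$spec$grid_shape, collapse = "x"), " voxels @ ",
      x$spec$voxel_size, " mm | ", n_streamlines(x$truth_streamlines),
      " truth streamlines in ", length(x$spec$bundles), " bundles | ",
      length(x$waypoint_rois), " waypoint ROIs\n", sep = "")
  invisible(x)
}

roi_separation_masks <- function(rois, roi_owner) {
  nms <- names(rois)
  sep <- Inf
  if (length(nms) < 2) return(sep)
  ctrs <- lapply(rois, mask_centres)
  for (a in seq_along(nms)[-length(nms)]) for (b in (a + 1):length(nms)) {
    if (roi_owner[nms[a]] == roi_owner[nms[b]]) next
    d2 <- min(pair_dist2(ctrs[[a]], ctrs[[b]]))
    sep <- min(sep, sqrt(d2))
  }
  sep
}

pair_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
}

#' @rdname generate_phantom
#' @param phantom a `csv_phantom`
#' @return `roi_separation()`: the minimum distance (mm) between TRUE voxel
#'   centres of waypoint ROIs belonging to different bundles.
#' @export
roi_separation <- function(phantom) {
  roi_separation_masks(phantom$waypoint_rois, phantom$roi_owner)
}

generate_truth_streamlines <- function(spec, csv_anchor) {
  pts <- list(); meta <- list()
  for (b in spec$bundles) {
    if (b$n_streamlines == 0) next
    cl <- densify_centreline(b$centreline, 2)
    s <- cumsum(c(0, sqrt(rowSums(diff(cl)^2))))
    frac <- s / s[length(s)]
    dir <- cl[nrow(cl), ] - cl[1, ]
    dir <- dir / sqrt(sum(dir^2))
    u <- perp_basis(dir)
    n_reroute <- round(b$csv_fraction * b$n_streamlines)
    for (k in seq_len(b$n_streamlines)) {
      r <- b$radius * sqrt(stats::runif(1))
      ang <- 2 * pi * stats::runif(1)
      off <- r * (cos(ang) * u$u + sin(ang) * u$v)
      tube <- sweep(cl, 2, off, `+`)
      reroute <- k <= n_reroute
      if (reroute) {
        keep <- frac <= b$exit_fraction
        body <- tube[keep, , drop = FALSE]
        endpt <- csv_anchor + ball_point(spec$csv_capture_mm)
        tail_line <- rbind(body[nrow(body), ], endpt)
        tail_pts <- resample_streamline(tail_line, 2)
        p <- rbind(body, tail_pts[-1, , drop = FALSE])
        jit <- matrix(stats::rnorm(length(p), sd = 0.15), ncol = 3)
        jit[nrow(jit), ] <- 0  # endpoint must stay inside the capture ball
        p <- p + jit
      } else {
        p <- tube + matrix(stats::rnorm(length(tube), sd = 0.15), ncol = 3)
      }
      pts[[length(pts) + 1]] <- p
      meta[[length(meta) + 1]] <- tibble::tibble(
        label = b$name, csv_true = reroute,
        csv_hemisphere = if (reroute) spec$csv_target else NA_character_)
    }
  }
  streamline_set(pts, meta = dplyr::bind_rows(meta))
}

perp_basis <- function(dir) {
  helper <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- pracma_cross(dir, helper); u <- u / sqrt(sum(u^2))
  v <- pracma_cross(dir, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

ball_point <- function(radius) {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2)) * radius * stats::runif(1)^(1 / 3)
}

## Per-voxel stick orientations + volume fractions, built from the local
## orientations of the realised truth streamlines: every node of every
## truth streamline (resampled at `step` mm) deposits one stick with its
## segment tangent in the voxel it falls in, with a volume fraction
## proportional to a global per-node constant (fibre density ~ summed
## path length), normalised so the densest voxel reaches 1 - f_iso_wm.
## Free water fills the remainder, so fractions sum to 1 everywhere, and
## the noiseless signal is exactly the stick forward model of the
## generating streamlines.
orientation_field <- function(spec, grid, truth, step = 1) {
  shp <- spec$grid_shape
  acc <- list()
  for (q in seq_len(n_streamlines(truth))) {
    p <- resample_streamline(truth$streamlines[[q]], step)
    ijk <- world_to_voxel(grid, p)
    ok <- in_bounds(grid, ijk)
    if (!any(ok)) next
    d <- diff(p)
    tang <- rbind(d, d[nrow(d), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    ijk <- ijk[ok, , drop = FALSE]; tang <- tang[ok, , drop = FALSE]
    acc[[q]] <- tibble::tibble(
      i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
      vx = tang[, 1], vy = tang[, 2], vz = tang[, 3],
      bundle = truth$meta$label[q])
  }
  sticks <- dplyr::bind_rows(acc)
  if (nrow(sticks) == 0) {
    return(list(sticks = tibble::tibble(i = integer(), j = integer(),
                                        k = integer(), vx = numeric(),
                                        vy = numeric(), vz = numeric(),
                                        f = numeric(), bundle = character()),
                f_iso = array(1, dim = shp),
                stick_mask = array(FALSE, dim = shp)))
  }
  lin <- 1L + sticks$i + sticks$j * shp[1] + sticks$k * shp[1] * shp[2]
  dens <- stats::aggregate(rep(1L, nrow(sticks)), by = list(lin = lin),
                           FUN = sum)
  cscale <- (1 - spec$f_iso_wm) / max(dens$x)
  sticks$f <- rep(cscale, nrow(sticks))
  stick_mask <- array(FALSE, dim = shp)
  stick_mask[cbind(sticks$i, sticks$j, sticks$k) + 1] <- TRUE
  f_iso <- array(1, dim = shp)
  f_iso[dens$lin] <- 1 - cscale * dens$x
  list(sticks = sticks, f_iso = f_iso, stick_mask = stick_mask)
}

phantom_tract_definitions <- function(spec, roi_owner) {
  nm <- unique(roi_owner)
  tibble::tibble(
    name = nm,
    required_rois = lapply(nm, function(b) names(roi_owner)[roi_owner == b]),
    hemisphere = vapply(nm, function(b) {
      if (b == "CALLOSAL") "midline" else spec$csv_target
    }, character(1)))
}

check_phantom_truth <- function(phantom) {
  defs <- phantom$tract_definitions
  for (idx in seq_len(n_streamlines(phantom$truth_streamlines))) {
    p <- phantom$truth_streamlines$streamlines[[idx]]
    lab <- phantom$truth_streamlines$meta$label[idx]
    own <- defs$required_rois[[match(lab, defs$name)]]
    for (rn in names(phantom$waypoint_rois)) {
      hit <- passes_roi(p, phantom$waypoint_rois[[rn]])
      want <- rn %in% own
      if (hit != want)
        stop("phantom truth violation: streamline ", idx, " (", lab, ") ",
             if (hit) "crosses foreign ROI '" else "misses own ROI '",
             rn, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}
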