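#' Exact voxel traversal of a polyline
#'
#' Enumerates every 0-based voxel index whose axis-aligned voxel box the
#' polyline intersects, by walking each segment through the half-integer
#' lattice planes in continuous index space (equivalent to exact
#' segment-box intersection for the convex voxel boxes).
#'
#' @param points n x 3 matrix of world coordinates
#' @param grid a [volume_grid()] (or [binary_mask()])
#' @return integer matrix of unique traversed voxel indices (m x 3, 0-based)
#' @export
streamline_voxels <- function(points, grid) {
  ijk <- world_to_voxel(grid, points, round = FALSE)
  vox <- vector("list", nrow(ijk) - 1L)
  for (s in seq_len(nrow(ijk) - 1L)) {
    vox[[s]] <- segment_voxels(ijk[s, ], ijk[s + 1L, ])
  }
  out <- unique(do.call(rbind, vox))
  shp <- grid_shape(grid)
  keep <- out[, 1] >= 0 & out[, 1] < shp[1] &
    out[, 2] >= 0 & out[, 2] < shp[2] &
    out[, 3] >= 0 & out[, 3] < shp[3]
  out[keep, , drop = FALSE]
}

## voxels traversed by one segment in continuous index space: voxel (i,j,k)
## owns [i-0.5, i+0.5) per axis; cut the segment at every half-integer
## plane crossing and round interval midpoints.
segment_voxels <- function(p0, p1) {
  d <- p1 - p0
  ts <- 0
  for (ax in 1:3) {
    if (d[ax] == 0) next
    lo <- min(p0[ax], p1[ax]); hi <- max(p0[ax], p1[ax])
    first <- ceiling(lo - 0.5) + 0.5
    if (first > hi) next
    planes <- seq(first, hi, by = 1)
    planes <- planes[planes > lo & planes < hi]
    if (length(planes)) ts <- c(ts, (planes - p0[ax]) / d[ax])
  }
  ts <- sort(unique(c(ts, 1)))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  pts <- cbind(p0[1] + mid * d[1], p0[2] + mid * d[2], p0[3] + mid * d[3])
  unique(round(pts))
}

#' Does a streamline pass through an ROI?
#'
#' `method = "exact"` (default) tests exact segment-voxel-box
#' intersection via [streamline_voxels()]. `method = "sampled"` resamples
#' the polyline at `step_mm` (default half the voxel size) and tests the
#' sampled points, which agrees with the exact test away from
#' corner-clipping configurations.
#'
#' @param streamline n x 3 matrix of world points
#' @param roi a [binary_mask()]
#' @param step_mm resampling step for `method = "sampled"` (> 0)
#' @param method `"exact"` or `"sampled"`
#' @return logical scalar
#' @export
passes_roi <- function(streamline, roi, step_mm = NULL,
                       method = c("exact", "sampled")) {
  method <- match.arg(method)
  streamline <- as_points(streamline)
  ## cheap bounding-box rejection in world space
  centres_bb <- attr(roi, "bbox")
  if (is.null(centres_bb)) {
    ctr <- mask_centres(roi)
    if (nrow(ctr) == 0) return(FALSE)
    half <- max(voxel_size(roi)) / 2 * sqrt(3)
    centres_bb <- rbind(apply(ctr, 2, min) - half, apply(ctr, 2, max) + half)
  }
  s_lo <- apply(streamline, 2, min); s_hi <- apply(streamline, 2, max)
  if (any(s_hi < centres_bb[1, ]) || any(s_lo > centres_bb[2, ]))
    return(FALSE)
  if (method == "sampled") {
    if (is.null(step_mm)) step_mm <- min(voxel_size(roi)) / 2
    if (step_mm <= 0) stop("step_mm must be > 0", call. = FALSE)
    pts <- resample_streamline(streamline, step_mm)
    ijk <- world_to_voxel(roi, pts)
    ok <- in_bounds(roi, ijk)
    if (!any(ok)) return(FALSE)
    return(any(roi$data[ijk[ok, , drop = FALSE] + 1]))
  }
  if (!is.null(step_mm) && step_mm <= 0)
    stop("step_mm must be > 0", call. = FALSE)
  vox <- streamline_voxels(streamline, roi)
  if (nrow(vox) == 0) return(FALSE)
  any(roi$data[vox + 1])
}

#' Tract definitions: ALL-of waypoint-ROI rules
#'
#' A streamline belongs to a tract when it crosses every ROI the tract
#' requires: two for the corticospinal tract (inferior cerebral-peduncle
#' and superior ROIs, both mandatory), one for every other tract. ROIs are
#' supplied as masks; the anatomical drawing rules behind them are
#' mask-authoring guidance, not re-derived here.
#'
#' @param name tract label
#' @param required_rois character vector of ROI mask names (non-empty;
#'   exactly 2 for CST, exactly 1 otherwise)
#' @param hemisphere `"left"`, `"right"` or `"midline"`
#' @return one-row tibble; combine rows into a definitions table.
#' @export
tract_definition <- function(name, required_rois,
                             hemisphere = c("left", "right", "midline")) {
  hemisphere <- match.arg(hemisphere)
  if (length(required_rois) == 0)
    stop("required_rois must be non-empty", call. = FALSE)
  if (name == "CST" && length(required_rois) != 2)
    stop("CST requires exactly 2 waypoint ROIs", call. = FALSE)
  if (name != "CST" && length(required_rois) != 1)
    stop("tract '", name, "' requires exactly 1 waypoint ROI", call. = FALSE)
  tibble::tibble(name = name, required_rois = list(required_rois),
                 hemisphere = hemisphere)
}

#' @rdname tract_definition
#' @export
default_precedence <- function() {
  c("CST", "AF", "CALLOSAL", "CINGULUM", "SLF_I", "SLF_II", "SLF_III")
}

#' Classify one streamline against tract definitions
#'
#' Evaluates every tract's ALL-of rule and returns the first satisfied
#' tract in precedence order, or `"UNCATEGORISED"` if none matches.
#'
#' @param streamline n x 3 matrix of world points
#' @param defs definitions tibble ([tract_definition()] rows)
#' @param rois named list of [binary_mask()] referenced by the definitions
#' @param precedence ordered character vector of tract labels (default:
#'   the standard order restricted to the tracts in `defs`)
#' @param method,step_mm passed to [passes_roi()]
#' @return list with `label` and `matched` (all tracts whose rule held)
#' @export
classify_streamline <- function(streamline, defs, rois,
                                precedence = NULL,
                                method = "exact", step_mm = NULL) {
  if (is.null(precedence))
    precedence <- intersect(default_precedence(), defs$name)
  unknown <- setdiff(precedence, defs$name)
  if (length(unknown))
    stop("precedence contains unknown tract label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_rois <- setdiff(unlist(defs$required_rois), names(rois))
  if (length(missing_rois))
    stop("definitions reference missing ROI mask(s): ",
         paste(missing_rois, collapse = ", "), call. = FALSE)
  roi_hit <- list()
  hit <- function(rn) {
    if (is.null(roi_hit[[rn]]))
      roi_hit[[rn]] <<- passes_roi(streamline, rois[[rn]], step_mm = step_mm,
                                   method = method)
    roi_hit[[rn]]
  }
  matched <- defs$name[vapply(seq_len(nrow(defs)), function(q)
    all(vapply(defs$required_rois[[q]], hit, logical(1))), logical(1))]
  ordered <- precedence[precedence %in% matched]
  label <- if (length(ordered)) ordered[1] else "UNCATEGORISED"
  list(label = label, matched = matched)
}

#' Classify a streamline set into tracts
#'
#' Applies [classify_streamline()] to every streamline. In the default
#' exclusive mode each streamline receives exactly one label (first match
#' in precedence order, `UNCATEGORISED` if none), so per-hemisphere counts
#' including `UNCATEGORISED` partition the input; streamlines whose
#' rules matched more than one tract are logged in `overlap_log` before
#' precedence resolution. `mode = "multi"` records all matching labels
#' instead.
#'
#' @param set a [streamline_set()] (typically the CSv selection, carrying a
#'   `hemisphere` meta column; `"left"` assumed if absent)
#' @param defs,rois,precedence,method,step_mm as in [classify_streamline()]
#' @param mode `"exclusive"` (default) or `"multi"`
#' @return An object of class `csv_classification`: tibble `labels`
#'   (index, hemisphere, label, matched), tibble `counts` (hemisphere,
#'   tract, n), tibble `overlap_log`.
#' @export
classify_set <- function(set, defs, rois, precedence = NULL,
                         mode = c("exclusive", "multi"),
                         method = "exact", step_mm = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "streamline_set"))
  if (is.null(precedence))
    precedence <- intersect(default_precedence(), defs$name)
  n <- n_streamlines(set)
  hemi <- set$meta[["hemisphere"]]
  if (is.null(hemi)) hemi <- rep("left", n)
  res <- lapply(seq_len(n), function(q)
    classify_streamline(set$streamlines[[q]], defs, rois, precedence,
                        method = method, step_mm = step_mm))
  labels <- tibble::tibble(
    index = seq_len(n),
    hemisphere = hemi,
    label = vapply(res, `[[`, character(1), "label"),
    matched = lapply(res, `[[`, "matched"))
  overlap <- labels[lengths(labels$matched) > 1, ]
  tracts <- c(defs$name, "UNCATEGORISED")
  count_base <- tidyr::expand_grid(hemisphere = unique(hemi), tract = tracts)
  tallied <- if (mode == "exclusive") {
    dplyr::count(labels, .data$hemisphere, tract = .data$label, name = "n")
  } else {
    long <- tidyr::unnest(
      dplyr::mutate(labels, tract = purrr::map(.data$matched, function(m)
        if (length(m)) m else "UNCATEGORISED")), "tract")
    dplyr::count(long, .data$hemisphere, .data$tract, name = "n")
  }
  counts <- dplyr::arrange(
    dplyr::mutate(dplyr::left_join(count_base, tallied,
                                   by = c("hemisphere", "tract")),
                  n = dplyr::coalesce(.data$n, 0L)),
    .data$hemisphere, match(.data$tract, tracts))
  structure(list(labels = labels, counts = counts, overlap_log = overlap,
                 mode = mode, n_input = n),
            class = "csv_classification")
}

#' @export
print.csv_classification <- function(x, ...) {
  cat("<csv_classification> ", x$n_input, " streamlines (", x$mode,
      " mode), ", nrow(x$overlap_log), " multi-rule matches\n", sep = "")
  print(tidyr::pivot_wider(x$counts, names_from = "hemisphere",
                           values_from = "n"))
  invisible(x)
}

#' @rdname classify_set
#' @param x a `csv_classification`
#' @method tidy csv_classification
#' @export
tidy.csv_classification <- function(x, ...) x$counts
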