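#' Selection configuration for CSv-proximal streamlines
#'
#' Streamlines qualify when either endpoint lies within `distance_mm`
#' (inclusive) of the nearest CSv voxel centre. 3 mm is the study
#' threshold; the distance is measured point-to-voxel-centre.
#'
#' @param distance_mm selection distance in mm (> 0; default 3)
#' @param endpoint_rule only `"either_endpoint"` is defined
#' @param distance_target only `"voxel_centres"` is defined
#' @export
selection_config <- function(distance_mm = 3.0,
                             endpoint_rule = "either_endpoint",
                             distance_target = "voxel_centres") {
  if (!is.numeric(distance_mm) || distance_mm <= 0)
    stop("distance_mm must be > 0", call. = FALSE)
  endpoint_rule <- match.arg(endpoint_rule, "either_endpoint")
  distance_target <- match.arg(distance_target, "voxel_centres")
  structure(list(distance_mm = distance_mm, endpoint_rule = endpoint_rule,
                 distance_target = distance_target),
            class = "selection_config")
}

#' Distance from a streamline's endpoints to a mask
#'
#' Minimum over both endpoints of the Euclidean distance to the nearest
#' TRUE-voxel centre (world mm). Interior points are ignored: termination
#' near the seed region is what qualifies a streamline.
#'
#' @param streamline n x 3 matrix of world points
#' @param mask a non-empty [binary_mask()]
#' @return scalar distance in mm
#' @export
endpoint_distance <- function(streamline, mask) {
  centres <- mask_centres(mask)
  if (nrow(centres) == 0) stop("mask is empty", call. = FALSE)
  streamline <- as_points(streamline)
  ends <- streamline[c(1, nrow(streamline)), , drop = FALSE]
  sqrt(min(pair_dist2(ends, centres)))
}

#' Select CSv streamlines by endpoint proximity
#'
#' Returns the streamlines with an endpoint within `distance_mm` of a CSv
#' voxel centre, tagged with the hemisphere of the qualifying mask. A
#' streamline within the threshold of both hemispheres' masks is assigned
#' to the nearer one, ties to the left. Original indices are retained in
#' the `orig_index` meta column; selection is order-independent and
#' monotone in the threshold.
#'
#' @param set a [streamline_set()]
#' @param csv_masks a single [binary_mask()] or a named list of them (e.g.
#'   `list(left = ..., right = ...)`)
#' @param cfg a [selection_config()]
#' @return The selected `streamline_set` with meta columns `orig_index`,
#'   `csv_distance`, `hemisphere` (possibly empty).
#' @export
select_csv_streamlines <- function(set, csv_masks, cfg = selection_config()) {
  stopifnot(inherits(set, "streamline_set"), inherits(cfg, "selection_config"))
  if (inherits(csv_masks, "binary_mask")) {
    csv_masks <- stats::setNames(list(csv_masks), csv_masks$hemisphere)
  }
  n <- n_streamlines(set)
  if (n == 0) return(empty_selection(set))
  dists <- vapply(csv_masks, function(m)
    vapply(set$streamlines, endpoint_distance, numeric(1), mask = m),
    numeric(n))
  dists <- matrix(dists, nrow = n,
                  dimnames = list(NULL, names(csv_masks)))
  dmin <- apply(dists, 1, min)
  sel <- which(dmin <= cfg$distance_mm)
  if (length(sel) == 0) return(empty_selection(set))
  hemi_order <- order(match(colnames(dists), c("left", "right", "midline")))
  hemi <- vapply(sel, function(r) {
    d <- dists[r, hemi_order]
    colnames(dists)[hemi_order][which.min(d)]  # which.min: first (left) on ties
  }, character(1))
  out <- set[sel]
  out$meta$orig_index <- sel
  out$meta$csv_distance <- dmin[sel]
  out$meta$hemisphere <- hemi
  out
}

empty_selection <- function(set) {
  out <- set[integer(0)]
  out$meta$orig_index <- integer(0)
  out$meta$csv_distance <- numeric(0)
  out$meta$hemisphere <- character(0)
  out
}
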