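#' Streamline sets
#'
#' A streamline is an ordered polyline of 3D world-space points (mm); a
#' streamline set bundles many of them with optional per-streamline
#' metadata: `provenance` (generation-parameter tag), non-negative
#' `weight`, and ground-truth or assigned tract `label`. Metadata live in a
#' tibble (`$meta`, one row per streamline) so downstream tabular results
#' can be joined onto it.
#'
#' @param points list of n_i x 3 numeric matrices, each with >= 2 rows of
#'   finite world coordinates (mm)
#' @param provenance optional character vector, one tag per streamline
#' @param weights optional non-negative numeric vector
#' @param labels optional character vector of tract labels
#' @param meta optional tibble of additional per-streamline columns
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(points, provenance = NULL, weights = NULL,
                           labels = NULL, meta = NULL) {
  if (!is.list(points)) stop("`points` must be a list of matrices", call. = FALSE)
  points <- lapply(points, function(p) {
    p <- as_points(p)
    if (nrow(p) < 2) stop("each streamline needs >= 2 points", call. = FALSE)
    if (any(!is.finite(p))) stop("streamline coordinates must be finite", call. = FALSE)
    unname(p)
  })
  n <- length(points)
  if (is.null(meta)) meta <- tibble::tibble(.rows = n)
  if (nrow(meta) != n) stop("meta must have one row per streamline", call. = FALSE)
  if (!is.null(provenance)) {
    stopifnot(length(provenance) == n)
    meta$provenance <- as.character(provenance)
  }
  if (!is.null(weights)) {
    if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite, non-negative, one per streamline", call. = FALSE)
    meta$weight <- as.numeric(weights)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    meta$label <- as.character(labels)
  }
  structure(list(streamlines = points, meta = meta), class = "streamline_set")
}

#' @rdname streamline_set
#' @param x a `streamline_set`
#' @export
n_streamlines <- function(x) length(x$streamlines)

#' @export
length.streamline_set <- function(x) n_streamlines(x)

#' @export
`[.streamline_set` <- function(x, i, ...) {
  streamline_set(x$streamlines[i], meta = x$meta[i, , drop = FALSE])
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- n_streamlines(x)
  cat("<streamline_set> ", n, " streamline", if (n != 1) "s", sep = "")
  if (n > 0) {
    len <- arc_lengths(x)
    cat(sprintf(" | length %.1f-%.1f mm", min(len), max(len)))
  }
  extra <- setdiff(names(x$meta), character())
  if (length(extra)) cat(" | meta:", paste(extra, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Streamline geometry
#'
#' `arc_length()` sums segment lengths of one polyline; `arc_lengths()`
#' vectorises over a set. `resample_streamline()` re-samples a polyline at a
#' fixed arc-length step (endpoints always retained).
#'
#' @param points n x 3 matrix of world coordinates
#' @param x a `streamline_set`
#' @param step step size in mm (> 0)
#' @export
arc_length <- function(points) {
  points <- as_points(points)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' @rdname arc_length
#' @export
arc_lengths <- function(x) vapply(x$streamlines, arc_length, numeric(1))

#' @rdname arc_length
#' @export
resample_streamline <- function(points, step) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  points <- as_points(points)
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) stop("degenerate streamline of zero length", call. = FALSE)
  target <- unique(c(seq(0, total, by = step), total))
  cbind(stats::approx(s, points[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, points[, 2], xout = target, ties = "ordered")$y,
        stats::approx(s, points[, 3], xout = target, ties = "ordered")$y)
}

#' Pool streamline sets (ensemble accounting)
#'
#' Concatenates several candidate sets (e.g. one per tracking-parameter
#' setting) into one, preserving per-streamline provenance so the pooled
#' bookkeeping — how many candidates each batch contributed — stays
#' auditable, in the spirit of ensemble tractography.
#'
#' @param sets list of `streamline_set` objects
#' @return A single `streamline_set`; `provenance_counts()` tabulates it.
#' @export
pool_streamline_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0)
  pts <- unlist(lapply(sets, `[[`, "streamlines"), recursive = FALSE)
  meta <- dplyr::bind_rows(lapply(sets, `[[`, "meta"))
  streamline_set(pts, meta = meta)
}

#' @rdname pool_streamline_sets
#' @param x a `streamline_set` with a `provenance` meta column
#' @export
provenance_counts <- function(x) {
  prov <- x$meta$provenance
  if (is.null(prov)) prov <- rep(NA_character_, n_streamlines(x))
  dplyr::count(tibble::tibble(provenance = prov), .data$provenance, name = "n")
}
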