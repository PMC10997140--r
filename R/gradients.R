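#' Diffusion gradient tables
#'
#' A gradient table pairs unit-norm gradient directions with b-values
#' (s/mm^2), one per acquired volume. Entries with `b <= b0_threshold` are
#' b=0 baselines and may carry a zero direction vector.
#'
#' @param directions n x 3 matrix of gradient directions; non-b0 rows must
#'   have Euclidean norm 1 within 1e-6
#' @param bvalues numeric vector of length n, all >= 0
#' @param b0_threshold b-values at or below this count as b=0 (default 50)
#' @return An object of class `gradient_table` with elements `directions`,
#'   `bvalues`, `n_b0`, `b0_threshold`.
#' @export
gradient_table <- function(directions, bvalues, b0_threshold = 50) {
  directions <- as_points(directions)
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("directions and bvalues must have equal length", call. = FALSE)
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("bvalues must be finite and >= 0", call. = FALSE)
  is_b0 <- bvalues <= b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[!is_b0] - 1) > 1e-6))
    stop("non-b0 gradient directions must be unit-norm within 1e-6", call. = FALSE)
  structure(list(directions = directions, bvalues = bvalues,
                 n_b0 = sum(is_b0), b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table> ", length(x$bvalues), " volumes (",
      x$n_b0, " b=0), b = ", paste(unique(round(x$bvalues)), collapse = "/"),
      " s/mm2\n", sep = "")
  invisible(x)
}

b0_index <- function(gtab) which(gtab$bvalues <= gtab$b0_threshold)
dw_index <- function(gtab) which(gtab$bvalues > gtab$b0_threshold)

#' @rdname gradient_table
#' @param bval_path,bvec_path FSL-style text files: bvals one whitespace-
#'   delimited row; bvecs three rows (x, y, z), columns matching bvals.
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3)
    stop("bvec file must have exactly 3 rows (x, y, z)", call. = FALSE)
  gradient_table(unname(t(bvecs)), bvals, b0_threshold)
}

#' @rdname gradient_table
#' @param gtab a `gradient_table`
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  fmt <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = " ")
  writeLines(fmt(gtab$bvalues), bval_path)
  writeLines(vapply(1:3, function(ax) fmt(gtab$directions[, ax]), character(1)),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Default acquisition scheme: 64 directions at b = 1000 plus 6 b = 0
#'
#' Directions are a deterministic spherical Fibonacci point set — an
#' approximately uniform sampling of the sphere, standing in for a
#' clinical-style 64-direction scheme.
#'
#' @param n_directions number of diffusion-weighted directions
#' @param bvalue b-value of the weighted volumes (s/mm^2)
#' @param n_b0 number of b=0 volumes (placed first)
#' @return a [gradient_table()]
#' @export
default_gradient_table <- function(n_directions = 64, bvalue = 1000, n_b0 = 6) {
  i <- seq_len(n_directions) - 0.5
  phi <- acos(1 - 2 * i / n_directions)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_table(rbind(matrix(0, n_b0, 3), dirs),
                 c(rep(0, n_b0), rep(bvalue, n_directions)))
}
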