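#' Simulate diffusion-weighted signal from the phantom's orientation field
#'
#' Per voxel the signal follows a multi-stick forward model:
#' `S(g, b) = S0 * (sum_k f_k exp(-b d_ax (g . t_k)^2) + f_iso exp(-b d_iso))`
#' where `t_k` are the voxel's stick orientations and `f_k` their volume
#' fractions (summing with `f_iso` to 1). Noise is Rician by default
#' (`|S + N(0, sigma) + i N(0, sigma)|`, `sigma = S0 / snr`), Gaussian
#' optionally; `snr = Inf` gives the exact noiseless forward model.
#'
#' @param phantom a `csv_phantom`
#' @param gtab a [gradient_table()]
#' @param snr signal-to-noise ratio (`Inf` for noiseless)
#' @param seed RNG seed for the noise draw (ignored when noiseless)
#' @return 4D [volume_grid()] of shape `grid x n_volumes`, non-negative.
#' @export
simulate_dwi <- function(phantom, gtab = phantom$gtab, snr = Inf, seed = 1) {
  spec <- phantom$spec
  shp <- spec$grid_shape
  of <- phantom$orientation_field
  b <- gtab$bvalues
  G <- gtab$directions
  nvol <- length(b)
  nvox <- prod(shp)

  f_iso <- as.vector(of$f_iso)
  sticks <- of$sticks
  lin <- if (nrow(sticks) > 0)
    1L + sticks$i + sticks$j * shp[1] + sticks$k * shp[1] * shp[2]
  else integer(0)
  ## fractions must sum to 1 in every voxel
  fsum <- f_iso
  if (length(lin) > 0) {
    add <- rowsum(sticks$f, lin)
    ul <- as.integer(rownames(add))
    fsum[ul] <- fsum[ul] + add[, 1]
  }
  if (any(abs(fsum - 1) > 1e-9))
    stop("orientation-field volume fractions do not sum to 1 in ",
         sum(abs(fsum - 1) > 1e-9), " voxel(s)", call. = FALSE)

  sig <- outer(f_iso, exp(-b * spec$d_iso))
  if (length(lin) > 0) {
    V <- as.matrix(sticks[, c("vx", "vy", "vz")])
    att <- exp(-sweep((G %*% t(V))^2, 1, b * spec$d_ax, `*`))  # nvol x n_stick
    contrib <- t(att) * sticks$f            # n_stick x nvol
    add <- rowsum(contrib, lin)
    ul <- as.integer(rownames(add))
    sig[ul, ] <- sig[ul, ] + add
  }
  sig <- spec$S0 * sig

  if (is.finite(snr)) {
    sigma <- spec$S0 / snr
    sig <- withr::with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow = nrow(sig))
      if (spec$noise_model == "rician") {
        n2 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow = nrow(sig))
        sqrt((sig + n1)^2 + n2^2)
      } else {
        sig + n1
      }
    })
  }
  volume_grid(array(sig, dim = c(shp, nvol)), phantom$grid$affine)
}

#' Generate candidate streamlines (truth members plus distractors)
#'
#' Emulates pooled multi-parameter tractography output at desk scale: a
#' shuffled union of (a) jittered copies of ground-truth bundle streamlines
#' and (b) spurious streamlines — smooth random walks whose local
#' orientations are decorrelated from the phantom's orientation field. Each
#' candidate carries a provenance tag drawn from four angle-threshold
#' batches (5.7, 11.5, 23.1, 47.2 degrees) and a ground-truth validity
#' flag. All candidates respect the length bounds.
#'
#' @param phantom a `csv_phantom`
#' @param n_true number of truth-derived candidates
#' @param n_spurious number of distractor candidates
#' @param seed RNG seed
#' @param min_length,max_length streamline length bounds in mm
#' @param jitter_sd Gaussian jitter (mm) applied to interior points of
#'   truth-derived candidates (endpoints stay exact)
#' @param turn_sd per-step direction perturbation of the spurious walks;
#'   larger values decorrelate them faster from any bundle orientation
#' @return A [streamline_set()] with meta columns `truth_valid`, `label`,
#'   `csv_true`, `csv_hemisphere`, `provenance`.
#' @export
generate_candidates <- function(phantom, n_true = 2000, n_spurious = 2000,
                                seed = 1, min_length = 4, max_length = 250,
                                jitter_sd = 0.2, turn_sd = 0.35) {
  stopifnot(n_true >= 0, n_spurious >= 0)
  angle_labels <- c("5.7deg", "11.5deg", "23.1deg", "47.2deg")
  truth <- phantom$truth_streamlines
  spec <- phantom$spec

  withr::with_seed(seed, {
    pts <- list(); meta <- NULL
    if (n_true > 0) {
      if (n_streamlines(truth) == 0)
        stop("phantom has no truth streamlines to subsample", call. = FALSE)
      idx <- sample(n_streamlines(truth), n_true,
                    replace = n_true > n_streamlines(truth))
      tp <- lapply(truth$streamlines[idx], function(p) {
        jit <- matrix(stats::rnorm(length(p), sd = jitter_sd), ncol = 3)
        jit[c(1, nrow(jit)), ] <- 0  # endpoints stay exact
        p + jit
      })
      tm <- truth$meta[idx, c("label", "csv_true", "csv_hemisphere")]
      tm$truth_valid <- TRUE
      pts <- c(pts, tp); meta <- tm
    }
    if (n_spurious > 0) {
      sp <- spurious_walks(spec, n_spurious, turn_sd)
      sm <- tibble::tibble(label = NA_character_, csv_true = FALSE,
                           csv_hemisphere = NA_character_,
                           truth_valid = FALSE, .rows = n_spurious)
      pts <- c(pts, sp); meta <- dplyr::bind_rows(meta, sm)
    }
    n <- length(pts)
    if (n == 0) return(streamline_set(list()))
    meta$provenance <- rep(angle_labels, length.out = n)
    ord <- sample(n)
    out <- streamline_set(pts[ord], meta = meta[ord, ])
    len <- arc_lengths(out)
    keep <- len >= min_length & len <= max_length
    out[keep]
  })
}

## smooth random walks, reflected at the grid border, step 2 mm
spurious_walks <- function(spec, n, turn_sd = 0.35) {
  half <- (spec$grid_shape - 1) / 2 * spec$voxel_size
  n_steps <- ceiling(stats::runif(n, 20, 80) / 2)
  max_steps <- max(n_steps)
  pos <- sweep(matrix(stats::runif(n * 3, -0.7, 0.7), ncol = 3), 2, half, `*`)
  v <- matrix(stats::rnorm(n * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  hist <- array(NA_real_, dim = c(max_steps + 1, n, 3))
  hist[1, , ] <- pos
  lim <- 0.92 * half
  for (s in seq_len(max_steps)) {
    nxt <- pos + 2 * v
    for (ax in 1:3) {
      flip <- abs(nxt[, ax]) > lim[ax]
      v[flip, ax] <- -v[flip, ax]
    }
    pos <- pos + 2 * v
    hist[s + 1, , ] <- pos
    v <- v + turn_sd * matrix(stats::rnorm(n * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
  }
  lapply(seq_len(n), function(w) {
    m <- hist[seq_len(n_steps[w] + 1), w, , drop = FALSE]
    matrix(m, ncol = 3)
  })
}
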