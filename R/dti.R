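#' Fit the diffusion tensor per voxel
#'
#' Ordinary (unweighted) log-linear least squares: per masked voxel the
#' model `ln(S/S0) = -b g' D g` is solved for the six unique elements of
#' the symmetric tensor D, with `S0` the mean of the b = 0 volumes and
#' non-positive signals clamped to `signal_floor * S0` before the log. The
#' fit is exact on noiseless single-tensor signal.
#'
#' @param signal 4D [volume_grid()] (spatial dims x volumes)
#' @param gtab matching [gradient_table()]; needs at least 6 non-collinear
#'   diffusion-weighted directions and one b = 0 volume
#' @param mask optional [binary_mask()] restricting the fit
#' @param signal_floor relative floor applied before the log (default 1e-6)
#' @return An object of class `tensor_fit`: arrays `eigenvalues`
#'   (shape x 3, sorted descending), `pdd` (shape x 3, unit principal
#'   direction), `fa` (shape), `tensor` (shape x 6: Dxx, Dyy, Dzz, Dxy,
#'   Dxz, Dyz), plus the grid and mask.
#' @export
fit_tensor <- function(signal, gtab, mask = NULL, signal_floor = 1e-6) {
  dims <- dim(signal$data)
  stopifnot(length(dims) == 4, dims[4] == length(gtab$bvalues))
  shp <- dims[1:3]
  b0 <- b0_index(gtab); dw <- dw_index(gtab)
  if (length(b0) < 1) stop("need at least one b = 0 volume", call. = FALSE)
  if (length(dw) < 6) stop("need at least 6 diffusion-weighted directions",
                           call. = FALSE)
  G <- gtab$directions[dw, , drop = FALSE]
  bv <- gtab$bvalues[dw]
  ## design: -b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
  B <- -bv * cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
                   2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3],
                   2 * G[, 2] * G[, 3])
  if (qr(B)$rank < 6)
    stop("gradient scheme is rank-deficient: fewer than 6 independent directions",
         call. = FALSE)

  flat <- matrix(signal$data, nrow = prod(shp))
  vox <- if (is.null(mask)) seq_len(prod(shp)) else which(as.vector(mask$data))
  s0 <- rowMeans(flat[vox, b0, drop = FALSE])
  s0[s0 <= 0] <- NA_real_
  sdw <- flat[vox, dw, drop = FALSE]
  floor_vals <- signal_floor * s0
  sdw <- pmax(sdw, floor_vals)          # recycles per column (voxel-wise floor)
  y <- log(sdw / s0)
  ## one least-squares inversion applied to all voxels at once
  coef <- t(qr.solve(B, t(y)))          # n_vox x 6

  ev <- matrix(NA_real_, length(vox), 3)
  pd <- matrix(NA_real_, length(vox), 3)
  for (q in seq_len(length(vox))) {
    d6 <- coef[q, ]
    if (any(!is.finite(d6))) next
    D <- matrix(c(d6[1], d6[4], d6[5],
                  d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    ev[q, ] <- e$values            # eigen() sorts descending
    v1 <- e$vectors[, 1]
    ## antipodally canonical: largest-magnitude component positive
    v1 <- v1 * sign(v1[which.max(abs(v1))])
    pd[q, ] <- v1 / sqrt(sum(v1^2))
  }
  md <- rowMeans(ev)
  denom <- rowSums(ev^2)
  fa_v <- sqrt(1.5 * rowSums((ev - md)^2) / pmax(denom, .Machine$double.eps))
  fa_v[denom == 0] <- 0

  to_arr <- function(m, d4) {
    a <- array(NA_real_, dim = c(shp, d4))
    flat_a <- matrix(a, nrow = prod(shp))
    flat_a[vox, ] <- m
    array(flat_a, dim = c(shp, d4))
  }
  fa_arr <- array(NA_real_, dim = shp); fa_arr[vox] <- fa_v
  structure(list(tensor = to_arr(coef, 6), eigenvalues = to_arr(ev, 3),
                 pdd = to_arr(pd, 3), fa = fa_arr,
                 grid = volume_grid(array(0, dim = shp), signal$affine),
                 mask_index = vox),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat("<tensor_fit> ", paste(dim(x$fa), collapse = "x"), " voxels, ",
      length(x$mask_index), " fitted | median FA ",
      signif(stats::median(x$fa[x$mask_index], na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Colour-coded principal-diffusion-direction (PDD) map
#'
#' Standard directional colour convention weighted by FA: red = left-right
#' (|x|), green = anterior-posterior (|y|), blue = superior-inferior (|z|),
#' each scaled by the voxel's FA and clipped to [0, 1]. Antipodal by
#' construction: negating the PDD leaves the map unchanged; FA = 0 voxels
#' are black.
#'
#' @param fit a [fit_tensor()] result
#' @return 4D [volume_grid()] with a trailing RGB dimension of size 3.
#' @export
pdd_rgb_map <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  shp <- dim(fit$fa)
  rgb <- abs(fit$pdd) * as.vector(fit$fa)   # fa recycled over the 3 channels
  rgb[is.na(rgb)] <- 0
  rgb <- pmin(pmax(rgb, 0), 1)
  volume_grid(array(rgb, dim = c(shp, 3)), fit$grid$affine)
}
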