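#' Build a linear fascicle evaluation (LiFE) model
#'
#' Maps non-negative per-streamline weights to the demeaned
#' diffusion-weighted signal. Each candidate is resampled at a fixed step
#' (default half the voxel size, so no voxel traversal is skipped on the
#' lattice); for every masked voxel it traverses, its contribution to
#' direction `g` is the demeaned single-stick prediction
#' `exp(-b d_ax (g . t)^2) - mean_g(...)` with `t` the local segment
#' orientation, summed over the streamline's nodes in that voxel. The
#' target is the measured diffusion-weighted signal demeaned per voxel
#' across directions, so direction-independent (isotropic) signal cancels.
#'
#' @param candidates a [streamline_set()] (non-empty)
#' @param signal 4D [volume_grid()] of measured signal
#' @param gtab matching [gradient_table()]
#' @param wm_mask [binary_mask()] of voxels entering the model
#' @param d_ax axial stick diffusivity (mm^2/s)
#' @param step resampling step in mm (default half the voxel size)
#' @return An object of class `life_model`: sparse `design`
#'   ((voxel, direction) rows x candidate columns), `target` vector,
#'   `node_map` (per-candidate traversed voxel indices with local
#'   orientations), and bookkeeping.
#' @export
build_life_model <- function(candidates, signal, gtab, wm_mask,
                             d_ax = 1e-3, step = NULL) {
  stopifnot(inherits(candidates, "streamline_set"),
            inherits(wm_mask, "binary_mask"))
  n_cand <- n_streamlines(candidates)
  if (n_cand == 0) stop("candidate set is empty", call. = FALSE)
  if (is.null(step)) step <- min(voxel_size(wm_mask)) / 2
  dims <- dim(signal$data)
  stopifnot(length(dims) == 4, dims[4] == length(gtab$bvalues),
            all(dims[1:3] == grid_shape(wm_mask)))
  shp <- dims[1:3]

  dw <- dw_index(gtab)
  G <- gtab$directions[dw, , drop = FALSE]
  bd <- gtab$bvalues[dw] * d_ax
  n_dir <- length(dw)

  vox_lin <- which(as.vector(wm_mask$data))       # 1-based linear indices
  n_vox <- length(vox_lin)
  if (n_vox == 0) stop("white-matter mask is empty", call. = FALSE)
  row_of <- integer(prod(shp)); row_of[vox_lin] <- seq_len(n_vox)

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  node_map <- vector("list", n_cand)
  for (jc in seq_len(n_cand)) {
    p <- resample_streamline(candidates$streamlines[[jc]], step)
    ijk <- world_to_voxel(wm_mask, p)
    ok <- in_bounds(wm_mask, ijk)
    if (!any(ok)) { node_map[[jc]] <- integer(0); next }
    lin <- 1L + ijk[, 1] + ijk[, 2] * shp[1] + ijk[, 3] * shp[1] * shp[2]
    ## node tangents from adjacent resampled points
    d <- diff(p)
    tang <- rbind(d, d[nrow(d), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    keep <- ok & row_of[lin] > 0
    if (!any(keep)) { node_map[[jc]] <- integer(0); next }
    lin <- lin[keep]; tang <- tang[keep, , drop = FALSE]
    ## demeaned stick profile per node: n_dir x n_node
    att <- exp(-bd * (G %*% t(tang))^2)
    att <- sweep(att, 2, colMeans(att))
    ## sum node profiles per traversed voxel
    per_vox <- rowsum(t(att), lin)                # n_uvox x n_dir
    uvox <- as.integer(rownames(per_vox))
    rows <- rep((row_of[uvox] - 1L) * n_dir, each = n_dir) + seq_len(n_dir)
    trip_i[[jc]] <- rows
    trip_j[[jc]] <- rep(jc, length(rows))
    trip_x[[jc]] <- as.vector(t(per_vox))
    node_map[[jc]] <- uvox
  }
  if (all(lengths(node_map) == 0))
    stop("no candidate intersects the white-matter mask: degenerate model",
         call. = FALSE)
  design <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                 x = unlist(trip_x),
                                 dims = c(n_vox * n_dir, n_cand))
  flat <- matrix(signal$data, nrow = prod(shp))[vox_lin, dw, drop = FALSE]
  target <- as.vector(t(flat - rowMeans(flat)))    # demeaned per voxel
  structure(list(design = design, target = target, node_map = node_map,
                 vox_lin = vox_lin, n_dir = n_dir, d_ax = d_ax, step = step),
            class = "life_model")
}

#' @export
print.life_model <- function(x, ...) {
  cat("<life_model> design ", nrow(x$design), " x ", ncol(x$design),
      " (", length(x$vox_lin), " voxels x ", x$n_dir, " directions)\n", sep = "")
  invisible(x)
}

#' Solve for non-negative streamline weights
#'
#' Minimises `||target - design w||^2` subject to `w >= 0` by cyclic
#' coordinate descent on the normal equations (each update is the exact
#' one-dimensional minimiser, so the objective is non-increasing), stopping
#' when the KKT residual falls below `tol` relative to the problem scale.
#' Non-convergence within `max_iter` sweeps returns the best iterate with
#' `converged = FALSE` and a warning.
#'
#' @param model a [build_life_model()] result, or a list with `design` and
#'   `target`
#' @param max_iter maximum coordinate-descent sweeps
#' @param tol relative KKT tolerance
#' @param epsilon_rel weights above `epsilon_rel * max(w)` count as kept
#' @return An object of class `life_result`: `weights` (>= 0), `rmse`,
#'   `kept_indices`, `converged`, `objective_trace`.
#' @export
solve_weights <- function(model, max_iter = 2000, tol = 1e-10,
                          epsilon_rel = 1e-8) {
  A <- model$design
  b <- model$target
  Q <- as.matrix(Matrix::crossprod(A))
  cvec <- as.numeric(Matrix::crossprod(A, b))
  fit <- nnls_cd(Q, cvec, as.integer(max_iter), tol)
  if (!fit$converged)
    warning("NNLS did not reach the KKT tolerance within ", max_iter,
            " sweeps; returning best iterate")
  w <- as.numeric(fit$x)
  resid <- b - as.numeric(A %*% w)
  eps <- if (max(w) > 0) epsilon_rel * max(w) else 0
  structure(list(weights = w, rmse = sqrt(mean(resid^2)),
                 kept_indices = which(w > eps), converged = fit$converged,
                 iterations = fit$iterations,
                 objective_trace = fit$objective_trace + sum(b^2) / 2),
            class = "life_result")
}

#' @export
print.life_result <- function(x, ...) {
  cat("<life_result> ", length(x$kept_indices), "/", length(x$weights),
      " streamlines kept | rmse ", signif(x$rmse, 4),
      if (!x$converged) " | NOT converged", "\n", sep = "")
  invisible(x)
}

#' Cull non-contributing streamlines
#'
#' Keeps only candidates whose weight exceeds `epsilon` (default 1e-8 of
#' the maximum weight — "did not contribute" read as numerically zero),
#' attaching the surviving weights to the returned set's metadata. Removed
#' columns carry (near-)zero weight, so the culled model's prediction
#' error equals the full model's to numerical precision.
#'
#' @param candidates the [streamline_set()] the model was built from
#' @param result a [solve_weights()] result aligned with `candidates`
#' @param epsilon absolute weight threshold (default `1e-8 * max(weights)`)
#' @return The culled `streamline_set` with a `weight` meta column (empty,
#'   with a warning, if every weight is at or below `epsilon`).
#' @export
cull_streamlines <- function(candidates, result, epsilon = NULL) {
  stopifnot(inherits(result, "life_result"),
            length(result$weights) == n_streamlines(candidates))
  w <- result$weights
  if (is.null(epsilon)) epsilon <- if (max(w) > 0) 1e-8 * max(w) else 0
  keep <- which(w > epsilon)
  if (length(keep) == 0) {
    warning("all weights <= epsilon: returning empty streamline set")
    return(streamline_set(list()))
  }
  out <- candidates[keep]
  out$meta$weight <- w[keep]
  out$meta$orig_index <- keep
  out
}
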