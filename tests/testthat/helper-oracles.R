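# Independent brute-force oracles used to cross-check the implementation.

## minimum endpoint-to-voxel-centre distance by explicit double loop
oracle_endpoint_distance <- function(points, mask) {
  centres <- mask_centres(mask)
  ends <- points[c(1, nrow(points)), , drop = FALSE]
  best <- Inf
  for (e in seq_len(nrow(ends)))
    for (v in seq_len(nrow(centres)))
      best <- min(best, sqrt(sum((ends[e, ] - centres[v, ])^2)))
  best
}

## exact segment vs axis-aligned box intersection (slab method)
oracle_segment_box <- function(p0, p1, lo, hi) {
  d <- p1 - p0
  tmin <- 0; tmax <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) return(FALSE)
    } else {
      t1 <- (lo[ax] - p0[ax]) / d[ax]
      t2 <- (hi[ax] - p0[ax]) / d[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
      if (tmin > tmax) return(FALSE)
    }
  }
  TRUE
}

## does any segment of the polyline intersect any TRUE voxel box?
oracle_passes_roi <- function(points, roi) {
  centres <- mask_centres(roi)
  half <- voxel_size(roi) / 2
  for (s in seq_len(nrow(points) - 1)) {
    for (v in seq_len(nrow(centres))) {
      if (oracle_segment_box(points[s, ], points[s + 1, ],
                             centres[v, ] - half, centres[v, ] + half))
        return(TRUE)
    }
  }
  FALSE
}

## NNLS by exhaustive enumeration of all support sets: the optimum is the
## best feasible (all-non-negative) unconstrained LS fit over any support
oracle_nnls <- function(A, b) {
  p <- ncol(A)
  best_obj <- sum(b^2)
  best_x <- numeric(p)
  for (mask_int in seq_len(2^p) - 1L) {
    S <- which(bitwAnd(mask_int, 2^(seq_len(p) - 1)) > 0)
    if (length(S) == 0) next
    As <- A[, S, drop = FALSE]
    coef <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(coef) || any(coef < 0)) next
    obj <- sum((b - As %*% coef)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best_x <- numeric(p); best_x[S] <- coef
    }
  }
  list(x = best_x, objective = best_obj)
}

## textbook one-sample t-test
oracle_ttest <- function(values, mu0 = 0, confidence = 0.95) {
  n <- length(values)
  m <- mean(values); s <- sd(values)
  se <- s / sqrt(n)
  tstat <- (m - mu0) / se
  crit <- qt(1 - (1 - confidence) / 2, n - 1)
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1),
       ci = c(m - crit * se, m + crit * se))
}

## random rigid rotation matrix
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
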