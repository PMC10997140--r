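# LiFE model construction, non-negative solve, and streamline culling.

## tiny grid: 3x3x3 voxels of 2 mm centred on the origin
tiny_grid_affine <- function() {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-2, -2, -2)
  aff
}

test_that("a design column equals the demeaned stick profile of its voxel", {
  aff <- tiny_grid_affine()
  wm <- array(FALSE, c(3, 3, 3)); wm[2, 2, 2] <- TRUE
  mask <- binary_mask(wm, aff, name = "wm", hemisphere = "midline")
  gt <- default_gradient_table()
  sig <- volume_grid(array(1, c(3, 3, 3, 70)), aff)
  ## straight through the centre voxel along z
  s_in <- matrix(c(0, 0, -0.9, 0, 0, 0.9), 2, 3, byrow = TRUE)
  ## entirely outside the mask
  s_out <- matrix(c(-2, -2, -2.9, -2, -2, 2.9), 2, 3, byrow = TRUE)
  cand <- streamline_set(list(s_in, s_out, s_in))
  model <- build_life_model(cand, sig, gt, mask, d_ax = 1e-3)

  dw <- which(gt$bvalues > 50)
  att <- exp(-1000 * 1e-3 * (gt$directions[dw, ] %*% c(0, 0, 1))^2)
  expected_profile <- att - mean(att)
  col1 <- as.numeric(model$design[, 1])
  expect_true(max(abs(col1)) > 0)
  k <- sum(col1 * expected_profile) / sum(expected_profile^2)
  expect_lt(max(abs(col1 - k * expected_profile)), 1e-10)  # nodes x profile
  expect_equal(as.numeric(model$design[, 2]), rep(0, 64))  # outside mask
  expect_identical(model$design[, 1], model$design[, 3])   # identical twins
})

test_that("the NNLS solver handles textbook cases and respects KKT", {
  m1 <- structure(list(design = Matrix::Matrix(diag(3), sparse = TRUE),
                       target = c(1, 0, 2)), class = "life_model")
  r1 <- solve_weights(m1)
  expect_equal(r1$weights, c(1, 0, 2), tolerance = 1e-10)

  m2 <- structure(list(design = Matrix::Matrix(matrix(c(1, 1), 2, 1), sparse = TRUE),
                       target = c(1, -1)), class = "life_model")
  r2 <- solve_weights(m2)
  expect_equal(r2$weights, 0, tolerance = 1e-12)  # boundary KKT
  expect_equal(r2$rmse, 1, tolerance = 1e-12)
})

test_that("the solver matches exhaustive active-set enumeration on 20 x 5 problems", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      A <- matrix(runif(100), 20, 5)
      b <- rnorm(20)
      model <- structure(list(design = Matrix::Matrix(A, sparse = TRUE),
                              target = b), class = "life_model")
      fit <- solve_weights(model, max_iter = 20000, tol = 1e-13)
      oracle <- oracle_nnls(A, b)
      expect_true(all(fit$weights >= 0))
      obj <- sum((b - A %*% fit$weights)^2)
      expect_lt(abs(obj - oracle$objective), 1e-8)
    }
  })
})

test_that("the solver objective is non-increasing across sweeps", {
  withr::with_seed(8, {
    A <- matrix(runif(600), 60, 10)
    b <- rnorm(60)
  })
  model <- structure(list(design = Matrix::Matrix(A, sparse = TRUE), target = b),
                     class = "life_model")
  fit <- solve_weights(model)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("duplicating a candidate never increases error; duplicates share its weight", {
  withr::with_seed(5, {
    A <- matrix(runif(80), 20, 4)
    b <- as.numeric(A %*% c(1, 0.5, 0, 2)) + rnorm(20, sd = 0.01)
  })
  base <- structure(list(design = Matrix::Matrix(A, sparse = TRUE), target = b),
                    class = "life_model")
  dup <- structure(list(design = Matrix::Matrix(cbind(A, A[, 1]), sparse = TRUE),
                        target = b), class = "life_model")
  f1 <- solve_weights(base, tol = 1e-13)
  f2 <- solve_weights(dup, tol = 1e-13)
  e1 <- sum((b - A %*% f1$weights)^2)
  e2 <- sum((b - cbind(A, A[, 1]) %*% f2$weights)^2)
  expect_lte(e2, e1 + 1e-10)
  expect_equal(f2$weights[1] + f2$weights[5], f1$weights[1], tolerance = 1e-6)
})

test_that("culling keeps exactly the above-threshold streamlines", {
  s <- streamline_set(lapply(1:3, function(i) rbind(c(0, 0, 0), c(0, 0, i))))
  res <- structure(list(weights = c(0, 0.5, 0), rmse = 0,
                        kept_indices = 2L, converged = TRUE),
                   class = "life_result")
  out <- cull_streamlines(s, res, epsilon = 1e-8)
  expect_equal(n_streamlines(out), 1)
  expect_equal(out$meta$orig_index, 2L)
  expect_equal(out$meta$weight, 0.5)
  expect_warning(empty <- cull_streamlines(s, res, epsilon = 1), "empty")
  expect_equal(n_streamlines(empty), 0)
})

test_that("degenerate models are refused", {
  aff <- tiny_grid_affine()
  wm <- array(FALSE, c(3, 3, 3)); wm[2, 2, 2] <- TRUE
  mask <- binary_mask(wm, aff, name = "wm", hemisphere = "midline")
  gt <- default_gradient_table()
  sig <- volume_grid(array(1, c(3, 3, 3, 70)), aff)
  outside <- streamline_set(list(matrix(c(-2, -2, -2.9, -2, -2, 2.9),
                                        2, 3, byrow = TRUE)))
  expect_error(build_life_model(outside, sig, gt, mask), "degenerate")
  expect_error(build_life_model(streamline_set(list()), sig, gt, mask), "empty")
})

test_that("LiFE separates true streamlines from distractors on the phantom", {
  ph <- life_phantom()
  ## exactly-representable regime: unjittered true candidates
  cand <- generate_candidates(ph, n_true = 100, n_spurious = 100, seed = 3,
                              jitter_sd = 0)
  model <- build_life_model(cand, ph$signal, ph$gtab, ph$wm_mask)
  res <- solve_weights(model)
  w <- res$weights
  truth <- cand$meta$truth_valid
  eps <- 1e-8 * max(w)
  expect_gte(mean(w[!truth] <= eps), 0.95)   # distractors zero-weighted
  expect_gte(mean(w[truth] > eps), 0.90)     # true streamlines kept
  expect_lt(res$rmse, 1e-6)                  # signal fully explained

  culled <- cull_streamlines(cand, res)
  expect_true(all(culled$meta$weight > eps))
  ## culling removed only ~zero-weight columns: prediction unchanged
  pred_full <- as.numeric(model$design %*% w)
  w_culled <- numeric(length(w)); w_culled[culled$meta$orig_index] <-
    culled$meta$weight
  pred_culled <- as.numeric(model$design %*% w_culled)
  expect_lt(max(abs(pred_full - pred_culled)), 1e-8)

  ## realistic regime: jittered candidates still keep the distractor weight
  ## share low while retaining the true set
  cand2 <- generate_candidates(ph, n_true = 100, n_spurious = 100, seed = 3)
  res2 <- solve_weights(build_life_model(cand2, ph$signal, ph$gtab, ph$wm_mask))
  w2 <- res2$weights; truth2 <- cand2$meta$truth_valid
  expect_lt(sum(w2[!truth2]) / sum(w2), 0.05)
  expect_gte(mean(w2[truth2] > 1e-8 * max(w2)), 0.90)
})
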