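# Ground-truth phantom generation, signal simulation, candidate sets.

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(bundles = default_bundles(n_streamlines = 8), seed = 7)
  a <- generate_phantom(spec, check = FALSE)
  b <- generate_phantom(spec, check = FALSE)
  expect_identical(a$truth_streamlines$streamlines, b$truth_streamlines$streamlines)
  expect_identical(a$signal$data, b$signal$data)
  expect_identical(a$orientation_field$sticks, b$orientation_field$sticks)
  ca <- generate_candidates(a, 50, 50, seed = 2)
  cb <- generate_candidates(b, 50, 50, seed = 2)
  expect_identical(ca$streamlines, cb$streamlines)
  expect_identical(ca$meta, cb$meta)
})

test_that("truth labels partition the streamlines across the seven bundles", {
  ph <- test_phantom()
  labs <- ph$truth_streamlines$meta$label
  expect_equal(n_streamlines(ph$truth_streamlines), 7 * 30)
  expect_equal(sort(unique(labs)),
               sort(c("SLF_I", "SLF_II", "SLF_III", "CINGULUM", "CALLOSAL",
                      "AF", "CST")))
  expect_true(all(table(labs) == 30))
})

test_that("every truth streamline crosses its own ROIs and no other bundle's", {
  ph <- test_phantom()
  defs <- ph$tract_definitions
  ## exhaustive check against the geometric oracle on a subsample per bundle
  withr::with_seed(5, idx <- unlist(tapply(
    seq_len(210), ph$truth_streamlines$meta$label, sample, size = 6)))
  for (q in idx) {
    p <- ph$truth_streamlines$streamlines[[q]]
    lab <- ph$truth_streamlines$meta$label[q]
    own <- defs$required_rois[[match(lab, defs$name)]]
    for (rn in names(ph$waypoint_rois)) {
      hit <- oracle_passes_roi(p, ph$waypoint_rois[[rn]])
      expect_identical(hit, rn %in% own,
                       label = paste(lab, "streamline vs ROI", rn))
    }
  }
})

test_that("CST streamlines cross both of their ROIs; cingulum crosses neither", {
  ph <- test_phantom()
  cst <- which(ph$truth_streamlines$meta$label == "CST")
  cing <- which(ph$truth_streamlines$meta$label == "CINGULUM")
  for (q in cst) {
    p <- ph$truth_streamlines$streamlines[[q]]
    expect_true(passes_roi(p, ph$waypoint_rois$CST_inferior))
    expect_true(passes_roi(p, ph$waypoint_rois$CST_superior))
  }
  for (q in cing) {
    p <- ph$truth_streamlines$streamlines[[q]]
    expect_false(passes_roi(p, ph$waypoint_rois$CST_inferior))
    expect_false(passes_roi(p, ph$waypoint_rois$CST_superior))
  }
})

test_that("waypoint ROIs of different bundles stay separated; overlap errors", {
  ph <- test_phantom()
  expect_gt(roi_separation(ph), 2 * ph$spec$voxel_size)
  ## two bundles drawn on top of each other must be refused
  clash <- list(
    bundle_spec("SLF_I", rbind(c(-20, -30, 20), c(-20, 30, 20)), n_streamlines = 5),
    bundle_spec("SLF_II", rbind(c(-18, -30, 20), c(-18, 30, 20)), n_streamlines = 5))
  expect_error(generate_phantom(phantom_spec(bundles = clash, seed = 1)),
               "2 voxel widths")
})

test_that("rerouted streamlines terminate within the selection distance of CSv", {
  ph <- test_phantom()
  truth <- ph$truth_streamlines
  csv_left <- ph$csv_masks$left
  d <- vapply(truth$streamlines, endpoint_distance, numeric(1), mask = csv_left)
  expect_true(all(d[truth$meta$csv_true] <= 3))
  expect_true(all(d[!truth$meta$csv_true] > 3))
  expect_equal(sum(truth$meta$csv_true), 7 * round(0.3 * 30))
})

test_that("stick forward model matches its closed form and symmetries", {
  ## one straight bundle along z, no free water inside: the densest voxel
  ## carries total stick fraction 1 so S(g || t) = S0 exp(-b d_ax),
  ## S(g perp t) = S0
  b <- bundle_spec("CST", rbind(c(0, 0, -20), c(0, 0, 20)),
                   n_streamlines = 30, csv_fraction = 0,
                   roi_stations = c(0.3, 0.6))
  gt <- gradient_table(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
                       c(0, 1000, 1000))
  spec <- phantom_spec(grid_shape = c(21, 21, 41), bundles = list(b),
                       csv_centres = list(left = c(-10, 0, 0)),
                       f_iso_wm = 0, S0 = 1, seed = 2, csv_target = "left")
  ph <- generate_phantom(spec, gtab = gt, check = FALSE)
  st <- ph$orientation_field$sticks
  dens <- aggregate(st$f, by = list(i = st$i, j = st$j, k = st$k), FUN = sum)
  top <- dens[which.max(dens$x), ]
  expect_equal(top$x, 1, tolerance = 1e-12)     # densest voxel: all stick
  svox <- ph$signal$data[top$i + 1, top$j + 1, top$k + 1, ]
  ## sticks in this voxel all point along z (+/- jitter): closed form
  expect_equal(svox[1], 1, tolerance = 1e-12)                  # b = 0
  expect_equal(svox[2], exp(-1), tolerance = 0.02)             # parallel
  expect_equal(svox[3], 1, tolerance = 0.02)                   # orthogonal
  ## isotropic voxel: identical attenuation in every direction
  iso <- ph$signal$data[2, 2, 2, ]
  expect_equal(iso[2], iso[3], tolerance = 1e-12)
  expect_equal(iso[2], exp(-3), tolerance = 1e-12)             # free water
})

test_that("snr = Inf reproduces the closed-form prediction; noise is seeded Rician", {
  ph <- test_phantom()
  clean1 <- simulate_dwi(ph, ph$gtab, snr = Inf)
  clean2 <- simulate_dwi(ph, ph$gtab, snr = Inf)
  expect_identical(clean1$data, clean2$data)
  noisy1 <- simulate_dwi(ph, ph$gtab, snr = 20, seed = 4)
  noisy2 <- simulate_dwi(ph, ph$gtab, snr = 20, seed = 4)
  noisy3 <- simulate_dwi(ph, ph$gtab, snr = 20, seed = 5)
  expect_identical(noisy1$data, noisy2$data)
  expect_false(identical(noisy1$data, noisy3$data))
  expect_true(all(noisy1$data >= 0))            # Rician magnitudes
  ## in the high-SNR regime (b = 0 volumes, S = S0 everywhere) the Rician
  ## magnitude noise is approximately Gaussian with sd = S0/snr
  resid_b0 <- noisy1$data[, , , 1] - clean1$data[, , , 1]
  expect_equal(sd(resid_b0), ph$spec$S0 / 20, tolerance = 0.05)
})

test_that("fractions must sum to one for signal simulation", {
  ph <- test_phantom()
  broken <- ph
  broken$orientation_field$sticks$f <- broken$orientation_field$sticks$f * 2
  expect_error(simulate_dwi(broken, ph$gtab), "sum to 1")
})

test_that("candidate sets respect counts, bounds and provenance batches", {
  ph <- test_phantom()
  expect_equal(n_streamlines(generate_candidates(ph, 0, 0, seed = 1)), 0)
  cand <- generate_candidates(ph, 200, 200, seed = 1)
  expect_equal(n_streamlines(cand), 400)
  len <- arc_lengths(cand)
  expect_true(all(len >= 4 & len <= 250))
  pc <- provenance_counts(cand)
  expect_equal(nrow(pc), 4)
  expect_equal(sum(pc$n), 400)
})

test_that("spurious candidates are orientation-decorrelated from the field", {
  ph <- test_phantom()
  cand <- generate_candidates(ph, 150, 150, seed = 2)
  ## per-voxel reference orientation: first stick direction
  st <- ph$orientation_field$sticks
  key <- paste(st$i, st$j, st$k)
  first <- !duplicated(key)
  ref <- new.env(parent = emptyenv())
  for (r in which(first))
    assign(key[r], c(st$vx[r], st$vy[r], st$vz[r]), envir = ref)
  mean_abs_cos <- function(p) {
    ijk <- world_to_voxel(ph$grid, p)
    d <- diff(p); d <- d / sqrt(rowSums(d^2))
    vals <- c()
    for (s in seq_len(nrow(d))) {
      k <- paste(ijk[s, 1], ijk[s, 2], ijk[s, 3])
      v <- ref[[k]]
      if (!is.null(v)) vals <- c(vals, abs(sum(d[s, ] * v)))
    }
    if (length(vals)) mean(vals) else NA_real_
  }
  scores <- vapply(cand$streamlines, mean_abs_cos, numeric(1))
  true_score <- mean(scores[cand$meta$truth_valid], na.rm = TRUE)
  spur_score <- mean(scores[!cand$meta$truth_valid], na.rm = TRUE)
  ## true candidates track the field (jitter and CSv-reroute tails keep the
  ## mean below 1); spurious walks sit far lower
  expect_gt(true_score, 0.85)
  expect_lt(spur_score, true_score - 0.3)
})
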