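# Tract proportions, one-sample t-tests, Bonferroni, group summaries.

test_that("one-sample t matches the textbook formula", {
  r <- one_sample_ttest(c(0.1, 0.2, 0.3))
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)  # 3.4641
  expect_equal(round(r$t, 4), 3.4641)
  expect_equal(r$df, 2)
  withr::with_seed(40, {
    for (rep in 1:20) {
      x <- rnorm(sample(3:15, 1), mean = runif(1), sd = runif(1, 0.01, 1))
      mu0 <- rnorm(1, sd = 0.2)
      got <- one_sample_ttest(x, mu0 = mu0)
      want <- oracle_ttest(x, mu0 = mu0)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      expect_equal(c(got$ci_low, got$ci_high), want$ci, tolerance = 1e-10)
    }
  })
})

test_that("zero-variance samples yield test-not-performed with a reason", {
  r0 <- one_sample_ttest(rep(0, 12))
  expect_false(r0$tested)
  expect_match(r0$reason, "zero")
  rc <- one_sample_ttest(rep(0.2, 5))
  expect_false(rc$tested)
  expect_equal(rc$sem, 0)
  expect_error(one_sample_ttest(0.5), "at least 2")
})

test_that("CI reconstruction identity holds: mean +/- t_crit * SEM = CI and t * SEM = mean - mu0", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      x <- rnorm(12, mean = 0.1, sd = 0.05)
      r <- one_sample_ttest(x)
      crit <- qt(0.975, r$df)
      expect_equal(c(r$mean - crit * r$sem, r$mean + crit * r$sem),
                   c(r$ci_low, r$ci_high), tolerance = 1e-10)
      expect_equal(r$t * r$sem, r$mean, tolerance = 1e-10)
    }
  })
})

test_that("Bonferroni thresholds follow family_alpha / m", {
  expect_equal(bonferroni_alpha(0.05, 7), 0.05 / 7)
  expect_equal(reported_alpha(0.05, 7), 0.007)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
})

## build a classification result directly from counts
counts_classification <- function(counts_df, n_input = sum(counts_df$n)) {
  structure(list(labels = NULL, counts = counts_df,
                 overlap_log = tibble::tibble(), mode = "exclusive",
                 n_input = n_input), class = "csv_classification")
}

test_that("tract proportions are count ratios; zero totals flag degeneracy", {
  counts <- tibble::tibble(
    hemisphere = "left",
    tract = c("SLF_I", "CINGULUM", "UNCATEGORISED"),
    n = c(10L, 5L, 85L))
  p <- tract_proportions(counts_classification(counts), "S01")
  expect_equal(p$proportion, c(0.10, 0.05, 0.85))
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
  expect_false(any(p$degenerate))

  zero <- tibble::tibble(hemisphere = "right",
                         tract = c("SLF_I", "UNCATEGORISED"), n = c(0L, 0L))
  pz <- tract_proportions(counts_classification(zero), "S01")
  expect_true(all(pz$degenerate))
  expect_true(all(pz$proportion == 0))
})

test_that("phantom proportions match by-construction counts exactly", {
  ph <- test_phantom()
  sel <- select_csv_streamlines(ph$truth_streamlines, ph$csv_masks,
                                selection_config(3))
  cls <- classify_set(sel, ph$tract_definitions, ph$waypoint_rois)
  p <- tract_proportions(cls, "S01", hemisphere = "left")
  ## 9 of 63 selected per bundle: uniform proportions 9/63
  expect_equal(p$proportion[p$tract == "SLF_I"], 9 / 63, tolerance = 1e-12)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
})

## simulated multi-subject proportions table
simulate_props <- function(n_subj = 12, slf1_mean = 0.1, slf1_sd = 0.03,
                           seed = 5) {
  tracts <- c("SLF_I", "CINGULUM", "AF")
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subj)) for (h in c("left", "right")) {
      slf <- max(0, rnorm(1, slf1_mean, slf1_sd))
      cing <- max(0, rnorm(1, 0.05, 0.04))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("S%02d", s), hemisphere = h,
        tract = c(tracts, "UNCATEGORISED"),
        n = c(round(100 * slf), round(100 * cing), 0L, 100L),
        proportion = c(slf, cing, 0, 1 - slf - cing))
    }
    dplyr::bind_rows(rows)
  })
}

test_that("group summary finds a strong effect and reports untestable cells", {
  props <- simulate_props()
  g <- summarize_group(props, family_alpha = 0.05, m_tests = 7)
  slf_l <- g[g$tract == "SLF_I" & g$hemisphere == "left", ]
  expect_true(slf_l$tested)
  expect_true(slf_l$significant)       # d ~ 3.3: power >> 99.9%
  expect_equal(slf_l$df, 11)
  af <- g[g$tract == "AF", ]
  expect_false(any(af$tested))
  expect_match(af$reason[1], "zero")
  expect_false(any(af$significant))
  expect_equal(attr(g, "alpha_per_test"), 0.05 / 7)
  ## presence bookkeeping: AF never present, SLF_I in every hemisphere
  expect_equal(unique(g$presence_n[g$tract == "SLF_I"]), 24L)
  expect_equal(unique(g$presence_k[g$tract == "AF"]), 0L)
  expect_gt(unique(g$presence_k[g$tract == "SLF_I"]), 20L)
})

test_that("constant proportions give SEM 0 and no test", {
  props <- simulate_props(n_subj = 4)
  props$proportion[props$tract == "CINGULUM"] <- 0.2
  props$n[props$tract == "CINGULUM"] <- 20L
  g <- summarize_group(props)
  cing <- g[g$tract == "CINGULUM", ]
  expect_true(all(cing$sem == 0))
  expect_false(any(cing$tested))
})

test_that("group summary validates its inputs", {
  props <- simulate_props(n_subj = 3)
  expect_error(summarize_group(props[0, ]), "at least 2|columns")
  uneven <- props[!(props$subject_id == "S03" & props$hemisphere == "right"), ]
  expect_error(summarize_group(uneven), "mismatched hemisphere")
})

test_that("rejection rate under the null matches alpha (Monte-Carlo)", {
  alpha <- 0.05
  withr::with_seed(44, {
    rejections <- vapply(seq_len(2000), function(i) {
      x <- rnorm(12, mean = 0.05, sd = 0.02)
      r <- one_sample_ttest(x, mu0 = 0.05)
      r$p < alpha
    }, logical(1))
  })
  rate <- mean(rejections)
  mc_err <- 3 * sqrt(alpha * (1 - alpha) / 2000)
  expect_lt(abs(rate - alpha), mc_err)
})

test_that("tidy and glance expose the summary as plain tibbles", {
  g <- summarize_group(simulate_props())
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("tract", "hemisphere", "mean_proportion", "sem", "t",
                    "p", "tested", "significant") %in% names(td)))
  gl <- glance(g)
  expect_equal(gl$m_tests, 7)
  expect_equal(gl$alpha_per_test, 0.05 / 7)
  expect_equal(gl$n_cells, nrow(g))
})
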