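#' Per-subject tract proportions
#'
#' For each hemisphere, the proportion of CSv streamlines assigned to each
#' tract (plus `UNCATEGORISED`): tract count divided by the hemisphere's
#' total CSv streamline count. In exclusive classification mode the
#' proportions sum to 1. A hemisphere with zero CSv streamlines is flagged
#' degenerate with all proportions 0.
#'
#' @param classification a [classify_set()] result
#' @param subject_id subject identifier string
#' @param hemisphere optional filter (`"left"`/`"right"`)
#' @return tibble: subject_id, hemisphere, tract, n, n_csv_streamlines,
#'   proportion, degenerate.
#' @export
tract_proportions <- function(classification, subject_id,
                              hemisphere = NULL) {
  stopifnot(inherits(classification, "csv_classification"))
  counts <- classification$counts
  if (!is.null(hemisphere))
    counts <- dplyr::filter(counts, .data$hemisphere %in% !!hemisphere)
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$hemisphere),
    n_csv_streamlines = sum(.data$n),
    proportion = ifelse(.data$n_csv_streamlines > 0,
                        .data$n / .data$n_csv_streamlines, 0),
    degenerate = .data$n_csv_streamlines == 0)
  out <- dplyr::ungroup(out)
  dplyr::bind_cols(tibble::tibble(subject_id = subject_id, .rows = nrow(out)),
                   out)
}

#' One-sample t-test with explicit zero-variance handling
#'
#' Two-sided one-sample t-test of the mean against `mu0`, with a two-sided
#' confidence interval (delegated to [stats::t.test()]). Samples with zero
#' variance — including the all-zero case that arises when no subject has
#' any streamline in a tract — yield a test-not-performed result with a
#' reason instead of an error, mirroring how untestable tract/hemisphere
#' cells are reported rather than dropped.
#'
#' @param values numeric sample (n >= 2)
#' @param mu0 null-hypothesis mean (default 0)
#' @param confidence confidence level for the CI (default 0.95)
#' @return one-row tibble: n, mean, sd, sem, t, df, ci_low, ci_high, p,
#'   tested, reason.
#' @export
one_sample_ttest <- function(values, mu0 = 0, confidence = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  base <- tibble::tibble(n = n, mean = m, sd = s, sem = s / sqrt(n),
                         t = NA_real_, df = n - 1L, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_, tested = FALSE,
                         reason = NA_character_)
  if (s == 0) {
    base$reason <- if (all(values == 0)) "all values zero" else "zero variance"
    return(base)
  }
  tt <- stats::t.test(values, mu = mu0, conf.level = confidence)
  base$t <- unname(tt$statistic)
  base$df <- unname(tt$parameter)
  base$ci_low <- tt$conf.int[1]
  base$ci_high <- tt$conf.int[2]
  base$p <- tt$p.value
  base$tested <- TRUE
  base$reason <- NA_character_
  base
}

#' Bonferroni-corrected per-test alpha
#'
#' `family_alpha / m`; with a 0.05 family level over the seven candidate
#' tracts this gives 0.00714..., conventionally reported as 0.007.
#'
#' @param family_alpha family-wise error rate (0 < alpha < 1)
#' @param m number of tests (>= 1)
#' @return scalar per-test alpha (unrounded; see `reported_alpha()`)
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(family_alpha > 0, family_alpha < 1, m >= 1)
  family_alpha / m
}

#' @rdname bonferroni_alpha
#' @export
reported_alpha <- function(family_alpha, m) round(bonferroni_alpha(family_alpha, m), 3)

#' Across-subject group statistics on tract proportions
#'
#' For every tract x hemisphere cell: mean proportion, SEM (sd/sqrt(n),
#' n - 1 denominator in sd), a two-sided one-sample t-test against zero,
#' and significance at the Bonferroni-corrected level
#' `bonferroni_alpha(family_alpha, m_tests)`. Zero-variance cells are
#' reported untested. `presence_k`/`presence_n` count, per tract, the
#' subject-hemispheres in which at least one streamline was assigned to
#' the tract (the "k/N hemispheres" style of reporting).
#'
#' @param props row-bound [tract_proportions()] tibbles across subjects
#' @param family_alpha family-wise error rate (default 0.05)
#' @param m_tests number of tracts in the Bonferroni family (default 7)
#' @param confidence CI level (default 0.95)
#' @param mu0 null mean (default 0)
#' @return An object of class `csv_group_stats` (a tibble): tract,
#'   hemisphere, n_subjects, mean, sem, t, df, ci_low, ci_high, p, tested,
#'   reason, significant, presence_k, presence_n; attributes
#'   `alpha_per_test`, `family_alpha`, `m_tests`.
#' @export
summarize_group <- function(props, family_alpha = 0.05, m_tests = 7,
                            confidence = 0.95, mu0 = 0) {
  needed <- c("subject_id", "hemisphere", "tract", "n", "proportion")
  if (!all(needed %in% names(props)))
    stop("props must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  tab <- dplyr::distinct(props[, c("subject_id", "hemisphere")])
  per_h <- dplyr::count(tab, .data$hemisphere)
  if (any(per_h$n < 2))
    stop("need at least 2 subjects per hemisphere", call. = FALSE)
  if (length(unique(per_h$n)) > 1)
    stop("mismatched hemisphere coverage across subjects", call. = FALSE)
  tracts <- setdiff(unique(props$tract), "UNCATEGORISED")

  presence <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(props, .data$tract %in% tracts), .data$tract),
    presence_k = sum(.data$n >= 1), presence_n = dplyr::n(),
    .groups = "drop")

  cells <- dplyr::group_by(
    dplyr::filter(props, .data$tract %in% tracts),
    .data$tract, .data$hemisphere)
  stats_tbl <- dplyr::reframe(cells,
    n_subjects = dplyr::n(),
    one_sample_ttest(.data$proportion, mu0 = mu0, confidence = confidence))
  alpha <- bonferroni_alpha(family_alpha, m_tests)
  out <- dplyr::mutate(stats_tbl,
    significant = .data$tested & !is.na(.data$p) & .data$p < alpha)
  out <- dplyr::left_join(out, presence, by = "tract")
  out <- dplyr::rename(out, mean_proportion = "mean")
  out <- tibble::new_tibble(out, class = "csv_group_stats",
                            alpha_per_test = alpha,
                            family_alpha = family_alpha, m_tests = m_tests)
  out
}

#' @rdname summarize_group
#' @param x a `csv_group_stats`
#' @param ... unused
#' @method tidy csv_group_stats
#' @export
tidy.csv_group_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname summarize_group
#' @method glance csv_group_stats
#' @export
glance.csv_group_stats <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_tested = sum(x$tested),
    n_significant = sum(x$significant),
    family_alpha = attr(x, "family_alpha"),
    m_tests = attr(x, "m_tests"),
    alpha_per_test = attr(x, "alpha_per_test"))
}
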