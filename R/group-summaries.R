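#' Cell means and SDs per group x condition x timepoint
#'
#' The descriptive table of the crossover design: one row per populated cell
#' with the number of contributing participants, mean, and SD (n - 1
#' denominator; `NA` for single-participant cells).
#'
#' @param data A [study_dataset()].
#' @param outcome Measurement column to summarise (e.g. `"csbp"`, `"bsbp"`,
#'   `"bdbp"`, `"hr"`, `"cfpwv"`).
#' @return Tibble: `group`, `condition`, `timepoint`, `outcome`, `n`,
#'   `mean`, `sd`.
#' @export
cell_summaries <- function(data, outcome = "csbp") {
  validate_study_dataset(data)
  if (!outcome %in% names(data$measurements)) {
    stop_schema(sprintf("unknown outcome column '%s'", outcome))
  }
  joined <- dplyr::left_join(data$measurements, data$participants,
                             by = "participant_id")
  joined <- joined[!is.na(joined[[outcome]]), ]
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$group, .data$condition, .data$timepoint),
    n = dplyr::n(),
    mean = mean(.data[[outcome]]),
    sd = if (dplyr::n() > 1) sd(.data[[outcome]]) else NA_real_,
    .groups = "drop"
  )
  out$timepoint <- factor(out$timepoint, levels = TIMEPOINTS)
  out <- dplyr::arrange(out, .data$group, .data$condition, .data$timepoint)
  out$timepoint <- as.character(out$timepoint)
  tibble::add_column(out, outcome = outcome, .after = "timepoint")
}

#' Marginal-mean contrast between two timepoints within a group
#'
#' Estimates the within-participant change between two timepoints,
#' marginalised over exercise intensity: each participant's change
#' (`timepoint_b - timepoint_a`) is first averaged over their available
#' conditions, then averaged over participants. The 95% CI comes from the t
#' distribution on the per-participant differences. For balanced, complete
#' crossover data this equals the marginal-mean contrast of a random-
#' intercept mixed model; with missing sessions it is the documented
#' approximation. Hedges' g standardises the estimate by the pooled SD of
#' the two cells being contrasted.
#'
#' @param data A [study_dataset()].
#' @param outcome Measurement column.
#' @param group `"CAD"` or `"CON"`.
#' @param timepoint_a,timepoint_b Timepoints; the contrast is b minus a
#'   (e.g. `"PRE"` and `"P30"` for the 30-min change from baseline).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `group`, `outcome`, `contrast`, `estimate`,
#'   `ci_lower`, `ci_upper`, `hedges_g`, `n_pairs`.
#' @export
marginal_contrast <- function(data, outcome, group = GROUPS,
                              timepoint_a = "PRE", timepoint_b = "P30",
                              conf_level = 0.95) {
  group <- match.arg(group)
  validate_study_dataset(data)
  ids <- data$participants$participant_id[data$participants$group == group]
  m <- data$measurements[data$measurements$participant_id %in% ids, ]

  wide <- tidyr::pivot_wider(
    m[m$timepoint %in% c(timepoint_a, timepoint_b),
      c("participant_id", "condition", "timepoint", outcome)],
    names_from = "timepoint", values_from = dplyr::all_of(outcome)
  )
  wide$diff <- wide[[timepoint_b]] - wide[[timepoint_a]]
  per_part <- dplyr::summarise(
    dplyr::group_by(wide[!is.na(wide$diff), ], .data$participant_id),
    diff = mean(.data$diff), .groups = "drop"
  )
  n_pairs <- nrow(per_part)
  if (n_pairs < 2) stop_domain("marginal_contrast needs at least 2 complete pairs")

  est <- mean(per_part$diff)
  se <- sd(per_part$diff) / sqrt(n_pairs)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n_pairs - 1)

  # Pooled SD of the two cells being contrasted (n - 1 weighting), pooled
  # over conditions, for the standardised effect size.
  va <- m[[outcome]][m$timepoint == timepoint_a]
  vb <- m[[outcome]][m$timepoint == timepoint_b]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  g <- if (length(va) > 1 && length(vb) > 1) {
    pooled <- sqrt(((length(va) - 1) * sd(va)^2 + (length(vb) - 1) * sd(vb)^2) /
                     (length(va) + length(vb) - 2))
    if (pooled > 0) hedges_g(est, pooled, length(va), length(vb)) else NA_real_
  } else NA_real_

  tibble::tibble(
    group = group, outcome = outcome,
    contrast = sprintf("d_%s-%s", timepoint_b, timepoint_a),
    estimate = est, ci_lower = est - tcrit * se, ci_upper = est + tcrit * se,
    hedges_g = g, n_pairs = n_pairs
  )
}

#' Hedges' g standardised mean difference
#'
#' Mean contrast divided by the pooled SD, with the small-sample bias
#' correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param contrast Mean contrast, outcome units.
#' @param pooled_sd Pooled SD of the two cells, outcome units (> 0).
#' @param n1,n2 Cell sizes.
#' @return Unitless effect size.
#' @export
#' @examples
#' hedges_g(5, 10, 17, 18) # 0.4886
hedges_g <- function(contrast, pooled_sd, n1, n2) {
  if (pooled_sd <= 0) stop_domain("pooled SD must be positive")
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  contrast / pooled_sd * j
}

#' Welch two-sample comparison
#'
#' Unequal-variance t test (Welch statistic, Satterthwaite df) between two
#' independent samples, as used for baseline between-group comparisons.
#' Thin wrapper over [stats::t.test()] returning a tidy one-row tibble.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `difference` (mean a minus mean b), `ci_lower`,
#'   `ci_upper`, `t`, `df`, `p`.
#' @export
welch_test <- function(sample_a, sample_b, conf_level = 0.95) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_domain("welch_test needs at least 2 values per sample")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    stop_domain("both samples have zero variance")
  }
  fit <- t.test(sample_a, sample_b, var.equal = FALSE,
                conf.level = conf_level)
  tibble::tibble(
    difference = unname(fit$estimate[1] - fit$estimate[2]),
    ci_lower = fit$conf.int[1], ci_upper = fit$conf.int[2],
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value
  )
}
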