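#' Region of practical equivalence from a baseline SD
#'
#' The ROPE is the symmetric null band around zero change inside which a
#' post-exercise delta is considered practically equivalent to no response:
#' plus/minus a fraction (default 20%) of the group's baseline standard
#' deviation, the smallest worthwhile change convention.
#'
#' @param baseline_sd Baseline between-participant SD of the outcome, mmHg.
#' @param fraction Multiplier applied to the SD (default 0.2). Must be > 0:
#'   a zero-width null region is degenerate and rejected.
#' @return One-row tibble: `lower`, `upper` (mmHg, `lower == -upper`),
#'   `fraction`, `source_sd`.
#' @export
#' @examples
#' rope_from_sd(18) # +/- 3.6 mmHg
rope_from_sd <- function(baseline_sd, fraction = 0.2) {
  if (baseline_sd <= 0) stop_domain("baseline SD must be positive")
  if (fraction <= 0) stop_domain("ROPE fraction must be positive")
  half <- fraction * baseline_sd
  tibble::tibble(lower = -half, upper = half,
                 fraction = fraction, source_sd = baseline_sd)
}

#' Specify a participant's posterior change distribution
#'
#' The "posterior" here is a measurement-error distribution around the
#' observed delta: Normal(location = observed change, scale = technical error
#' times sqrt(2), the SD of a difference of two equally noisy measurements).
#' No prior updating is involved.
#'
#' @param location Observed post-exercise change, mmHg.
#' @param scale Posterior SD, mmHg (technical error x sqrt(2)); must be > 0.
#' @param n_draws Number of Monte Carlo draws (default 1000; minimum 100).
#' @param hdi_mass Credible mass of the highest-density interval
#'   (default 0.89).
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `posterior_spec`.
#' @export
posterior_spec <- function(location, scale, n_draws = 1000,
                           hdi_mass = 0.89, seed = 1L) {
  if (!is.finite(scale) || scale <= 0) {
    stop_domain("posterior scale must be positive")
  }
  if (n_draws < 100) stop_domain("n_draws must be at least 100")
  if (hdi_mass <= 0 || hdi_mass >= 1) {
    stop_domain("hdi_mass must lie strictly between 0 and 1")
  }
  structure(list(location = location, scale = scale,
                 n_draws = as.integer(n_draws), hdi_mass = hdi_mass,
                 seed = as.integer(seed)),
            class = "posterior_spec")
}

#' Draw from a posterior change distribution
#'
#' @param spec A [posterior_spec()].
#' @return Numeric vector of `n_draws` values from
#'   Normal(location, scale), identical for identical seeds. The global RNG
#'   state is left untouched.
#' @export
draw_posterior <- function(spec) {
  stopifnot(inherits(spec, "posterior_spec"))
  withr::with_seed(spec$seed,
                   rnorm(spec$n_draws, mean = spec$location, sd = spec$scale))
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval of sorted draws containing the requested
#' mass: among all windows of `ceiling(mass * n)` consecutive order
#' statistics, the one of minimal width (ties broken by the lowest start
#' index). For a unimodal posterior this estimates the highest-density
#' credible interval.
#'
#' @param sample Numeric vector of at least 10 draws.
#' @param mass Credible mass in (0, 1), default 0.89.
#' @return One-row tibble: `lower`, `upper`, `mass`.
#' @export
#' @examples
#' hdi(1:10, mass = 0.5) # window of 5 draws: [1, 5]
hdi <- function(sample, mass = 0.89) {
  n <- length(sample)
  if (n < 10) stop_domain("hdi needs a sample of at least 10 draws")
  if (mass <= 0 || mass >= 1) stop_domain("mass must lie in (0, 1)")
  s <- sort(sample)
  k <- ceiling(mass * n)
  widths <- s[k:n] - s[seq_len(n - k + 1)]
  i <- which.min(widths) # which.min returns the first minimum: lowest start
  tibble::tibble(lower = s[i], upper = s[i + k - 1], mass = mass)
}

#' Fraction of HDI draws inside the ROPE
#'
#' Proportion of the draws that fall inside the HDI which also fall inside
#' the ROPE — the decision statistic of the equivalence rule.
#'
#' @param sample Posterior draws.
#' @param hdi One-row tibble from [hdi()] computed from `sample`.
#' @param rope One-row tibble from [rope_from_sd()] (or with `lower`/`upper`
#'   columns).
#' @return Fraction in `[0, 1]`.
#' @export
pct_hdi_in_rope <- function(sample, hdi, rope) {
  in_hdi <- sample >= hdi$lower & sample <= hdi$upper
  if (!any(in_hdi)) return(0)
  mean(sample[in_hdi] >= rope$lower & sample[in_hdi] <= rope$upper)
}

#' Classify one participant from the ROPE decision statistic
#'
#' More than `upper_thr` of the HDI inside the ROPE: the change is
#' practically null (non-responder). Less than `lower_thr`: a decisive
#' response, hypotensive or hypertensive by the sign of the delta. Anything
#' in between is undecided.
#'
#' @param pct Fraction of the HDI inside the ROPE.
#' @param delta Observed change, mmHg (sets the response direction).
#' @param upper_thr,lower_thr Decision thresholds (defaults 0.99 and 0.01);
#'   the undecided band `[lower_thr, upper_thr]` is inclusive.
#' @return One of `"HYPOTENSIVE_RESPONDER"`, `"HYPERTENSIVE_RESPONDER"`,
#'   `"NON_RESPONDER"`, `"UNDECIDED"`.
#' @export
classify_responder <- function(pct, delta, upper_thr = 0.99,
                               lower_thr = 0.01) {
  if (pct < 0 || pct > 1) stop_domain("pct must lie in [0, 1]")
  if (pct > upper_thr) return("NON_RESPONDER")
  if (pct < lower_thr) {
    if (delta == 0) {
      stop_integrity("decisive response with zero delta is contradictory")
    }
    return(if (delta < 0) "HYPOTENSIVE_RESPONDER" else "HYPERTENSIVE_RESPONDER")
  }
  "UNDECIDED"
}

#' Configuration of the responder-classification pipeline
#'
#' @param rope_fraction ROPE half-width as a fraction of the group baseline
#'   SD (default 0.2).
#' @param hdi_mass Credible mass of the HDI (default 0.89).
#' @param n_draws Posterior draws per participant (default 1000).
#' @param upper_thr,lower_thr Decision thresholds on the fraction of HDI
#'   inside the ROPE (defaults 0.99 / 0.01).
#' @param cv_source `"group"` to use the fixed per-group CVs in `group_cv`,
#'   or `"individual"` to use per-participant CVs estimated from duplicate
#'   measurements (supplied to [classify_cohort()] as `cv_table`).
#' @param group_cv Named CV fractions per group (defaults: CAD 5%, CON 4%,
#'   the duplicate-tonometry CVs of the two study groups).
#' @param delta_timepoints Post-exercise timepoints pooled into the delta
#'   (default 15 and 30 min).
#' @param delta_method `"mean"` pools the per-timepoint changes into one
#'   delta per participant; `"per_timepoint"` classifies each timepoint
#'   separately.
#' @param rope_override Optional named numeric vector of ROPE half-widths
#'   (mmHg) per group, bypassing the SD computation (the published bounds can
#'   be imposed directly, e.g. `c(CAD = 3.60, CON = 3.20)`).
#' @param pct_scope `"hdi"` computes the decision statistic over draws inside
#'   the HDI (the decision rule as stated); `"posterior"` uses all draws, for
#'   sensitivity analysis.
#' @return A list of class `responder_config`.
#' @export
responder_config <- function(rope_fraction = 0.2,
                             hdi_mass = 0.89,
                             n_draws = 1000,
                             upper_thr = 0.99,
                             lower_thr = 0.01,
                             cv_source = c("group", "individual"),
                             group_cv = c(CAD = 0.05, CON = 0.04),
                             delta_timepoints = c("P15", "P30"),
                             delta_method = c("mean", "per_timepoint"),
                             rope_override = NULL,
                             pct_scope = c("hdi", "posterior")) {
  cfg <- list(
    rope_fraction = rope_fraction, hdi_mass = hdi_mass,
    n_draws = as.integer(n_draws), upper_thr = upper_thr,
    lower_thr = lower_thr, cv_source = match.arg(cv_source),
    group_cv = group_cv, delta_timepoints = delta_timepoints,
    delta_method = match.arg(delta_method), rope_override = rope_override,
    pct_scope = match.arg(pct_scope)
  )
  structure(cfg, class = "responder_config")
}

#' Read a responder configuration from YAML
#'
#' Any field of [responder_config()] may appear in the file; unspecified
#' fields keep their defaults. `group_cv` and `rope_override` are given as
#' named maps.
#'
#' @param path Path to a YAML file.
#' @return A `responder_config`.
#' @export
read_responder_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_schema("reading YAML configuration requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(responder_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  raw <- raw[intersect(names(raw), known)]
  for (field in c("group_cv", "rope_override")) {
    if (!is.null(raw[[field]])) raw[[field]] <- unlist(raw[[field]])
  }
  do.call(responder_config, raw)
}

# Per-participant baseline mean of an outcome: PRE values averaged across
# the participant's available conditions.
participant_baselines <- function(measurements, outcome) {
  pre <- measurements[measurements$timepoint == "PRE" &
                        !is.na(measurements[[outcome]]), ]
  dplyr::summarise(dplyr::group_by(pre, .data$participant_id),
                   baseline = mean(.data[[outcome]]), .groups = "drop")
}

#' Classify every complete participant of a cohort
#'
#' Runs the full ROPE + HDI decision rule for one outcome and exercise
#' condition: per participant, the pooled 15/30-min change from baseline is
#' wrapped in a Normal measurement-error posterior with SD equal to the
#' technical error times sqrt(2), the 89% HDI is extracted from `n_draws`
#' draws, and the fraction of the HDI inside the group's ROPE decides the
#' label. Incomplete participants are skipped with a message. Results are
#' deterministic for a fixed `seed`: per-participant seeds are derived by
#' stable hashing of (seed, participant id, outcome, condition), so the
#' output is independent of row order.
#'
#' @param data A [study_dataset()].
#' @param outcome `"csbp"` or `"bsbp"`.
#' @param condition `"MOD"` or `"HIGH"`.
#' @param config A [responder_config()].
#' @param seed Master integer seed.
#' @param cv_table Per-participant CVs (tibble with `participant_id`, `cv`),
#'   required when `config$cv_source == "individual"`; see [estimate_cv()].
#' @return Tibble with one row per classified (participant, delta): columns
#'   `participant_id`, `group`, `outcome`, `condition`, `timepoint`
#'   (`"P15+P30"` for the pooled delta), `delta`, `scale`, `hdi_lower`,
#'   `hdi_upper`, `rope_lower`, `rope_upper`, `pct_in_rope`, `label`.
#' @export
classify_cohort <- function(data, outcome = OUTCOMES, condition = CONDITIONS,
                            config = responder_config(), seed = 1L,
                            cv_table = NULL) {
  outcome <- match.arg(outcome)
  condition <- match.arg(condition)
  validate_study_dataset(data)
  stopifnot(inherits(config, "responder_config"))

  m <- data$measurements
  baselines <- participant_baselines(m, outcome)
  groups <- setNames(data$participants$group,
                     data$participants$participant_id)

  # ROPE per group from the between-participant baseline SD (or override).
  rope_by_group <- lapply(setNames(GROUPS, GROUPS), function(g) {
    if (!is.null(config$rope_override) && g %in% names(config$rope_override)) {
      half <- config$rope_override[[g]]
      return(tibble::tibble(lower = -half, upper = half,
                            fraction = NA_real_, source_sd = NA_real_))
    }
    b <- baselines$baseline[groups[baselines$participant_id] == g]
    if (length(b) == 0) return(NULL)
    if (length(b) < 2) {
      stop_domain(sprintf(
        "group %s has fewer than 2 baseline observations: cannot form a ROPE", g))
    }
    rope_from_sd(sd(b), config$rope_fraction)
  })

  complete <- complete_participants(data, outcome, condition)
  skipped <- setdiff(data$participants$participant_id, complete)
  if (length(skipped)) {
    message(sprintf("skipping %d incomplete participant(s) for %s/%s: %s",
                    length(skipped), outcome, condition,
                    paste(skipped, collapse = ", ")))
  }

  sess <- m[m$condition == condition, ]
  rows <- lapply(complete, function(id) {
    vals <- setNames(sess[[outcome]][sess$participant_id == id],
                     sess$timepoint[sess$participant_id == id])
    pre <- vals[["PRE"]]
    deltas <- vapply(config$delta_timepoints, function(tp) {
      if (tp %in% names(vals)) delta_from_baseline(pre, vals[[tp]]) else NA_real_
    }, numeric(1))
    deltas <- deltas[!is.na(deltas)]
    if (config$delta_method == "mean") {
      deltas <- setNames(mean(deltas),
                         paste(names(deltas), collapse = "+"))
    }

    g <- groups[[id]]
    cv <- if (config$cv_source == "group") {
      if (!g %in% names(config$group_cv)) {
        stop_schema(sprintf("no group CV configured for group '%s'", g))
      }
      config$group_cv[[g]]
    } else {
      if (is.null(cv_table)) {
        stop_schema("cv_source = 'individual' requires a cv_table")
      }
      hit <- cv_table$cv[cv_table$participant_id == id]
      if (length(hit) != 1 || is.na(hit)) {
        stop_schema(sprintf("no individual CV available for '%s'", id))
      }
      hit
    }
    bl <- baselines$baseline[baselines$participant_id == id]
    te <- technical_error(cv, bl)
    scale <- te * sqrt(2)
    rope <- rope_by_group[[g]]

    dplyr::bind_rows(lapply(names(deltas), function(tp_label) {
      spec <- posterior_spec(
        location = deltas[[tp_label]], scale = scale,
        n_draws = config$n_draws, hdi_mass = config$hdi_mass,
        seed = derive_seed(seed, id, outcome, condition, tp_label)
      )
      draws <- draw_posterior(spec)
      h <- hdi(draws, config$hdi_mass)
      pct <- if (config$pct_scope == "hdi") {
        pct_hdi_in_rope(draws, h, rope)
      } else {
        mean(draws >= rope$lower & draws <= rope$upper)
      }
      tibble::tibble(
        participant_id = id, group = g, outcome = outcome,
        condition = condition, timepoint = tp_label,
        delta = unname(deltas[[tp_label]]), scale = scale,
        hdi_lower = h$lower, hdi_upper = h$upper,
        rope_lower = rope$lower, rope_upper = rope$upper,
        pct_in_rope = pct,
        label = classify_responder(pct, deltas[[tp_label]],
                                   config$upper_thr, config$lower_thr)
      )
    }))
  })
  calls <- dplyr::bind_rows(rows)

  # With group-level CVs the posterior scale can exceed the ROPE so far that
  # >99% of the HDI can never fall inside it: surface that, loudly.
  if (nrow(calls)) {
    max_pct <- (2 * stats::pnorm(calls$rope_upper / calls$scale) - 1) /
      config$hdi_mass
    if (all(max_pct <= config$upper_thr)) {
      warn(paste0(
        "posterior scale vs ROPE width makes NON_RESPONDER calls ",
        "unattainable for every participant (max achievable fraction of HDI ",
        "in ROPE ", sprintf("%.3f", max(max_pct)), " <= threshold ",
        config$upper_thr, "); consider cv_source = 'individual'"))
    }
  }
  calls
}

#' Tally responder labels per group
#'
#' @param calls Output of [classify_cohort()].
#' @return Tibble of counts and proportions per group x label (only labels
#'   that occur).
#' @export
responder_counts <- function(calls) {
  out <- dplyr::count(calls, .data$group, .data$outcome, .data$condition,
                      .data$label, name = "n")
  dplyr::mutate(dplyr::group_by(out, .data$group, .data$outcome,
                                .data$condition),
                prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Estimate per-participant CVs from duplicate measurements
#'
#' Pools the within-pair [coefficient_of_variation()] of duplicate readings
#' over all of a participant's sessions by root mean square (the typical-
#' error convention, unbiased for the squared CV, unlike the arithmetic mean
#' of per-pair CVs which is biased low for normal noise), giving the
#' individual CV used when `cv_source = "individual"`.
#'
#' @param replicates Tibble with columns `participant_id`, `rep1`, `rep2`
#'   (one row per duplicated reading), e.g. the `replicates` element returned
#'   by [generate_cohort()] filtered to one outcome.
#' @return Tibble with `participant_id` and `cv`.
#' @export
estimate_cv <- function(replicates) {
  dplyr::summarise(
    dplyr::group_by(replicates, .data$participant_id),
    cv = sqrt(mean(coefficient_of_variation(.data$rep1, .data$rep2)^2)),
    .groups = "drop"
  )
}
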