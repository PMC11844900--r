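#' Parameters of one synthetic study group
#'
#' Describes a group of the simulated crossover trial: baseline distributions
#' of the pressure outcomes, duplicate-measurement noise (as a CV), and the
#' mixture of true post-exercise response profiles. Defaults for the two
#' study-like groups are provided by [cad_group_params()] and
#' [con_group_params()].
#'
#' The observed baseline SD targets are decomposed internally into a latent
#' between-participant SD plus duplicate-averaged measurement error, so the
#' generated observed baselines match the stated mean/SD.
#'
#' @param label Group label, `"CAD"` or `"CON"`.
#' @param n Number of participants (>= 2).
#' @param csbp,bsbp,bdbp Named vectors `c(mean = , sd = )`, mmHg (observed
#'   baseline targets).
#' @param cv Duplicate-measurement coefficient of variation (fraction).
#' @param responder_mix Named proportions over the true central-pressure
#'   response profiles `SUSTAINED_ELEVATION` / `HYPOTENSIVE` / `NULL`
#'   (must sum to 1).
#' @param responder_mix_bsbp Same, for the brachial outcome (brachial
#'   responses are largely null in both study groups).
#' @param effect_magnitude Mean absolute true change at 15/30 min for
#'   responder profiles, mmHg.
#' @param transient_5min_bump Named per-outcome transient elevation at 5 min,
#'   mmHg (applies to all profiles: the immediate post-exercise rise).
#' @param hr Named vector `c(mean = , sd = )` for baseline heart rate.
#' @param cfpwv_baseline Named vector `c(mean = , sd = )` for baseline pulse
#'   wave velocity, m/s.
#' @return A list of class `group_params`.
#' @export
group_params <- function(label, n,
                         csbp = c(mean = 101, sd = 18),
                         bsbp = c(mean = 112, sd = 8),
                         bdbp = c(mean = 70, sd = 6),
                         cv = 0.05,
                         responder_mix = c(SUSTAINED_ELEVATION = 0.65,
                                           HYPOTENSIVE = 0.12,
                                           "NULL" = 0.23),
                         responder_mix_bsbp = c(SUSTAINED_ELEVATION = 0.12,
                                                HYPOTENSIVE = 0.06,
                                                "NULL" = 0.82),
                         effect_magnitude = 10,
                         transient_5min_bump = c(csbp = 16, bsbp = 3),
                         hr = c(mean = 63, sd = 11),
                         cfpwv_baseline = c(mean = 8.1, sd = 1.6)) {
  if (!label %in% GROUPS) stop_parse(sprintf("unknown group label '%s'", label))
  if (n < 2) stop_domain("a synthetic group needs at least 2 participants")
  for (b in list(csbp, bsbp, bdbp)) {
    if (b[["sd"]] <= 0) stop_domain("baseline SDs must be positive")
  }
  for (mix in list(responder_mix, responder_mix_bsbp)) {
    if (!setequal(names(mix), PROFILES) || abs(sum(mix) - 1) > 1e-8) {
      stop_domain("responder mixes must be proportions over the three profiles summing to 1")
    }
  }
  if (cv < 0) stop_domain("cv must be non-negative")
  structure(
    list(label = label, n = as.integer(n), csbp = csbp, bsbp = bsbp,
         bdbp = bdbp, cv = cv,
         responder_mix = responder_mix[PROFILES],
         responder_mix_bsbp = responder_mix_bsbp[PROFILES],
         effect_magnitude = effect_magnitude,
         transient_5min_bump = transient_5min_bump,
         hr = hr, cfpwv_baseline = cfpwv_baseline),
    class = "group_params"
  )
}

#' @rdname group_params
#' @param ... Overrides passed on to [group_params()].
#' @export
cad_group_params <- function(n = 17, ...) {
  args <- utils::modifyList(
    list(label = "CAD", n = n,
         csbp = c(mean = 101, sd = 18), bsbp = c(mean = 112, sd = 8),
         bdbp = c(mean = 70, sd = 6), cv = 0.05,
         responder_mix = c(SUSTAINED_ELEVATION = 0.65, HYPOTENSIVE = 0.12,
                           "NULL" = 0.23),
         responder_mix_bsbp = c(SUSTAINED_ELEVATION = 0.12, HYPOTENSIVE = 0.06,
                                "NULL" = 0.82),
         effect_magnitude = 10, transient_5min_bump = c(csbp = 16, bsbp = 3),
         hr = c(mean = 62, sd = 11), cfpwv_baseline = c(mean = 8.1, sd = 1.6)),
    list(...))
  do.call(group_params, args)
}

#' @rdname group_params
#' @export
con_group_params <- function(n = 18, ...) {
  args <- utils::modifyList(
    list(label = "CON", n = n,
         csbp = c(mean = 122, sd = 18), bsbp = c(mean = 122, sd = 9),
         bdbp = c(mean = 77, sd = 7), cv = 0.04,
         responder_mix = c(SUSTAINED_ELEVATION = 0.11, HYPOTENSIVE = 0.61,
                           "NULL" = 0.28),
         responder_mix_bsbp = c(SUSTAINED_ELEVATION = 0.05, HYPOTENSIVE = 0.17,
                                "NULL" = 0.78),
         effect_magnitude = 10, transient_5min_bump = c(csbp = 7, bsbp = 12),
         hr = c(mean = 63, sd = 15), cfpwv_baseline = c(mean = 8.4, sd = 1.8)),
    list(...))
  do.call(group_params, args)
}

profile_effect_sign <- c(SUSTAINED_ELEVATION = 1, HYPOTENSIVE = -1, "NULL" = 0)

#' Expected responder label for a true response profile
#'
#' @param profile `"SUSTAINED_ELEVATION"`, `"HYPOTENSIVE"` or `"NULL"`.
#' @return The responder label a perfect classifier would assign.
#' @export
expected_label_for_profile <- function(profile) {
  map <- c(SUSTAINED_ELEVATION = "HYPERTENSIVE_RESPONDER",
           HYPOTENSIVE = "HYPOTENSIVE_RESPONDER",
           "NULL" = "NON_RESPONDER")
  unname(map[profile])
}

# Vectorised generation of one group's measurements, truth and duplicate
# replicates. Called inside a fixed-RNG scope by generate_cohort().
generate_group <- function(gp) {
  n <- gp$n
  ids <- sprintf("%s%03d", gp$label, seq_len(n))

  latent_baseline <- function(b) {
    te <- gp$cv * b[["mean"]]
    lat_sd <- sqrt(max(b[["sd"]]^2 - te^2 / 2, (0.1 * b[["sd"]])^2))
    rnorm(n, b[["mean"]], lat_sd)
  }
  lat <- list(csbp = latent_baseline(gp$csbp),
              bsbp = latent_baseline(gp$bsbp),
              bdbp = rnorm(n, gp$bdbp[["mean"]], gp$bdbp[["sd"]]),
              hr = rnorm(n, gp$hr[["mean"]], gp$hr[["sd"]]),
              cfpwv = rnorm(n, gp$cfpwv_baseline[["mean"]],
                            gp$cfpwv_baseline[["sd"]]))
  lat$bsbp <- pmax(lat$bsbp, lat$bdbp + 5)
  lat$csbp <- pmax(lat$csbp, 10)
  lat$hr <- pmax(lat$hr, 35)
  lat$cfpwv <- pmax(lat$cfpwv, 2)

  labels <- list(
    csbp = sample(PROFILES, n, replace = TRUE, prob = gp$responder_mix),
    bsbp = sample(PROFILES, n, replace = TRUE, prob = gp$responder_mix_bsbp)
  )
  effects <- lapply(labels, function(l) {
    gp$effect_magnitude * unname(profile_effect_sign[l])
  })

  grid <- tidyr::expand_grid(idx = seq_len(n), condition = CONDITIONS,
                             timepoint = TIMEPOINTS)
  at_p5 <- grid$timepoint == "P5"
  at_late <- grid$timepoint %in% c("P15", "P30")

  reps <- list()
  obs <- list()
  for (oc in OUTCOMES) {
    truth_traj <- lat[[oc]][grid$idx] +
      gp$transient_5min_bump[[oc]] * at_p5 +
      effects[[oc]][grid$idx] * at_late
    noise_sd <- gp$cv * lat[[oc]][grid$idx]
    rep1 <- pmax(truth_traj + rnorm(nrow(grid), 0, noise_sd), 1)
    rep2 <- pmax(truth_traj + rnorm(nrow(grid), 0, noise_sd), 1)
    reps[[oc]] <- tibble::tibble(
      participant_id = ids[grid$idx], condition = grid$condition,
      timepoint = grid$timepoint, outcome = oc, rep1 = rep1, rep2 = rep2
    )
    obs[[oc]] <- (rep1 + rep2) / 2
  }

  bdbp_obs <- lat$bdbp[grid$idx] +
    rnorm(nrow(grid), 0, gp$cv * lat$bdbp[grid$idx] / sqrt(2))
  bdbp_obs <- pmax(bdbp_obs, 1)
  bsbp_obs <- pmax(obs$bsbp, bdbp_obs + 0.5)
  hr_traj <- c(PRE = 0, P5 = 9, P15 = 6, P30 = 5)
  hr_obs <- pmax(lat$hr[grid$idx] + unname(hr_traj[grid$timepoint]) +
                   rnorm(nrow(grid), 0, 2), 30)
  pwv_traj <- c(PRE = 0, P5 = 0.45, P15 = 0.15, P30 = 0.1)
  pwv_obs <- pmax(lat$cfpwv[grid$idx] + unname(pwv_traj[grid$timepoint]) +
                    rnorm(nrow(grid), 0, 0.3), 1)

  list(
    participants = tibble::tibble(participant_id = ids, group = gp$label),
    measurements = tibble::tibble(
      participant_id = ids[grid$idx], condition = grid$condition,
      timepoint = grid$timepoint, hr = hr_obs, bsbp = bsbp_obs,
      bdbp = bdbp_obs, csbp = pmax(obs$csbp, 1), cfpwv = pwv_obs
    ),
    truth = dplyr::bind_rows(lapply(OUTCOMES, function(oc) {
      tibble::tibble(participant_id = ids, group = gp$label, outcome = oc,
                     true_label = labels[[oc]],
                     true_effect = effects[[oc]])
    })),
    replicates = dplyr::bind_rows(reps)
  )
}

#' Generate a synthetic crossover cohort with known ground truth
#'
#' Simulates the full trial layout: for every participant a latent baseline
#' per outcome, a true response profile drawn from the group's mixture (step
#' trajectory: zero at PRE, transient bump at 5 min, the true effect at 15
#' and 30 min for responder profiles), and duplicate tonometry replicates
#' with multiplicative-in-mean noise (`SD = cv x latent`), averaged into the
#' recorded measurement exactly as duplicate readings are averaged at ingest.
#' MOD and HIGH sessions are simulated independently given the latent
#' baseline.
#'
#' @param params List of [group_params()] (one per group), e.g.
#'   `list(cad_group_params(), con_group_params())`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return List with elements `data` (a validated [study_dataset()]),
#'   `truth` (tibble: `participant_id`, `group`, `outcome`, `true_label`,
#'   `true_effect`) and `replicates` (tibble of duplicate readings per
#'   session, from which individual CVs are estimable via [estimate_cv()]).
#' @export
generate_cohort <- function(params = list(cad_group_params(),
                                          con_group_params()),
                            seed = 1L) {
  if (inherits(params, "group_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, logical(1), "group_params")))
  pieces <- withr::with_seed(as.integer(seed), lapply(params, generate_group))
  data <- study_dataset(
    participants = dplyr::bind_rows(lapply(pieces, `[[`, "participants")),
    measurements = dplyr::bind_rows(lapply(pieces, `[[`, "measurements")),
    provenance = sprintf("synthetic cohort (seed %d)", as.integer(seed))
  )
  list(
    data = data,
    truth = dplyr::bind_rows(lapply(pieces, `[[`, "truth")),
    replicates = dplyr::bind_rows(lapply(pieces, `[[`, "replicates"))
  )
}

#' Label-recovery experiment
#'
#' Repeatedly generates a cohort and classifies it, tallying the confusion
#' between true response profiles and called responder labels — the
#' validation harness for the decision rule's operating characteristics.
#'
#' @param params List of [group_params()].
#' @param n_reps Number of independent replicates (0 gives an empty table).
#' @param master_seed Integer; per-replicate seeds are derived from it.
#' @param outcome,condition Outcome and condition passed to
#'   [classify_cohort()].
#' @param config A [responder_config()]. When `config$cv_source` is
#'   `"individual"`, per-participant CVs are estimated from the generated
#'   duplicate replicates of the chosen outcome.
#' @return Tibble: `true_label`, `label`, `n`, aggregated over replicates.
#' @export
recovery_experiment <- function(params, n_reps, master_seed = 1L,
                                outcome = OUTCOMES, condition = "HIGH",
                                config = responder_config()) {
  outcome <- match.arg(outcome)
  if (n_reps == 0) {
    return(tibble::tibble(true_label = character(), label = character(),
                          n = integer()))
  }
  tallies <- lapply(seq_len(n_reps), function(i) {
    seed_i <- derive_seed(master_seed, "cohort", i)
    gen <- generate_cohort(params, seed = seed_i)
    cv_table <- if (config$cv_source == "individual") {
      estimate_cv(gen$replicates[gen$replicates$outcome == outcome, ])
    }
    calls <- classify_cohort(gen$data, outcome, condition, config,
                             seed = derive_seed(seed_i, "classify"),
                             cv_table = cv_table)
    merged <- dplyr::inner_join(
      calls, gen$truth[gen$truth$outcome == outcome,
                       c("participant_id", "true_label")],
      by = "participant_id")
    dplyr::count(merged, .data$true_label, .data$label, name = "n")
  })
  out <- dplyr::bind_rows(tallies)
  dplyr::summarise(dplyr::group_by(out, .data$true_label, .data$label),
                   n = sum(.data$n), .groups = "drop")
}
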