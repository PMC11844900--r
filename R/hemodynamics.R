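#' Mean arterial pressure from brachial pressures
#'
#' Uses the diastolic-weighted form `2/3 * bDBP + 1/3 * bSBP`, the calibration
#' convention for supine tonometry in which diastolic and mean pressures are
#' assumed constant along the arterial tree. The result always lies strictly
#' between the diastolic and systolic inputs.
#'
#' @param bsbp Brachial systolic pressure, mmHg. Vectorised.
#' @param bdbp Brachial diastolic pressure, mmHg.
#' @return Mean arterial pressure, mmHg.
#' @export
#' @examples
#' mean_arterial_pressure(112, 70) # 84
mean_arterial_pressure <- function(bsbp, bdbp) {
  if (any(bdbp <= 0 | bsbp <= bdbp)) {
    stop_domain("mean_arterial_pressure requires bsbp > bdbp > 0")
  }
  2 / 3 * bdbp + 1 / 3 * bsbp
}

#' Amplification pressure
#'
#' Brachial minus central systolic pressure: the pressure added peripherally
#' by wave reflection. Positive in compliant arteries; may be negative, e.g.
#' immediately after exercise when central pressure transiently exceeds
#' brachial.
#'
#' @param bsbp Brachial systolic pressure, mmHg.
#' @param csbp Central systolic pressure, mmHg.
#' @return Amplification pressure, mmHg (sign preserved).
#' @export
amplification <- function(bsbp, csbp) {
  if (any(bsbp <= 0 | csbp <= 0)) {
    stop_domain("amplification requires positive pressures")
  }
  bsbp - csbp
}

#' Brachial and central pulse pressures
#'
#' Central pulse pressure uses the brachial diastolic value because the
#' tonometry calibration assumes diastolic pressure is constant throughout
#' the vascular system; no separate central diastolic measurement exists.
#'
#' @inheritParams mean_arterial_pressure
#' @param csbp Central systolic pressure, mmHg.
#' @return Tibble with columns `bpp` (`bsbp - bdbp`) and `cpp`
#'   (`csbp - bdbp`), mmHg.
#' @export
pulse_pressures <- function(bsbp, bdbp, csbp) {
  if (any(bdbp <= 0 | bsbp <= bdbp)) {
    stop_domain("pulse_pressures requires bsbp > bdbp > 0")
  }
  if (any(csbp <= 0)) stop_domain("pulse_pressures requires csbp > 0")
  tibble::tibble(bpp = bsbp - bdbp, cpp = csbp - bdbp)
}

#' Carotid-femoral pulse wave velocity
#'
#' Ratio of the taped carotid-femoral surface distance to the pulse transit
#' time, with the distance scaled by the standard 0.8 correction that accounts
#' for the overestimation of the true aortic path by body-surface taping.
#'
#' @param taped_distance Taped carotid-femoral distance, metres.
#' @param ptt Pulse transit time, seconds.
#' @param correction Distance correction factor (default 0.8; set 1 to
#'   disable).
#' @return Pulse wave velocity, m/s.
#' @export
#' @examples
#' cfpwv(0.80, 0.080) # 8 m/s
cfpwv <- function(taped_distance, ptt, correction = 0.8) {
  if (any(taped_distance <= 0 | ptt <= 0 | correction <= 0)) {
    stop_domain("cfpwv requires positive distance, transit time and correction")
  }
  correction * taped_distance / ptt
}

#' Heart-rate recovery at one minute
#'
#' Peak exercise heart rate minus the heart rate one minute into recovery, so
#' that faster vagal reactivation yields larger positive values (the reporting
#' convention for group summaries).
#'
#' @param hr_peak Peak heart rate, beats/min.
#' @param hr_1min Heart rate after 1 min of recovery, beats/min.
#' @return Heart-rate recovery, beats/min.
#' @export
hrr1 <- function(hr_peak, hr_1min) {
  if (any(hr_peak <= 0 | hr_1min <= 0)) {
    stop_domain("hrr1 requires positive heart rates")
  }
  hr_peak - hr_1min
}

#' Describe a combined-exercise session
#'
#' A session plan is the input to [trimp()]: the ordered main aerobic segments
#' (duration in minutes, intensity zone relative to the ventilatory
#' thresholds) plus the resistance circuit (sets x reps at a fraction of each
#' exercise's one-repetition maximum). Warm-up and cool-down are not part of
#' the plan: the session load convention counts main-segment work only.
#'
#' @param segments Tibble with columns `duration` (min, > 0) and `zone` (one
#'   of `"BELOW_VT1"`, `"AT_VT1"`, `"AT_VT2"`).
#' @param exercises Optional tibble with columns `one_rm` (kg), `fraction`
#'   (of 1-RM, in (0, 1]), `sets`, `reps`.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(segments, exercises = NULL) {
  segments <- tibble::as_tibble(segments)
  if (!all(c("duration", "zone") %in% names(segments))) {
    stop_schema("segments needs columns 'duration' and 'zone'")
  }
  if (any(segments$duration <= 0)) stop_domain("segment durations must be > 0")
  bad <- setdiff(unique(segments$zone), names(TRIMP_ZONE_WEIGHTS))
  if (length(bad)) stop_parse(sprintf("unknown zone '%s'", bad[1]))
  if (!is.null(exercises)) {
    exercises <- tibble::as_tibble(exercises)
    if (!all(c("one_rm", "fraction", "sets", "reps") %in% names(exercises))) {
      stop_schema("exercises needs columns one_rm, fraction, sets, reps")
    }
    if (any(exercises$fraction <= 0 | exercises$fraction > 1)) {
      stop_domain("1-RM fractions must lie in (0, 1]")
    }
  }
  structure(list(segments = segments, exercises = exercises),
            class = "session_plan")
}

TRIMP_ZONE_WEIGHTS <- c(BELOW_VT1 = 1, AT_VT1 = 2, AT_VT2 = 3)

#' Moderate-intensity session plan
#'
#' The moderate combined bout's main aerobic segment: 18 min of continuous
#' cycling at the first ventilatory threshold followed by 2 min of unloaded
#' cycling; resistance circuit at 60% of 1-RM when loads are supplied.
#'
#' @param one_rm Optional vector of per-exercise 1-RM loads, kg.
#' @param sets,reps Resistance scheme (default 2 x 12).
#' @return A [session_plan()].
#' @export
mod_session_plan <- function(one_rm = NULL, sets = 2, reps = 12) {
  ex <- if (!is.null(one_rm)) {
    tibble::tibble(one_rm = one_rm, fraction = 0.6, sets = sets, reps = reps)
  }
  session_plan(
    tibble::tibble(duration = c(18, 2), zone = c("AT_VT1", "BELOW_VT1")),
    exercises = ex
  )
}

#' High-intensity session plan
#'
#' The high-intensity combined bout's main aerobic segment: 5 x 2 min at the
#' second ventilatory threshold interspersed with 4 x 2 min at the first,
#' followed by 2 min of de-loading; resistance circuit at 80% of 1-RM when
#' loads are supplied.
#'
#' @inheritParams mod_session_plan
#' @return A [session_plan()].
#' @export
high_session_plan <- function(one_rm = NULL, sets = 2, reps = 12) {
  zones <- c(rep(c("AT_VT2", "AT_VT1"), 4), "AT_VT2", "BELOW_VT1")
  ex <- if (!is.null(one_rm)) {
    tibble::tibble(one_rm = one_rm, fraction = 0.8, sets = sets, reps = reps)
  }
  session_plan(
    tibble::tibble(duration = rep(2, length(zones)), zone = zones),
    exercises = ex
  )
}

#' Training impulse (TRIMP) of a combined session
#'
#' Aerobic load is the zone-weighted time of the main aerobic segments
#' (weights 1, 2, 3 for below-VT1, at-VT1 and at-VT2 work); resistance load is
#' `sets x reps x effective load` summed over exercises, with effective load
#' equal to the 1-RM times the prescribed fraction. The two printed session
#' totals of the protocol follow from this weighting: the moderate bout scores
#' 18x2 + 2x1 = 38 and the high-intensity bout 5x2x3 + 4x2x2 + 2x1 = 48.
#'
#' @param plan A [session_plan()].
#' @param zone_weights Named weights per zone; override to explore other
#'   weighting conventions.
#' @return Tibble with columns `aerobic`, `resistance` and `total`.
#' @export
trimp <- function(plan, zone_weights = TRIMP_ZONE_WEIGHTS) {
  stopifnot(inherits(plan, "session_plan"))
  if (nrow(plan$segments) == 0 && is.null(plan$exercises)) {
    warn("empty session plan: TRIMP is zero")
  }
  aerobic <- sum(plan$segments$duration *
                   unname(zone_weights[plan$segments$zone]))
  resistance <- if (is.null(plan$exercises)) 0 else {
    with(plan$exercises, sum(sets * reps * one_rm * fraction))
  }
  tibble::tibble(aerobic = aerobic, resistance = resistance,
                 total = aerobic + resistance)
}

#' Technical error of measurement
#'
#' The measurement-error scale used to build each participant's posterior:
#' coefficient of variation times the baseline mean of the outcome.
#'
#' @param cv Coefficient of variation as a fraction (e.g. 0.05).
#' @param baseline_mean Baseline outcome mean, mmHg.
#' @return Technical error, mmHg.
#' @export
technical_error <- function(cv, baseline_mean) {
  if (any(cv < 0)) stop_domain("cv must be non-negative")
  if (any(baseline_mean <= 0)) stop_domain("baseline mean must be positive")
  if (any(cv > 1)) warn("cv > 1 is implausible for blood-pressure tonometry")
  cv * baseline_mean
}

#' Coefficient of variation of duplicate measurements
#'
#' Within-pair standard deviation divided by the pair mean, where the SD of a
#' duplicate pair is `|rep1 - rep2| / sqrt(2)`. This is the per-session CV of
#' the two repeated tonometry readings.
#'
#' @param rep1,rep2 The two repeated measurements, mmHg. Vectorised.
#' @return CV as a fraction.
#' @export
#' @examples
#' coefficient_of_variation(98, 102) # 0.0283
coefficient_of_variation <- function(rep1, rep2) {
  if (any(rep1 <= 0 | rep2 <= 0)) {
    stop_domain("duplicate measurements must be positive")
  }
  (abs(rep1 - rep2) / sqrt(2)) / ((rep1 + rep2) / 2)
}

#' Post-exercise change from baseline
#'
#' @param pre Baseline value.
#' @param post Post-exercise value.
#' @return `post - pre`; `NA` propagates.
#' @export
delta_from_baseline <- function(pre, post) {
  post - pre
}

#' Derived hemodynamic panel for every session measurement
#'
#' Applies [mean_arterial_pressure()], [pulse_pressures()] and
#' [amplification()] row-wise over a dataset's measurements.
#'
#' @param data A [study_dataset()].
#' @return Tibble: the measurements with `map`, `bpp`, `cpp` and
#'   `amplification` columns appended.
#' @export
hemodynamic_panel <- function(data) {
  m <- validate_study_dataset(data)$measurements
  pp <- pulse_pressures(m$bsbp, m$bdbp, m$csbp)
  dplyr::mutate(m,
    map = mean_arterial_pressure(.data$bsbp, .data$bdbp),
    bpp = pp$bpp,
    cpp = pp$cpp,
    amplification = amplification(.data$bsbp, .data$csbp)
  )
}
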