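test_that("ROPE construction is symmetric and rejects degenerate inputs", {
  r <- rope_from_sd(18)
  expect_equal(r$lower, -r$upper)
  expect_equal(r$upper, 0.2 * 18)
  expect_error(rope_from_sd(18, fraction = 0), class = "peh_error_domain")
  expect_error(rope_from_sd(0), class = "peh_error_domain")
})

test_that("posterior draws are reproducible and calibrated", {
  spec <- posterior_spec(location = 0, scale = 1, n_draws = 1000, seed = 17)
  a <- draw_posterior(spec)
  b <- draw_posterior(spec)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 4 / sqrt(1000)) # CLT bound on the sample mean
  expect_equal(sd(a), 1, tolerance = 0.1)
  # a different location shifts the draws
  s2 <- posterior_spec(location = 5, scale = 1, n_draws = 1000, seed = 17)
  expect_equal(mean(draw_posterior(s2)), 5, tolerance = 0.2)
  expect_error(posterior_spec(0, scale = 0), class = "peh_error_domain")
  expect_error(posterior_spec(0, 1, n_draws = 50), class = "peh_error_domain")
  expect_error(posterior_spec(0, 1, hdi_mass = 1), class = "peh_error_domain")
})

test_that("the HDI is the narrowest window of sorted draws", {
  h <- hdi(1:10, mass = 0.5)
  expect_equal(c(h$lower, h$upper), c(1, 5)) # ties resolved to lowest start
  x <- rep(3.5, 20)
  h <- hdi(x, 0.89)
  expect_equal(h$upper - h$lower, 0)
  expect_equal(h$lower, 3.5)
  expect_error(hdi(1:5, 0.89), class = "peh_error_domain")
  expect_error(hdi(1:20, 0), class = "peh_error_domain")
})

test_that("the HDI matches an exhaustive window search on random samples", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(10:200, 1)
    mass <- runif(1, 0.3, 0.97)
    x <- switch(1 + s %% 3,
                rnorm(n),
                rexp(n), # skewed: HDI must hug the mode, not the centre
                c(rnorm(n %/% 2, -4), rnorm(n - n %/% 2, 4)))
    h <- hdi(x, mass)
    o <- hdi_oracle(x, mass)
    expect_equal(c(h$lower, h$upper), unname(o))
  }
})

test_that("the ROPE decision statistic behaves at the tails and the boundary", {
  rope <- rope_from_sd(18) # +/- 3.6
  inside <- seq(-3, 3, length.out = 500)
  expect_equal(pct_hdi_in_rope(inside, hdi(inside, 0.89), rope), 1)

  spec <- posterior_spec(15, 2.83, n_draws = 10000, seed = 5)
  d <- draw_posterior(spec)
  expect_lt(pct_hdi_in_rope(d, hdi(d, 0.89), rope), 1e-3)

  # posterior centred exactly on the ROPE boundary with small scale: half in
  spec <- posterior_spec(3.6, 0.1, n_draws = 10000, seed = 6)
  d <- draw_posterior(spec)
  expect_equal(pct_hdi_in_rope(d, hdi(d, 0.89), rope), 0.5, tolerance = 0.05)
})

test_that("labels follow the threshold pair and the sign of the delta", {
  expect_equal(classify_responder(0.995, -1), "NON_RESPONDER")
  expect_equal(classify_responder(0.0005, -10), "HYPOTENSIVE_RESPONDER")
  expect_equal(classify_responder(0.0005, 10), "HYPERTENSIVE_RESPONDER")
  expect_equal(classify_responder(0.43, 2), "UNDECIDED")
  # the undecided band is inclusive at both thresholds
  expect_equal(classify_responder(0.99, 2), "UNDECIDED")
  expect_equal(classify_responder(0.01, 2), "UNDECIDED")
  expect_error(classify_responder(0.0005, 0), class = "peh_error_integrity")
  expect_error(classify_responder(1.2, 1), class = "peh_error_domain")
})

test_that("pct-in-ROPE is non-increasing in |delta| at fixed scale", {
  rope <- rope_from_sd(18)
  pct <- vapply(seq(0, 16, by = 0.5), function(delta) {
    spec <- posterior_spec(delta, 3, n_draws = 20000, seed = 99)
    d <- draw_posterior(spec)
    pct_hdi_in_rope(d, hdi(d, 0.89), rope)
  }, numeric(1))
  expect_true(all(diff(pct) <= 0.02)) # Monte-Carlo slack on a decreasing curve
  expect_lt(pct[length(pct)], pct[1])
})

test_that("widening the technical error never manufactures non-responders", {
  rope <- rope_from_sd(18)
  for (delta in c(0, 1, 2.5, 4, 6)) {
    labels <- vapply(c(0.5, 1, 2, 4, 7, 10), function(scale) {
      spec <- posterior_spec(delta, scale, n_draws = 4000, seed = 12)
      d <- draw_posterior(spec)
      classify_responder(pct_hdi_in_rope(d, hdi(d, 0.89), rope), delta + 1e-9)
    }, character(1))
    seen_undecided <- FALSE
    for (lab in labels) {
      if (lab == "UNDECIDED") seen_undecided <- TRUE
      if (seen_undecided) expect_false(lab == "NON_RESPONDER")
    }
  }
})

test_that("cohort classification recovers exact deltas deterministically", {
  cfg_tight <- responder_config(group_cv = c(CAD = 0.001, CON = 0.001),
                                rope_override = c(CAD = 3.6, CON = 3.2))

  d0 <- exact_delta_dataset(0)
  calls <- classify_cohort(d0, "csbp", "MOD", cfg_tight, seed = 2)
  expect_equal(nrow(calls), 6)
  expect_true(all(calls$label == "NON_RESPONDER"))
  expect_true(all(calls$delta == 0))

  d10 <- exact_delta_dataset(10)
  calls <- classify_cohort(d10, "csbp", "MOD", cfg_tight, seed = 2)
  expect_true(all(calls$label == "HYPERTENSIVE_RESPONDER"))
  expect_equal(calls$timepoint, rep("P15+P30", 6))

  dneg <- exact_delta_dataset(-12)
  calls <- classify_cohort(dneg, "bsbp", "HIGH", cfg_tight, seed = 2)
  expect_true(all(calls$label == "HYPOTENSIVE_RESPONDER"))
})

test_that("incomplete participants are skipped, not classified", {
  d <- exact_delta_dataset(10, n_per_group = 4)
  m <- d$measurements
  drop <- m$participant_id == "cad01" & m$condition == "MOD" &
    m$timepoint %in% c("P15", "P30")
  d2 <- study_dataset(d$participants, m[!drop, ])
  cfg <- responder_config(group_cv = c(CAD = 0.001, CON = 0.001),
                          rope_override = c(CAD = 3.6, CON = 3.2))
  expect_message(calls <- classify_cohort(d2, "csbp", "MOD", cfg, seed = 2),
                 "cad01")
  expect_equal(nrow(calls), 7) # 8 participants, 1 incomplete
})

test_that("classification is seed-stable and row-order independent", {
  gen <- generate_cohort(list(cad_group_params(n = 6),
                              con_group_params(n = 6)), seed = 21)
  cfg <- responder_config(group_cv = c(CAD = 0.01, CON = 0.01))
  a <- classify_cohort(gen$data, "csbp", "HIGH", cfg, seed = 77)
  b <- classify_cohort(gen$data, "csbp", "HIGH", cfg, seed = 77)
  expect_identical(a, b)

  shuffled <- gen$data
  set.seed(5)
  shuffled$measurements <-
    shuffled$measurements[sample(nrow(shuffled$measurements)), ]
  shuffled$participants <-
    shuffled$participants[sample(nrow(shuffled$participants)), ]
  c2 <- classify_cohort(shuffled, "csbp", "HIGH", cfg, seed = 77)
  expect_identical(dplyr::arrange(a, participant_id),
                   dplyr::arrange(c2, participant_id))

  c3 <- classify_cohort(gen$data, "csbp", "HIGH", cfg, seed = 78)
  expect_false(identical(a$hdi_lower, c3$hdi_lower))
})

test_that("group-level CVs at 5%/4% make non-responder calls unattainable", {
  # the posterior scale (TE * sqrt(2), ~7 mmHg) dwarfs a +/-3.6 ROPE: even a
  # zero delta cannot push >99% of the HDI inside it, and the cohort
  # classifier says so out loud
  d0 <- exact_delta_dataset(0)
  cfg <- responder_config(rope_override = c(CAD = 3.6, CON = 3.2))
  expect_warning(calls <- classify_cohort(d0, "csbp", "MOD", cfg, seed = 4),
                 "unattainable")
  expect_false(any(calls$label == "NON_RESPONDER"))
  expect_true(all(calls$label == "UNDECIDED"))
})

test_that("per-timepoint classification yields one call per delta", {
  d <- exact_delta_dataset(10)
  cfg <- responder_config(group_cv = c(CAD = 0.001, CON = 0.001),
                          rope_override = c(CAD = 3.6, CON = 3.2),
                          delta_method = "per_timepoint")
  calls <- classify_cohort(d, "csbp", "MOD", cfg, seed = 2)
  expect_equal(nrow(calls), 12) # 6 participants x {P15, P30}
  expect_setequal(unique(calls$timepoint), c("P15", "P30"))
  expect_equal(delta_from_baseline(101, 111), 10)
})

test_that("a YAML file configures the pipeline like the in-R constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rope_fraction: 0.25",
               "n_draws: 2000",
               "cv_source: individual",
               "group_cv:",
               "  CAD: 0.03",
               "  CON: 0.02",
               "rope_override:",
               "  CAD: 3.71",
               "  CON: 3.24"), path)
  cfg <- read_responder_config(path)
  expect_s3_class(cfg, "responder_config")
  expect_equal(cfg$rope_fraction, 0.25)
  expect_equal(cfg$n_draws, 2000L)
  expect_equal(cfg$cv_source, "individual")
  expect_equal(cfg$group_cv, c(CAD = 0.03, CON = 0.02))
  expect_equal(cfg$rope_override, c(CAD = 3.71, CON = 3.24))
  expect_equal(cfg$hdi_mass, 0.89) # untouched default
  writeLines("bogus_field: 1", path)
  expect_warning(read_responder_config(path), "bogus_field")
})
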