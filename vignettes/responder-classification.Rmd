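---
title: "Classifying individual post-exercise blood-pressure responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying individual post-exercise blood-pressure responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pehresponse)
```

## The problem

Post-exercise hypotension — a sustained fall in blood pressure after an
acute exercise bout — is clinically attractive but notoriously variable
between individuals, and brachial cuff pressure can diverge from the central
aortic pressure that the heart, brain and kidneys actually see. In a
crossover trial where each participant completes a moderate- and a
high-intensity combined (aerobic + resistance) session, with tonometric
central and oscillometric brachial pressures at baseline and 5, 15 and
30 min of recovery, two questions arise:

1. At the group level, how do central and brachial systolic pressure evolve
   after exercise in patients versus controls?
2. At the individual level, which participants show a *real* hypotensive or
   hypertensive response, as opposed to measurement noise?

`pehresponse` implements both analyses plus the simulation machinery to
validate them.

## The measurement-error posterior and the decision rule

The individual analysis is an equivalence test, not a full Bayesian model.
For participant $i$, outcome $Y$ (cSBP or bSBP) and condition $c$:

- The observed change is
  $\Delta_i = \tfrac12\left[(Y_{i,15} - Y_{i,\mathrm{pre}}) + (Y_{i,30} - Y_{i,\mathrm{pre}})\right]$
  by default — the 15- and 30-min changes are pooled because the display and
  decision are per participant, not per timepoint
  (`delta_method = "per_timepoint"` classifies each separately).
- The "posterior" is the measurement-error distribution
  $N(\Delta_i,\; \mathrm{TE}_i \sqrt{2})$ with
  $\mathrm{TE}_i = \mathrm{CV} \times \bar Y_{i,\mathrm{pre}}$: the
  $\sqrt{2}$ is the standard deviation of a difference of two equally noisy
  measurements. There is no prior and no likelihood updating; the interval
  expresses how far the observed delta could move under repeat measurement.
- From `n_draws = 1000` draws, the **89% HDI** is extracted; the fraction of
  in-HDI draws that fall inside the **ROPE**
  $[-0.2\,s_Y^{(g)},\; +0.2\,s_Y^{(g)}]$ (where $s_Y^{(g)}$ is the
  between-participant baseline SD of the outcome in the participant's group)
  is the decision statistic $p_{\mathrm{ROPE}}$.
- $p_{\mathrm{ROPE}} > 0.99$: non-responder.
  $p_{\mathrm{ROPE}} < 0.01$: responder, hypotensive if $\Delta_i < 0$ else
  hypertensive. Otherwise: undecided. The undecided band is closed at both
  ends, which resolves the ambiguity of quoting the band as "2%–98%"
  alongside strict ">99% / <1%" thresholds: the strict inequalities define
  the decisive calls, everything else is undecided.

### Numerical choices

- **HDI**: the narrowest contiguous window of
  $\lceil \mathrm{mass} \cdot n\rceil$ sorted draws; ties are broken by the
  lowest start index, so the estimator is deterministic given the sample.
  For unimodal samples this converges to the true highest-density interval;
  its endpoints have $O(n^{-1/3})$-type Monte-Carlo wander, which is why
  validation averages endpoints over replicate samples rather than trusting
  a single draw.
- **$p_{\mathrm{ROPE}}$ scope**: computed over draws restricted to the HDI
  (the rule as stated: "% of HDI inside ROPE"). `pct_scope = "posterior"`
  switches to the full-posterior proportion for sensitivity analysis; the
  two differ by at most the factor 1/mass.
- **Seeds**: every participant's draw seed is derived by a stable string
  hash of (master seed, participant id, outcome, condition, timepoint
  label), so cohort results are bit-identical across runs and independent of
  row order.
- **Degenerate inputs**: a zero-width ROPE, a non-positive posterior scale,
  and a decisive responder call with $\Delta = 0$ (directionless) are all
  rejected as errors rather than silently classified.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rope_fraction` | 0.2 | of baseline SD | smallest-worthwhile-change convention |
| `hdi_mass` | 0.89 | — | conventional credible mass for decision HDIs |
| `n_draws` | 1000 | draws | matches the method's stated simulation size |
| `upper_thr` / `lower_thr` | 0.99 / 0.01 | — | decisive-call thresholds |
| `group_cv` | CAD 5%, CON 4% | fraction | duplicate-tonometry CVs of the two groups |
| `cv_source` | `"group"` | — | see the tension below |
| `rope_override` | unset | mmHg | impose externally fixed ROPE bounds |

### The CV-source tension

With group-level CVs of 5%/4% and baseline pressures near 100–120 mmHg, the
posterior scale is $\mathrm{TE}\sqrt2 \approx 7$ mmHg against a ROPE
half-width of ~3.6 mmHg. Even a delta of exactly zero then places at most
$(2\Phi(3.6/7) - 1)/0.89 \approx 0.6$ of the HDI inside the ROPE — the
non-responder call is *mathematically unattainable*, yet published analyses
of this design report many non-responders. `classify_cohort()` therefore
computes that bound per cohort and warns loudly when the non-responder
region is empty. The alternative, `cv_source = "individual"`, uses
per-participant CVs estimated from duplicate readings via `estimate_cv()`
(root-mean-square pooling over sessions, the typical-error convention,
because the arithmetic mean of per-pair CVs is biased low by the
half-normal factor $\sqrt{2/\pi}$). The default remains `"group"` — the
rule as literally stated — with the warning as the guard rail.

ROPE bounds are directly overridable (`rope_override`) because published
bands for the brachial outcome (±3.71 / ±3.24 mmHg) are not 0.2× the
printed baseline brachial SDs (8 and 9 mmHg) under any obvious pooling, so
reproducing a published analysis may require imposing its bounds verbatim.
When computed from data, the group baseline SD is taken across participants'
condition-averaged PRE values.

## Group-level summaries

`cell_summaries()` gives the mean (SD) table per group × condition ×
timepoint. `marginal_contrast()` estimates within-participant timepoint
changes marginalised over intensity: each participant's change is averaged
over their available conditions, then across participants, with a paired
t-based 95% CI. For balanced complete crossover data this equals the
marginal-mean contrast of a random-intercept linear mixed model; we use the
balanced average rather than refitting an REML model because the design is
complete by construction and the estimand is then identical (with missing
sessions it is a documented approximation). No multiplicity adjustment is
applied. Hedges' $g$ divides the contrast by the pooled SD of the two cells
(n−1 weighting) and applies the small-sample correction
$J = 1 - 3/(4(n_1+n_2)-9)$. Baseline between-group comparisons use Welch's
unequal-variance t test.

## Session load

`trimp()` scores a combined session as zone-weighted aerobic minutes
(below-VT1 = 1, at-VT1 = 2, at-VT2 = 3, main aerobic segments only —
warm-up and cool-down excluded) plus resistance volume
(sets × reps × fraction-of-1RM load). This weighting is the one under which
the two published session structures reproduce their printed aerobic totals
(moderate 18×2 + 2×1 = 38; high 5×2×3 + 4×2×2 + 2×1 = 48); both the weights
and the constructors are overridable, and whether the warm-up belongs in
the aerobic term is genuinely open — the reconstruction that matches the
printed totals excludes it.

```{r trimp}
trimp(mod_session_plan())
trimp(high_session_plan())
```

## What the synthetic cohort does and does not emulate

`generate_cohort()` simulates, per participant: a latent baseline per
outcome (normal, with the *observed* target SD decomposed into latent
between-participant variance plus duplicate-averaged measurement error, so
the generated observed baselines match the stated mean/SD); a true response
profile drawn from the group mixture (sustained elevation / hypotensive /
null); a step trajectory (0 at PRE, a transient bump at 5 min for everyone,
the ±effect at 15 and 30 min for responders); and duplicate replicates with
multiplicative-in-mean noise (SD = CV × latent), truncated at zero and
averaged into the recorded value exactly as duplicate tonometry readings
are averaged at ingest. Defaults mirror the study-like conditions: CAD
baselines 101 (18) / 112 (8) / 70 (6) mmHg with CV 5%, controls 122 (18) /
122 (9) / 77 (7) with CV 4%; central response mixtures 65/12/23% (CAD) and
11/61/28% (controls); brachial mixtures dominated by null profiles; effect
magnitude 10 mmHg (the headline group change), transient bumps 16/7 mmHg
(central) per group. Brachial ordering (bSBP > bDBP) is enforced by a small
floor, a truncation that matters only in the extreme tails.

It deliberately does **not** model: within-participant correlation between
the MOD and HIGH sessions (none is reported; sessions are independent given
the latent baseline), autocorrelated recovery trajectories, medication
effects, HR–BP coupling, or any hemodynamic ODE. Passing recovery tests
therefore shows the *decision rule* behaves correctly under the stated
noise model — not that real recovery dynamics are captured.

Note one deliberate inconsistency inherited from the study conditions: a
65/12/23 mixture of ±10 mmHg effects has a mean true change of ~5 mmHg, not
the 10 mmHg headline group contrast; both numbers are kept as stated rather
than re-calibrated, and group-contrast recovery is therefore checked against
the generator's own expectation, not the headline value.

## Validation harness and problem sizes

`recovery_experiment()` repeatedly generates and classifies cohorts and
tallies true-profile versus called-label confusion. The shipped test suite
uses: exhaustive-search equivalence of the HDI on 100 random samples of up
to 200 draws; 40 replicate samples of 100 000 standard-normal draws for the
closed-form 89% interval (±1.598); 200-seed recovery runs with 4+4
participants per cohort for the separable-effect (13 mmHg vs posterior SD
≤ 0.9 mmHg) and pure-null operating characteristics; and 2000 null
replicates for the Welch type-I rate. These sizes give Monte-Carlo error
comfortably below the asserted margins while keeping the default test run
fast on a laptop.

## Known limitations

- The classifier assumes normal measurement error with a CV that is either
  constant within group or estimable from duplicates; heteroscedastic or
  heavy-tailed tonometry error would widen the undecided band in ways the
  warning bound does not capture.
- `marginal_contrast()` is exactly the mixed-model marginal contrast only
  for complete balanced data.
- The HDI estimator is for unimodal posteriors; for the normal
  measurement-error posterior used here that is always satisfied, but the
  function will happily return the narrowest window of a bimodal sample.
- XLSX input requires readxl; output is CSV only.
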