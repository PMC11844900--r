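# Shared fixtures and independent oracles, built in code at test time.

# Two-participant, fully crossed toy dataset with plausible pressures.
toy_dataset <- function() {
  grid <- expand.grid(
    participant_id = c("p1", "p2"), condition = c("MOD", "HIGH"),
    timepoint = c("PRE", "P5", "P15", "P30"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$participant_id, grid$condition), ]
  n <- nrow(grid)
  study_dataset(
    participants = tibble::tibble(
      participant_id = c("p1", "p2"), group = c("CAD", "CON"),
      age = c(63, 62), sex = c("M", "F")
    ),
    measurements = tibble::tibble(
      participant_id = grid$participant_id,
      condition = grid$condition, timepoint = grid$timepoint,
      hr = 60 + seq_len(n), bsbp = 110 + seq_len(n),
      bdbp = 70 + (seq_len(n) %% 3), csbp = 100 + seq_len(n),
      cfpwv = 8 + 0.1 * seq_len(n)
    )
  )
}

# Exhaustive-search HDI oracle: literal scan over every contiguous window of
# ceiling(mass * n) sorted draws, tracking the minimal width (first minimum
# wins). Deliberately loop-based and independent of the package code path.
hdi_oracle <- function(sample, mass) {
  s <- sort(sample)
  n <- length(s)
  k <- ceiling(mass * n)
  best_i <- 1
  best_w <- Inf
  for (i in seq_len(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best_w) {
      best_w <- w
      best_i <- i
    }
  }
  c(lower = s[best_i], upper = s[best_i + k - 1])
}

# Hand-built dataset in which every participant of every group changes by
# exactly `effect` at 15/30 min (no noise): a deterministic classifier input.
exact_delta_dataset <- function(effect, n_per_group = 3,
                                baselines = c(CAD = 101, CON = 122)) {
  parts <- tibble::tibble(
    participant_id = c(sprintf("cad%02d", seq_len(n_per_group)),
                       sprintf("con%02d", seq_len(n_per_group))),
    group = rep(c("CAD", "CON"), each = n_per_group)
  )
  # Distinct baselines per participant so the group baseline SD is non-zero.
  base <- unname(baselines[parts$group]) + seq_len(nrow(parts)) * 4
  grid <- expand.grid(i = seq_len(nrow(parts)), condition = c("MOD", "HIGH"),
                      timepoint = c("PRE", "P5", "P15", "P30"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  traj <- ifelse(grid$timepoint %in% c("P15", "P30"), effect,
                 ifelse(grid$timepoint == "P5", 8, 0))
  study_dataset(
    participants = parts,
    measurements = tibble::tibble(
      participant_id = parts$participant_id[grid$i],
      condition = grid$condition, timepoint = grid$timepoint,
      hr = 62, bsbp = base[grid$i] + traj + 10,
      bdbp = 70, csbp = base[grid$i] + traj,
      cfpwv = NA_real_
    )
  )
}
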