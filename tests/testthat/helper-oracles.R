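# Independent oracles used across the test files.

# Brute-force Kendall's W, written directly from the printed formula with
# explicitly computed ranks: rank each series, sum ranks per time point,
# W = (sum R_i^2 - n * Rbar^2) / (K^2 (n^3 - n) / 12).
kendall_w_bruteforce <- function(x) {
  n <- nrow(x); K <- ncol(x)
  R <- numeric(n)
  for (k in seq_len(K)) {
    rk <- rank(x[, k])          # average ranks on ties
    for (i in seq_len(n)) R[i] <- R[i] + rk[i]
  }
  rbar <- (n + 1) * K / 2
  s <- 0
  for (i in seq_len(n)) s <- s + R[i]^2
  (s - n * rbar^2) / ((1 / 12) * K^2 * (n^3 - n))
}

# A minimal hand-built 4D scan from a voxel-by-time series matrix placed on
# the given mask (everything else zero).
toy_scan <- function(series, mask, tr = 2) {
  gs <- dim(mask)
  nt <- ncol(series)
  flat <- matrix(0, prod(gs), nt)
  flat[which(mask), ] <- series
  structure(list(data = array(flat, c(gs, nt)), tr = tr, brain_mask = mask,
                 subject_id = "toy", scan_id = "toy", label = "NC"),
            class = "scan4d")
}

# Tiny deterministic cohort + stacks shared by the slower CNN tests; built
# once per test run.
tiny_experiment_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- desk_cohort_config(seed = 7, n_subjects_per_class = 4,
                                amplitude_scale = 2.5, coherence_boost = 0.8)
      cohort <- generate_cohort(cfg)
      stacks <- cohort_map_stacks(cohort)
      cache <<- list(cfg = cfg, cohort = cohort, stacks = stacks,
                     roi = attr(cfg, "roi"))
    }
    cache
  }
})
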