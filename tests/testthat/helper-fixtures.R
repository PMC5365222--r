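# Shared fixtures and independent oracles used across the suite.

# tiny hand-built cohort with two binary and one numeric covariate
tiny_cohort <- function(n = 40, seed = 42, p_event = 0.7) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    trial = rep(c("A", "B"), length.out = n),
    time_days = round(runif(n, 30, 900), 1),
    event = rbinom(n, 1, p_event),
    x1 = rbinom(n, 1, 0.4),
    x2 = rbinom(n, 1, 0.3),
    z = round(rnorm(n), 3))
  if (sum(df$event) == 0) df$event[1] <- 1
  cohort_table(df, c(x1 = "binary", x2 = "binary", z = "numeric"))
}

# brute-force cumulative/dynamic AUC for UNCENSORED data: exhaustive
# Mann-Whitney between {T <= t} and {T > t}
brute_auc_uncensored <- function(risk, time, t) {
  cases <- which(time <= t)
  ctrl <- which(time > t)
  if (!length(cases) || !length(ctrl)) return(NA_real_)
  s <- 0
  for (i in cases) for (j in ctrl)
    s <- s + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  s / (length(cases) * length(ctrl))
}

# brute-force Harrell concordance by exhaustive comparable-pair count
brute_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable iff the earlier time is an observed event
    a <- i; b <- j
    if (time[b] < time[a]) { a <- j; b <- i }
    if (time[a] == time[b]) {
      if (event[a] == 1 && event[b] == 1) next  # tied event times: skip
      if (event[a] == event[b]) next
      # one died, one censored at the same time: death is "earlier"
      if (event[b] == 1) { tmp <- a; a <- b; b <- tmp }
    }
    if (event[a] != 1) next
    den <- den + 1
    num <- num + (risk[a] > risk[b]) + 0.5 * (risk[a] == risk[b])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# small simulated cohort for search / ensemble tests
ci_sim_config <- function(n = 600, ...) {
  per <- c(trial_A = ceiling(n / 3), trial_B = ceiling(n / 3),
           trial_C = n - 2 * ceiling(n / 3))
  sim_config(n_per_trial = per, ...)
}

# generator config matching a sparse-signal selection study:
# 25 binary features, 5 informative (|log HR| >= 0.5), labs pure noise
selection_config <- function() {
  sim_config(
    n_per_trial = c(trial_A = 750, trial_B = 750),
    n_binary = c(mh = 9, pm = 8, met = 8),
    block_betas = list(
      mh = c(0.6, -0.5, 0.55, rep(0, 6)),
      pm = c(0.5, rep(0, 7)),
      met = c(-0.55, rep(0, 7))),
    beta_severity = 0, factor_loading = 0, n_labs = 2, factor_labs = 1,
    interaction = NULL, beta_interaction = 0,
    censoring_target = 0.3, hide_lesion_sizes_in = NULL)
}

informative_features <- c("mh_01", "mh_02", "mh_03", "pm_01", "met_01")

fast_config <- function(...) {
  search_config(reps_screen = 40, reps_full = 120, top_k = 8,
                max_iterations = 4, ...)
}
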