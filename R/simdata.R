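#' Configuration of the synthetic multi-trial cohort generator
#'
#' Describes a simulated multi-trial oncology cohort with the
#' statistical structure the pipeline is designed for: several trials;
#' three blocks of binary covariates (medical history, prior
#' medication, metastasis sites) with sparse true log-hazards; a latent
#' disease-severity factor that drives a designated subset of the
#' laboratory values and enters the hazard directly (so the first lab
#' principal component is prognostic); lesion counts and sizes feeding
#' target lesion volume, with one trial hiding lesion sizes to exercise
#' the imputation path; a Cox-Weibull event-time model including one
#' pairwise interaction; and independent exponential censoring
#' calibrated to a target censoring fraction.
#'
#' @param n_per_trial named integer vector, patients per trial
#'   (>= 2 trials).
#' @param n_binary named integer vector, features per binary block.
#' @param block_betas list of per-block log-hazard vectors (sparse;
#'   defaults put a few effects of |log HR| 0.3-0.5 per block).
#' @param binary_prev Bernoulli prevalence of the binary features.
#' @param n_labs number of laboratory columns.
#' @param factor_labs how many of the first labs load on the severity
#'   factor.
#' @param factor_loading loading of those labs on the factor.
#' @param lab_noise_sd residual lab noise standard deviation.
#' @param beta_severity log-hazard per unit of the latent severity
#'   factor.
#' @param interaction length-2 character vector of binary feature
#'   names interacting in the hazard (NULL = none).
#' @param beta_interaction log-hazard of the interaction product.
#' @param lesion_mean Poisson mean of the per-patient lesion count
#'   (log-mean shifted by 0.25 x severity so lesion burden is
#'   prognostic).
#' @param lesion_meanlog,lesion_sdlog log-normal lesion size
#'   parameters.
#' @param bone_prob probability a lesion is a bone lesion.
#' @param weibull_shape,weibull_scale baseline Weibull parameters
#'   (days).
#' @param censoring_target target censoring fraction in (0,1).
#' @param hide_lesion_sizes_in trial label whose lesion sizes are set
#'   missing (NULL = none).
#' @return a `sim_config` list.
#' @export
sim_config <- function(
    n_per_trial = c(trial_A = 500, trial_B = 550, trial_C = 550),
    n_binary = c(mh = 12, pm = 10, met = 8),
    block_betas = NULL,
    binary_prev = 0.3,
    n_labs = 10, factor_labs = 6, factor_loading = 0.8,
    lab_noise_sd = 0.6,
    beta_severity = 0.8,
    interaction = c("mh_01", "met_01"), beta_interaction = 0.35,
    lesion_mean = 3, lesion_meanlog = 0.8, lesion_sdlog = 0.5,
    bone_prob = 0.35,
    weibull_shape = 1.2, weibull_scale = 900,
    censoring_target = 0.35,
    hide_lesion_sizes_in = "trial_A") {
  stopifnot(length(n_per_trial) >= 2, all(n_per_trial >= 1),
            length(n_binary) == 3, all(n_binary >= 1),
            n_labs >= 2, factor_labs >= 1, factor_labs <= n_labs,
            censoring_target > 0, censoring_target < 1,
            weibull_shape > 0, weibull_scale > 0)
  if (is.null(names(n_per_trial)))
    names(n_per_trial) <- paste0("trial_", LETTERS[seq_along(n_per_trial)])
  if (is.null(names(n_binary))) names(n_binary) <- c("mh", "pm", "met")
  if (is.null(block_betas)) {
    mk <- function(k, eff) { b <- numeric(k); b[seq_along(eff)] <- eff; b }
    block_betas <- list(
      mh = mk(n_binary[[1]], c(0.45, -0.40, 0.30)),
      pm = mk(n_binary[[2]], c(0.35, -0.30)),
      met = mk(n_binary[[3]], c(0.50, 0.30)))
  }
  names(block_betas) <- names(n_binary)
  stopifnot(all(lengths(block_betas) == n_binary))
  if (!is.null(hide_lesion_sizes_in) &&
      !hide_lesion_sizes_in %in% names(n_per_trial))
    stop("`hide_lesion_sizes_in` must name a trial", call. = FALSE)
  structure(as.list(environment())[c(
    "n_per_trial", "n_binary", "block_betas", "binary_prev", "n_labs",
    "factor_labs", "factor_loading", "lab_noise_sd", "beta_severity",
    "interaction", "beta_interaction", "lesion_mean", "lesion_meanlog",
    "lesion_sdlog", "bone_prob", "weibull_shape", "weibull_scale",
    "censoring_target", "hide_lesion_sizes_in")],
    class = "sim_config")
}

binary_feature_names <- function(config) {
  unlist(lapply(names(config$n_binary), function(b)
    sprintf("%s_%02d", b, seq_len(config$n_binary[[b]]))),
    use.names = FALSE)
}

#' Generate a synthetic multi-trial cohort
#'
#' Draws a cohort under the model described in [sim_config()]: a
#' standard-normal latent severity factor per patient; binary blocks
#' with the configured sparse log-hazards; labs generated as
#' `loading x severity + noise` for the designated subset (pure noise
#' otherwise); event times from a Weibull baseline with proportional
#' hazard `exp(eta)`; independent exponential censoring whose rate is
#' calibrated by root finding so the realised censoring fraction
#' matches the target; and a lesion table whose sizes are hidden for
#' the designated trial. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `cohort` (a [cohort_table()]), `lesions` (a
#'   [lesion_table()]), `schema`, and `truth` (true coefficient list,
#'   per-patient linear predictor `eta`, severity factor, censoring
#'   details).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- sum(config$n_per_trial)
  trial <- rep(names(config$n_per_trial), config$n_per_trial)
  pid <- sprintf("P%05d", seq_len(n))
  severity <- rnorm(n)

  bnames <- binary_feature_names(config)
  B <- matrix(rbinom(n * length(bnames), 1, config$binary_prev), n,
              dimnames = list(NULL, bnames))
  beta_bin <- setNames(unlist(config$block_betas, use.names = FALSE),
                       bnames)

  labs <- matrix(rnorm(n * config$n_labs, sd = config$lab_noise_sd), n)
  colnames(labs) <- sprintf("lab_%02d", seq_len(config$n_labs))
  loaded <- colnames(labs)[seq_len(config$factor_labs)]
  labs[, loaded] <- labs[, loaded] + config$factor_loading * severity

  eta <- config$beta_severity * severity + drop(B %*% beta_bin)
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    if (!all(ia %in% bnames))
      stop("interaction features not in binary blocks: ",
           paste(setdiff(ia, bnames), collapse = ", "), call. = FALSE)
    eta <- eta + config$beta_interaction * B[, ia[1]] * B[, ia[2]]
  }

  # Cox-Weibull event times: S(t|x) = exp(-(t/scale)^shape * exp(eta))
  u <- runif(n)
  t_event <- config$weibull_scale *
    (-log(u) / exp(eta))^(1 / config$weibull_shape)
  cens <- calibrate_censoring(t_event, config$censoring_target)
  time_days <- pmax(pmin(t_event, cens$c_times), 0.5)
  event <- as.numeric(t_event <= cens$c_times)

  age <- pmin(pmax(round(rnorm(n, 70, 8)), 45), 92)
  race <- sample(c("white", "black", "asian", "other"), n, TRUE,
                 prob = c(0.75, 0.12, 0.08, 0.05))
  ecog <- findInterval(severity + rnorm(n, sd = 0.8),
                       c(-0.3, 1.2))  # 0/1/2, worse with severity

  lesion_n <- rpois(n, exp(log(config$lesion_mean) + 0.25 * severity))
  les <- data.frame(
    patient_id = rep(pid, lesion_n),
    size = rlnorm(sum(lesion_n), config$lesion_meanlog,
                  config$lesion_sdlog),
    is_bone = rbinom(sum(lesion_n), 1, config$bone_prob))
  if (!is.null(config$hide_lesion_sizes_in)) {
    hidden <- rep(trial, lesion_n) == config$hide_lesion_sizes_in
    les$size[hidden] <- NA_real_
  }

  df <- data.frame(patient_id = pid, trial = trial,
                   time_days = time_days, event = event,
                   age = age, race = race, ecog = ecog,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(B), as.data.frame(labs))
  schema <- c(age = "numeric", race = "categorical", ecog = "ordinal",
              setNames(rep("binary", length(bnames)), bnames),
              setNames(rep("numeric", ncol(labs)), colnames(labs)))
  list(cohort = cohort_table(df, schema),
       lesions = lesion_table(les),
       schema = schema,
       truth = list(beta_binary = beta_bin,
                    beta_severity = config$beta_severity,
                    interaction = config$interaction,
                    beta_interaction = config$beta_interaction,
                    eta = setNames(eta, pid),
                    severity = setNames(severity, pid),
                    loaded_labs = loaded,
                    censoring_rate = cens$rate,
                    censoring_realized = mean(event == 0),
                    config = config))
}

# exponential censoring rate r with E[1 - exp(-r T)] = target
calibrate_censoring <- function(t_event, target) {
  f <- function(lr) mean(1 - exp(-exp(lr) * t_event)) - target
  lo <- log(1e-8); hi <- log(1)
  while (f(hi) < 0 && hi < log(1e6)) hi <- hi + 1
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "cannot calibrate censoring to %.2f (achievable range ends at %.3f)",
      target, mean(1 - exp(-exp(hi) * t_event))), call. = FALSE)
  rate <- exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
  list(rate = rate, c_times = rexp(length(t_event), rate))
}

#' Reference performance of the true linear predictor
#'
#' Evaluates the generator's true per-patient log-hazard on the
#' generated outcome - the performance ceiling any fitted model can be
#' compared against.
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param cohort the matching [cohort_table()].
#' @param grid a [time_grid()].
#' @return list with `iAUC` and `c_index` of the true predictor.
#' @export
truth_metrics <- function(truth, cohort, grid = time_grid()) {
  outcome <- as_surv_outcome(cohort)
  eta <- truth$eta[cohort$patient_id]
  list(iAUC = integrated_auc(eta, outcome, grid),
       c_index = concordance_index(eta, outcome))
}
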