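#' Weighted ensemble of fitted Cox models
#'
#' Combines several fitted Cox models into one risk score: a weighted
#' sum of the members' linear predictors, with weights on the
#' probability simplex (nonnegative, summing to 1; equal by default).
#' Because linear predictors from different specifications live on
#' incomparable scales, member risks are z-standardised across the
#' scored cohort before weighting unless `standardize` is turned off.
#'
#' @param members list of converged `fitted_cox_model`s.
#' @param weights nonnegative weights, one per member (default equal);
#'   rescaled to sum to 1.
#' @param standardize z-standardise member risks before weighting.
#' @return an `ensemble_model`.
#' @export
ensemble_model <- function(members, weights = NULL, standardize = TRUE) {
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, TRUE, "fitted_cox_model")))
  if (!all(vapply(members, function(m) m$converged, TRUE)))
    stop("all ensemble members must have converged", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(members),
                                       length(members))
  weights <- as.numeric(weights)
  if (length(weights) != length(members))
    stop("need one weight per member", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  weights <- weights / sum(weights)
  structure(list(members = members, weights = weights,
                 standardize = standardize),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, weights: %s%s\n",
              length(x$members),
              paste(round(x$weights, 3), collapse = ", "),
              if (x$standardize) " (standardised members)" else ""))
  invisible(x)
}

#' Ensemble risk scores
#'
#' `risk(i) = sum_m w_m * r_m(i)` where `r_m` is member m's linear
#' predictor on the cohort (z-standardised across the cohort when the
#' ensemble was built with `standardize = TRUE`).
#'
#' @param ens an [ensemble_model()].
#' @param cohort a [cohort_table()] covering every member's covariates.
#' @return named numeric vector of risk scores.
#' @export
ensemble_risk <- function(ens, cohort) {
  stopifnot(inherits(ens, "ensemble_model"))
  risks <- vapply(seq_along(ens$members), function(m) {
    r <- tryCatch(predict_risk(ens$members[[m]], cohort),
                  error = function(e)
                    stop("member ", m, " failed to predict: ",
                         conditionMessage(e), call. = FALSE))
    if (ens$standardize) {
      s <- sd(r)
      if (s > 0) r <- (r - mean(r)) / s
    }
    r
  }, numeric(nrow(cohort)))
  setNames(drop(as.matrix(risks) %*% ens$weights), cohort$patient_id)
}

# uniform draw from the probability simplex
rsimplex <- function(k) {
  e <- rexp(k)
  e / sum(e)
}

#' Search ensemble weights by random initialisation
#'
#' Draws `n_init` random weight vectors from the probability simplex
#' (the equal-weight vector is always evaluated as well) and scores
#' each by Monte-Carlo cross-validated performance of the combined
#' risk: on every random split the member specifications are refitted
#' on the estimation subset and their held-out risks combined under
#' each candidate weighting, so all weight vectors are compared on the
#' same splits. Ties are broken in favour of the equal-weight vector.
#'
#' @param members list of converged `fitted_cox_model`s (their
#'   specifications are refitted per split).
#' @param cohort a [cohort_table()].
#' @param config a [search_config()]; supplies the criterion, grid,
#'   train fraction and seed.
#' @param n_init number of random weight draws (0 = evaluate only the
#'   equal-weight vector).
#' @param n_reps Monte-Carlo splits used for scoring.
#' @param standardize z-standardise member risks within each split.
#' @return list with `weights` (best vector), `mean_metric`, and
#'   `table` (all evaluated vectors with their scores, best first).
#' @export
search_weights <- function(members, cohort, config = search_config(),
                           n_init = 100, n_reps = config$reps_screen,
                           standardize = TRUE) {
  stopifnot(length(members) >= 2)
  nm <- length(members)
  outcome <- as_surv_outcome(cohort)
  n <- nrow(cohort)
  designs <- lapply(members, function(m) {
    d <- build_design(m$spec, cohort, xlev = m$xlev)
    sweep(d$X, 2, colMeans(d$X))
  })
  splits <- make_splits(n, round(config$train_fraction * n), n_reps,
                        config$seed)
  W <- rbind(rep(1 / nm, nm),
             if (n_init > 0)
               with_seed(config$seed + 1L,
                         t(replicate(n_init, rsimplex(nm)))))
  vals <- matrix(NA_real_, nrow(W), n_reps)
  for (r in seq_len(n_reps)) {
    tr <- splits[[r]]
    te <- seq_len(n)[-tr]
    R <- matrix(NA_real_, length(te), nm)
    ok <- TRUE
    for (m in seq_len(nm)) {
      fit <- cpp_coxfit(designs[[m]][tr, , drop = FALSE],
                        outcome$time[tr], outcome$event[tr])
      if (!isTRUE(fit$converged)) { ok <- FALSE; break }
      rm_ <- drop(designs[[m]][te, , drop = FALSE] %*% fit$coef)
      if (standardize && sd(rm_) > 0) rm_ <- (rm_ - mean(rm_)) / sd(rm_)
      R[, m] <- rm_
    }
    if (!ok) next
    ote <- outcome_subset(outcome, te)
    for (w in seq_len(nrow(W)))
      vals[w, r] <- eval_metric(drop(R %*% W[w, ]), ote, config)
  }
  means <- rowMeans(vals, na.rm = TRUE)
  if (all(is.na(means)))
    stop("all weight evaluations failed", call. = FALSE)
  ord <- order(means, decreasing = TRUE)
  # stable order: the equal-weight row (index 1) wins exact ties
  best <- ord[1]
  ties <- which(means == means[best])
  if (1 %in% ties) best <- 1L
  tab <- data.frame(W[ord, , drop = FALSE])
  names(tab) <- paste0("w", seq_len(nm))
  tab$mean_metric <- means[ord]
  list(weights = as.numeric(W[best, ]), mean_metric = means[best],
       table = tab)
}
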