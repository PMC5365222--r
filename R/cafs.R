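#' Configuration of a CAFS model search
#'
#' Bundles the tunable parameters of the curated ad-hoc feature
#' selection loop. Defaults follow the published schedule: two-thirds of
#' patients for parameter estimation in each Monte-Carlo split, 500
#' cross-validation repetitions when screening the many forward
#' candidates, 10,000 repetitions for definitive performance estimates,
#' the top 30 screened candidates re-estimated at the full schedule, and
#' termination once the best candidate improves the criterion by less
#' than `improvement_tol` (0.001 iAUC operationalises "marginal").
#'
#' @param train_fraction fraction of patients in the estimation subset.
#' @param reps_screen Monte-Carlo repetitions for candidate screening.
#' @param reps_full repetitions for definitive estimates
#'   (`reps_screen <= reps_full`).
#' @param top_k screened candidates promoted to rescreening.
#' @param improvement_tol minimal criterion gain to keep expanding.
#' @param max_iterations hard stop on search iterations.
#' @param seed integer; every random split derives from it.
#' @param metric optimisation criterion, `"iAUC"` or `"cIndex"`, or a
#'   function `(risk, outcome) -> scalar` for a custom criterion.
#' @param grid [time_grid()] for the iAUC.
#' @param shared_split_seeds reuse the same splits for every candidate
#'   within a screening round (paired comparison, lower variance).
#' @param complexity_penalty lambda in `mean - lambda * n_terms`, a
#'   guard against the interaction-selection bias of greedy searches
#'   (default 0: plain criterion).
#' @return a `search_config` list.
#' @export
search_config <- function(train_fraction = 2 / 3, reps_screen = 500,
                          reps_full = 10000, top_k = 30,
                          improvement_tol = 0.001, max_iterations = 20,
                          seed = 1L, metric = c("iAUC", "cIndex"),
                          grid = time_grid(), shared_split_seeds = TRUE,
                          complexity_penalty = 0) {
  metric_fn <- NULL
  if (is.function(metric)) {
    metric_fn <- metric
    metric <- "custom"
  } else {
    metric <- match.arg(metric)
  }
  stopifnot(train_fraction > 0, train_fraction < 1,
            reps_screen >= 1, reps_full >= reps_screen, top_k >= 1,
            improvement_tol >= 0, max_iterations >= 1,
            complexity_penalty >= 0, inherits(grid, "time_grid"))
  structure(list(train_fraction = train_fraction,
                 reps_screen = as.integer(reps_screen),
                 reps_full = as.integer(reps_full),
                 top_k = as.integer(top_k),
                 improvement_tol = improvement_tol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), metric = metric,
                 metric_fn = metric_fn, grid = grid,
                 shared_split_seeds = shared_split_seeds,
                 complexity_penalty = complexity_penalty),
            class = "search_config")
}

# evaluate the configured criterion on held-out risks; NA = failed split
eval_metric <- function(risk, outcome, config) {
  tryCatch(
    if (!is.null(config$metric_fn)) config$metric_fn(risk, outcome)
    else if (config$metric == "iAUC")
      integrated_auc(risk, outcome, config$grid)
    else concordance_index(risk, outcome),
    error = function(e) NA_real_)
}

outcome_subset <- function(outcome, idx) {
  structure(list(time = outcome$time[idx], event = outcome$event[idx]),
            class = "surv_outcome")
}

# deterministic train-index list; RNG state is restored afterwards
make_splits <- function(n, n_train, n_reps, seed) {
  with_seed(seed, replicate(n_reps, sample.int(n, n_train),
                            simplify = FALSE))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# inner CV loop on a prebuilt design matrix
mc_cv_core <- function(X, outcome, splits, config) {
  n <- length(outcome$time)
  vals <- rep(NA_real_, length(splits))
  empty <- ncol(X) == 0
  for (r in seq_along(splits)) {
    tr <- splits[[r]]
    te <- seq_len(n)[-tr]
    if (empty) {
      risk <- numeric(length(te))
    } else {
      fit <- cpp_coxfit(X[tr, , drop = FALSE], outcome$time[tr],
                        outcome$event[tr])
      if (!isTRUE(fit$converged)) next
      risk <- drop(X[te, , drop = FALSE] %*% fit$coef)
    }
    vals[r] <- eval_metric(risk, outcome_subset(outcome, te), config)
  }
  vals
}

#' Monte-Carlo cross-validated performance of one model specification
#'
#' Repeatedly splits the cohort at random into an estimation subset
#' (`train_fraction`, unstratified) and an evaluation subset, fits the
#' spec's Cox model on the first, predicts risk on the second and
#' computes the configured criterion there. The mean over successful
#' repetitions is the performance estimate; splits whose fit fails to
#' converge (or whose criterion is undefined) count as failed and are
#' excluded. Fully reproducible from `seed`. An empty spec scores a
#' constant risk, i.e. criterion 0.5.
#'
#' @param spec a [model_spec()].
#' @param cohort a [cohort_table()].
#' @param n_reps number of random splits.
#' @param config a [search_config()].
#' @param seed split seed (default `config$seed`).
#' @return a `cv_result`: `spec`, `mean_metric`, `sd_metric`, `n_reps`,
#'   `n_failed`.
#' @export
mc_cv <- function(spec, cohort, n_reps, config = search_config(),
                  seed = config$seed) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort_table"))
  outcome <- as_surv_outcome(cohort)
  X <- if (n_spec_terms(spec) == 0)
    matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  else {
    d <- build_design(spec, cohort)
    sweep(d$X, 2, colMeans(d$X))
  }
  n <- nrow(cohort)
  splits <- make_splits(n, round(config$train_fraction * n), n_reps, seed)
  vals <- if (config$metric == "iAUC" && is.null(config$metric_fn) &&
              ncol(X) > 0) {
    # fused compiled loop; splits and results identical to mc_cv_core
    full <- cpp_coxfit(X, outcome$time, outcome$event)
    beta0 <- if (isTRUE(full$converged)) as.numeric(full$coef)
             else numeric(ncol(X))
    as.numeric(cpp_screen_iauc(
      list(X), outcome$time, outcome$event, do.call(cbind, splits),
      config$grid$t_lo, config$grid$t_hi,
      config$grid$eval_times %||% numeric(0), list(beta0)))
  } else {
    mc_cv_core(X, outcome, splits, config)
  }
  cv_result(spec, vals)
}

# Evaluate many candidate specs on shared splits in one compiled pass
# (iAUC criterion); falls back to per-spec mc_cv otherwise. Returns a
# list of cv_result, dropping candidates whose every split failed.
screen_specs <- function(specs, cohort, n_reps, config, seed) {
  if (!length(specs)) return(list())
  fast <- config$metric == "iAUC" && is.null(config$metric_fn) &&
    config$shared_split_seeds
  if (!fast) {
    out <- lapply(seq_along(specs), function(k) {
      s <- if (config$shared_split_seeds) seed else seed + k
      tryCatch(mc_cv(specs[[k]], cohort, n_reps, config, seed = s),
               error = function(e) NULL)
    })
    return(Filter(Negate(is.null), out))
  }
  outcome <- as_surv_outcome(cohort)
  designs <- lapply(specs, function(s) {
    if (n_spec_terms(s) == 0) return(NULL)
    tryCatch({
      d <- build_design(s, cohort)
      sweep(d$X, 2, colMeans(d$X))
    }, error = function(e) NULL)
  })
  keep <- !vapply(designs, is.null, TRUE)
  empty <- vapply(specs, n_spec_terms, 0L) == 0
  res <- vector("list", length(specs))
  if (any(keep)) {
    b0 <- lapply(designs[keep], function(X) {
      full <- cpp_coxfit(X, outcome$time, outcome$event)
      if (isTRUE(full$converged)) as.numeric(full$coef)
      else numeric(ncol(X))
    })
    n <- nrow(cohort)
    splits <- make_splits(n, round(config$train_fraction * n), n_reps,
                          seed)
    vals <- cpp_screen_iauc(
      designs[keep], outcome$time, outcome$event,
      do.call(cbind, splits), config$grid$t_lo, config$grid$t_hi,
      config$grid$eval_times %||% numeric(0), b0)
    ki <- which(keep)
    for (j in seq_along(ki)) {
      res[[ki[j]]] <- tryCatch(cv_result(specs[[ki[j]]], vals[, j]),
                               error = function(e) NULL)
    }
  }
  for (k in which(empty)) {
    res[[k]] <- tryCatch(mc_cv(specs[[k]], cohort, n_reps, config,
                               seed = seed), error = function(e) NULL)
  }
  Filter(Negate(is.null), res)
}

cv_result <- function(spec, vals) {
  ok <- !is.na(vals)
  if (!any(ok))
    stop("all CV repetitions failed for ", format(spec), call. = FALSE)
  structure(list(spec = spec, mean_metric = mean(vals[ok]),
                 sd_metric = if (sum(ok) > 1) sd(vals[ok]) else 0,
                 n_reps = length(vals), n_failed = sum(!ok)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s\n  mean = %.4f (sd %.4f, %d reps, %d failed)\n",
              format(x$spec), x$mean_metric, x$sd_metric, x$n_reps,
              x$n_failed))
  invisible(x)
}

# criterion used for ranking: optional complexity penalty
cv_score <- function(res, config) {
  res$mean_metric - config$complexity_penalty * n_spec_terms(res$spec)
}

#' Backward candidate models
#'
#' One candidate per removable term of the spec: dropping an
#' interaction removes just that pair; dropping a main effect also
#' removes every interaction containing it (hierarchy preserved). The
#' number of candidates equals the number of main effects plus the
#' number of interaction terms.
#'
#' @param spec a [model_spec()].
#' @return list of `model_spec` (empty for an empty spec).
#' @export
backward_candidates <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- list()
  for (m in spec$main) {
    keep_int <- Filter(function(p) !(m %in% p), spec$interactions)
    out[[length(out) + 1]] <-
      model_spec(setdiff(spec$main, m), keep_int, spec$exclude)
  }
  for (i in seq_along(spec$interactions)) {
    out[[length(out) + 1]] <-
      model_spec(spec$main, spec$interactions[-i], spec$exclude)
  }
  out
}

#' Forward candidate models
#'
#' For every new feature `f` in the feature space: one base candidate
#' adding `f` as a main effect, plus one candidate per existing main
#' term `m` adding both `f` and the interaction `f:m`. The total
#' candidate count is `|F| * (1 + number of existing main terms)`.
#' Features already in the spec or listed in `spec$exclude` never
#' appear.
#'
#' @param spec a [model_spec()].
#' @param feature_space character vector of candidate covariate names.
#' @return list of `model_spec`.
#' @export
forward_candidates <- function(spec, feature_space) {
  stopifnot(inherits(spec, "model_spec"))
  feature_space <- setdiff(feature_space, c(spec$main, spec$exclude))
  out <- list()
  for (f in feature_space) {
    base_main <- c(spec$main, f)
    out[[length(out) + 1]] <-
      model_spec(base_main, spec$interactions, spec$exclude)
    for (m in spec$main) {
      out[[length(out) + 1]] <-
        model_spec(base_main, c(spec$interactions, list(c(f, m))),
                   spec$exclude)
    }
  }
  out
}

#' Re-estimate the top screened candidates at the full CV schedule
#'
#' Screening at few repetitions is noisy; the `top_k` candidates by
#' screened mean are re-evaluated at `reps_full` repetitions with fresh
#' splits and returned re-ranked (best first). Fewer than `top_k`
#' candidates are all rescreened.
#'
#' @param results list of `cv_result` from screening.
#' @param cohort the cohort the candidates were screened on.
#' @param config a [search_config()].
#' @param seed split seed for the rescreen (fresh by default).
#' @return list of `cv_result`, sorted by decreasing mean.
#' @export
rescreen_top <- function(results, cohort, config = search_config(),
                         seed = config$seed + 1L) {
  if (!length(results)) return(list())
  sc <- vapply(results, cv_score, numeric(1), config = config)
  keep <- order(sc, decreasing = TRUE)[seq_len(min(config$top_k,
                                                   length(results)))]
  resc <- screen_specs(lapply(results[keep], `[[`, "spec"), cohort,
                       config$reps_full, config, seed)
  sc2 <- vapply(resc, cv_score, numeric(1), config = config)
  resc[order(sc2, decreasing = TRUE)]
}

#' Default automatic curator
#'
#' Stands in for the panel of researchers who, in the original
#' procedure, nominated the best current model at each iteration and
#' decided whether to expand, shrink or stop. The automatic rule:
#' choose the candidate with the highest (penalty-adjusted) mean
#' criterion; expand while it beats the current best by at least
#' `improvement_tol`; otherwise request a shrink pass; a custom curator
#' with the same signature can veto candidates or stop early.
#'
#' @param best current best `cv_result`.
#' @param candidates rescreened forward candidates (list of
#'   `cv_result`, best first).
#' @param trace iterations recorded so far.
#' @param config the [search_config()].
#' @return list with `action` (`"expand"`, `"shrink"` or
#'   `"terminate"`), `chosen` (index into `candidates` when expanding)
#'   and `rationale` (free text recorded in the trace).
#' @export
curator_greedy <- function(best, candidates, trace, config) {
  if (!length(candidates))
    return(list(action = "shrink", chosen = NA_integer_,
                rationale = "no forward candidates"))
  gain <- cv_score(candidates[[1]], config) - cv_score(best, config)
  if (gain >= config$improvement_tol)
    list(action = "expand", chosen = 1L,
         rationale = sprintf("best candidate gains %.4f", gain))
  else
    list(action = "shrink", chosen = NA_integer_,
         rationale = sprintf("best forward gain %.4f below tolerance",
                             gain))
}

candidate_table <- function(results, config) {
  if (!length(results))
    return(data.frame(spec = character(), mean_metric = numeric(),
                      sd_metric = numeric(), n_failed = integer()))
  data.frame(
    spec = vapply(results, function(r) format(r$spec), ""),
    mean_metric = vapply(results, function(r) r$mean_metric, 0),
    sd_metric = vapply(results, function(r) r$sd_metric, 0),
    n_failed = vapply(results, function(r) r$n_failed, 0L),
    stringsAsFactors = FALSE)
}

#' Curated ad-hoc feature selection search
#'
#' The greedy model search: starting from an initial specification,
#' each iteration screens every forward candidate
#' ([forward_candidates()]) at `reps_screen` Monte-Carlo repetitions,
#' re-estimates the top `top_k` at `reps_full` ([rescreen_top()]), and
#' hands the ranked candidates to the curator. The curator either
#' expands (adopts a candidate), requests a shrink pass - backward
#' candidates ([backward_candidates()]) evaluated at `reps_full`, the
#' best adopted if it strictly improves on the current best - or
#' terminates. The search stops when neither expanding nor shrinking
#' improves the criterion, or after `max_iterations`. Within a
#' screening round all candidates share the same splits when
#' `shared_split_seeds` is set. The whole run is reproducible from
#' `config$seed`.
#'
#' @param initial a fittable [model_spec()] (may be empty: the search
#'   then starts from the constant-risk baseline at criterion 0.5).
#' @param cohort a [cohort_table()].
#' @param feature_space covariate names the search may draw from.
#' @param config a [search_config()].
#' @param curator decision hook with the signature of
#'   [curator_greedy()].
#' @return list with `spec` (final [model_spec()]), `result` (its
#'   `cv_result` at `reps_full`) and `trace` (a `cafs_trace`).
#' @export
cafs_search <- function(initial, cohort, feature_space,
                        config = search_config(),
                        curator = curator_greedy) {
  stopifnot(inherits(initial, "model_spec"),
            inherits(cohort, "cohort_table"))
  feature_space <- setdiff(feature_space, initial$exclude)
  seed0 <- config$seed
  best <- mc_cv(initial, cohort, config$reps_full, config, seed = seed0)
  trace <- list()
  shrunk_since_expand <- FALSE
  for (iter in seq_len(config$max_iterations)) {
    iter_seed <- (seed0 + 7919L * iter) %% 2147483629L
    space <- setdiff(feature_space, best$spec$main)
    fc <- forward_candidates(best$spec, space)
    screened <- screen_specs(fc, cohort, config$reps_screen, config,
                             seed = iter_seed)
    resc <- rescreen_top(screened, cohort, config, seed = iter_seed + 1L)
    decision <- curator(best, resc, trace, config)
    it_rec <- list(iteration = iter, action = decision$action,
                   candidates = candidate_table(resc, config),
                   n_forward = length(fc),
                   n_space = length(space),
                   n_mains = length(best$spec$main),
                   chosen = NA_character_,
                   rationale = decision$rationale %||% "")
    if (identical(decision$action, "expand") &&
        length(resc) >= decision$chosen) {
      best <- resc[[decision$chosen]]
      it_rec$chosen <- format(best$spec)
      trace[[length(trace) + 1]] <- it_rec
      shrunk_since_expand <- FALSE
      next
    }
    if (identical(decision$action, "shrink")) {
      bc <- backward_candidates(best$spec)
      bres <- screen_specs(bc, cohort, config$reps_full, config,
                           seed = iter_seed + 2L)
      if (length(bres)) {
        sc <- vapply(bres, cv_score, numeric(1), config = config)
        cand <- bres[[which.max(sc)]]
        if (cv_score(cand, config) > cv_score(best, config)) {
          best <- cand
          it_rec$action <- "shrink"
          it_rec$chosen <- format(best$spec)
          it_rec$candidates <- rbind(it_rec$candidates,
                                     candidate_table(bres, config))
          trace[[length(trace) + 1]] <- it_rec
          shrunk_since_expand <- TRUE
          next
        }
      }
      it_rec$action <- "terminate"
      it_rec$chosen <- format(best$spec)
      trace[[length(trace) + 1]] <- it_rec
      break
    }
    if (identical(decision$action, "terminate")) {
      it_rec$chosen <- format(best$spec)
      trace[[length(trace) + 1]] <- it_rec
      break
    }
  }
  if (!length(trace) ||
      !identical(trace[[length(trace)]]$action, "terminate")) {
    trace[[length(trace) + 1]] <-
      list(iteration = length(trace) + 1, action = "terminate",
           candidates = candidate_table(list(), config),
           chosen = format(best$spec),
           rationale = "iteration limit reached")
  }
  structure(list(spec = best$spec, result = best,
                 trace = structure(trace, class = "cafs_trace")),
            class = "cafs_fit")
}

#' @export
print.cafs_fit <- function(x, ...) {
  cat("CAFS search result\n  final:", format(x$spec), "\n")
  cat(sprintf("  criterion = %.4f over %d iterations\n",
              x$result$mean_metric, length(x$trace)))
  invisible(x)
}

#' @export
print.cafs_trace <- function(x, ...) {
  for (it in x) {
    cat(sprintf("[%d] %-9s %s (%d candidates)\n", it$iteration,
                it$action, it$chosen, nrow(it$candidates)))
  }
  invisible(x)
}

#' Branching CAFS searches for ensemble member diversity
#'
#' Runs an independent seeded [cafs_search()] per branch - different
#' initial models and/or per-branch feature exclusions - mirroring how
#' distinct ensemble members are obtained by branching the selection
#' path. Failures are reported per branch without aborting the others;
#' branches converging to the same final spec are deduplicated with a
#' warning.
#'
#' @param initials list of initial [model_spec()]s, one per branch.
#' @param cohort a [cohort_table()].
#' @param feature_space shared candidate covariate names.
#' @param config a [search_config()].
#' @param exclusions optional list (per branch) of covariate names
#'   banned in that branch.
#' @param seeds per-branch seeds (default `config$seed + 0:(B-1)`).
#' @param curator decision hook, as in [cafs_search()].
#' @return list of `cafs_fit` objects (deduplicated); branch errors are
#'   attached as attribute `"failures"`.
#' @export
branch_search <- function(initials, cohort, feature_space,
                          config = search_config(), exclusions = NULL,
                          seeds = NULL, curator = curator_greedy) {
  nb <- length(initials)
  if (is.null(seeds)) seeds <- config$seed + seq_len(nb) - 1L
  stopifnot(length(seeds) == nb,
            is.null(exclusions) || length(exclusions) == nb)
  fits <- list(); failures <- list()
  for (b in seq_len(nb)) {
    init <- initials[[b]]
    if (!is.null(exclusions) && length(exclusions[[b]]))
      init <- model_spec(init$main, init$interactions,
                         union(init$exclude, exclusions[[b]]))
    cfg <- config
    cfg$seed <- as.integer(seeds[b])
    res <- tryCatch(
      cafs_search(init, cohort, feature_space, cfg, curator = curator),
      error = function(e) e)
    if (inherits(res, "error")) failures[[as.character(b)]] <- res
    else fits[[length(fits) + 1]] <- res
  }
  keys <- vapply(fits, function(f) spec_key(f$spec), "")
  if (anyDuplicated(keys)) {
    warning("deduplicated ", sum(duplicated(keys)),
            " branch(es) with identical final specs", call. = FALSE)
    fits <- fits[!duplicated(keys)]
  }
  if (length(failures))
    warning(length(failures), " branch(es) failed", call. = FALSE)
  attr(fits, "failures") <- failures
  fits
}
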