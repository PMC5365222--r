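#' Build the design matrix for a model specification
#'
#' Expands a [model_spec()] against a cohort: categorical covariates
#' become reference-coded indicator columns (first level is the
#' reference), ordinal/numeric/binary covariates enter as-is, and an
#' interaction pair expands to all element-wise products of the two
#' members' expanded columns. Column order is deterministic: main terms
#' in spec order, then interactions in spec order.
#'
#' @param spec a [model_spec()].
#' @param cohort a [cohort_table()].
#' @param xlev optional named list of factor levels recorded at fit time;
#'   supply at predict time so coding matches training. Unseen levels
#'   raise an error.
#' @return list with `X` (numeric matrix), `xlev` (levels used for
#'   categorical terms).
#' @export
build_design <- function(spec, cohort, xlev = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort_table"))
  schema <- attr(cohort, "schema")
  unknown <- setdiff(spec$main, names(schema))
  if (length(unknown))
    stop("spec names not in cohort covariates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  na_cols <- spec$main[vapply(spec$main, function(cv) anyNA(cohort[[cv]]),
                              logical(1))]
  if (length(na_cols))
    stop("missing values in used column(s): ",
         paste(na_cols, collapse = ", "),
         "; impute or drop incomplete cases first", call. = FALSE)

  xlev_out <- list()
  expand_main <- function(cv) {
    v <- cohort[[cv]]
    if (schema[[cv]] == "categorical") {
      levs <- if (!is.null(xlev) && !is.null(xlev[[cv]])) xlev[[cv]]
              else sort(unique(as.character(v)))
      bad <- setdiff(unique(as.character(v)), levs)
      if (length(bad))
        stop("unseen level(s) in `", cv, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      xlev_out[[cv]] <<- levs
      if (length(levs) < 2) {
        m <- matrix(numeric(nrow(cohort)), ncol = 1)
        colnames(m) <- paste0(cv, "=", levs[1])
        return(m[, 0, drop = FALSE])  # single level: no columns
      }
      m <- vapply(levs[-1], function(l) as.numeric(v == l),
                  numeric(nrow(cohort)))
      m <- matrix(m, nrow = nrow(cohort))
      colnames(m) <- paste0(cv, "=", levs[-1])
      m
    } else {
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- cv
      m
    }
  }
  blocks <- lapply(spec$main, expand_main)
  names(blocks) <- spec$main
  for (p in spec$interactions) {
    a <- blocks[[p[1]]]; b <- blocks[[p[2]]]
    prod_cols <- list()
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
      cn <- paste0(colnames(a)[i], ":", colnames(b)[j])
      prod_cols[[cn]] <- a[, i] * b[, j]
    }
    m <- do.call(cbind, prod_cols)
    blocks[[paste(p, collapse = ":")]] <- m
  }
  X <- do.call(cbind, blocks)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  list(X = X, xlev = xlev_out)
}

#' Fit a Cox proportional hazards model for a model specification
#'
#' Maximises the Cox partial likelihood (Breslow tie handling) by
#' Newton-Raphson with step halving, converging when the relative change
#' in log partial likelihood falls below `eps` (default 1e-9) or after
#' `iter_max` iterations. A rank-deficient design or failed convergence
#' yields a model with `converged = FALSE` rather than an error, so a
#' model search can skip the candidate and continue.
#'
#' @inheritParams build_design
#' @param eps relative log-partial-likelihood convergence tolerance.
#' @param iter_max maximum Newton-Raphson iterations.
#' @return a `fitted_cox_model`: spec, named `coef` and `se`, column
#'   `center` (training means, subtracted before prediction), factor
#'   levels, `converged`/`singular` flags, `n_train`, `loglik`
#'   (null and maximised).
#' @export
fit_cox <- function(spec, cohort, eps = 1e-9, iter_max = 100) {
  outcome <- as_surv_outcome(cohort)
  if (sum(outcome$event) < 1)
    stop("cannot fit: no observed events in cohort", call. = FALSE)
  d <- build_design(spec, cohort)
  if (ncol(d$X) == 0)
    stop("empty model: spec has no terms to fit", call. = FALSE)
  singular <- qr(d$X)$rank < ncol(d$X)
  if (singular) {
    warning("singular design for ", format(spec), call. = FALSE)
    fit <- list(coef = rep(NA_real_, ncol(d$X)),
                se = rep(NA_real_, ncol(d$X)),
                loglik = c(NA_real_, NA_real_), converged = FALSE)
  } else {
    center <- colMeans(d$X)
    Xc <- sweep(d$X, 2, center)
    fit <- cpp_coxfit(Xc, outcome$time, outcome$event, eps, iter_max)
  }
  structure(list(
    spec = spec,
    coef = setNames(as.numeric(fit$coef), colnames(d$X)),
    se = setNames(as.numeric(fit$se), colnames(d$X)),
    center = if (singular) NULL else setNames(center, colnames(d$X)),
    xlev = d$xlev,
    converged = isTRUE(fit$converged) && !singular,
    singular = singular,
    n_train = nrow(cohort),
    loglik = as.numeric(fit$loglik)),
    class = "fitted_cox_model")
}

#' @export
print.fitted_cox_model <- function(x, ...) {
  cat(format(x$spec), "\n")
  if (!x$converged) {
    cat("  NOT converged", if (x$singular) " (singular design)", "\n",
        sep = "")
    return(invisible(x))
  }
  tab <- data.frame(coef = x$coef, se = x$se, z = x$coef / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Per-patient risk scores from a fitted Cox model
#'
#' The linear predictor `x . beta` on the training-centered design
#' (log relative hazard); higher scores mean worse prognosis.
#'
#' @param model a converged `fitted_cox_model`.
#' @param cohort a [cohort_table()] carrying the model's covariates.
#' @return named numeric vector of risk scores (names = patient ids).
#' @export
predict_risk <- function(model, cohort) {
  stopifnot(inherits(model, "fitted_cox_model"))
  if (!model$converged)
    stop("model did not converge; no risk prediction available",
         call. = FALSE)
  d <- build_design(model$spec, cohort, xlev = model$xlev)
  if (!identical(colnames(d$X), names(model$coef)))
    stop("design mismatch between fit and predict cohorts", call. = FALSE)
  Xc <- sweep(d$X, 2, model$center)
  setNames(drop(Xc %*% model$coef), cohort$patient_id)
}

#' Serialize and restore fitted Cox models
#'
#' Stores the spec, coefficients, centering information and factor
#' levels as JSON so a fitted model can be reused on new cohorts.
#'
#' @param model a `fitted_cox_model`.
#' @param path JSON file path.
#' @export
write_cox_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_cox_model"))
  obj <- list(
    spec = list(main = as.list(model$spec$main),
                interactions = as.list(interaction_labels(model$spec)),
                exclude = as.list(model$spec$exclude)),
    coef = as.list(model$coef), se = as.list(model$se),
    center = as.list(model$center), xlev = model$xlev,
    converged = model$converged, singular = model$singular,
    n_train = model$n_train, loglik = model$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cox_model
#' @export
read_cox_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(as.character(unlist(obj$spec$main)),
                     as.character(unlist(obj$spec$interactions)),
                     as.character(unlist(obj$spec$exclude)))
  structure(list(
    spec = spec,
    coef = unlist(obj$coef), se = unlist(obj$se),
    center = unlist(obj$center),
    xlev = lapply(obj$xlev, as.character),
    converged = isTRUE(obj$converged), singular = isTRUE(obj$singular),
    n_train = obj$n_train, loglik = as.numeric(obj$loglik)),
    class = "fitted_cox_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
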