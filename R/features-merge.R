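#' Univariable Cox Wald z-scores
#'
#' Fits each column of `x` alone against the outcome with a Cox
#' proportional hazards model (Breslow ties) and returns the Wald
#' z-statistic coefficient / standard error. A column constant across
#' patients has no defined fit; its z is returned as `NA` with a
#' warning.
#'
#' @param x numeric matrix (patients x features) without missing values.
#' @param outcome a [surv_outcome()].
#' @return named numeric vector of z-statistics.
#' @export
univariable_cox_z <- function(x, outcome) {
  stopifnot(inherits(outcome, "surv_outcome"))
  x <- as.matrix(x)
  if (nrow(x) != length(outcome))
    stop("`x` must have one row per patient", call. = FALSE)
  if (sum(outcome$event) < 1)
    stop("at least one event required", call. = FALSE)
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  z <- apply(x, 2, function(v) {
    if (var(v) == 0) return(NA_real_)
    fit <- cpp_coxfit(matrix(v - mean(v), ncol = 1), outcome$time,
                      outcome$event)
    if (!isTRUE(fit$converged)) return(NA_real_)
    fit$coef[1] / fit$se[1]
  })
  if (anyNA(z))
    warning("constant or non-fittable feature(s): ",
            paste(colnames(x)[is.na(z)], collapse = ", "), call. = FALSE)
  setNames(as.numeric(z), colnames(x))
}

#' Merge a block of binary covariates into one score
#'
#' Collapses a patients-x-features 0/1 block (e.g. medical-history
#' items, prior medications, metastasis sites) into a single per-patient
#' metavariable. Three merge modes: `logical_or` (any item present),
#' `sum` (item count), and `zscore_sum` (items weighted by their
#' univariable Cox Wald z against the survival outcome, so the score is
#' proportional to each item's strength of association). Features that
#' are constant get weight 0 under `zscore_sum` (their Cox fit is
#' undefined).
#'
#' @param block numeric matrix with entries 0/1 (or `NA`).
#' @param mode one of `"logical_or"`, `"sum"`, `"zscore_sum"`.
#' @param outcome [surv_outcome()], required for `zscore_sum`.
#' @param na_value value substituted for missing entries before merging
#'   (default 0: an unreported history item counts as absent).
#' @return list with `score` (per-patient numeric) and `weights`
#'   (a `merge_weights` object that reproduces the score via
#'   [apply_merge_weights()]).
#' @export
merge_binary_block <- function(block,
                               mode = c("logical_or", "sum", "zscore_sum"),
                               outcome = NULL, na_value = 0) {
  mode <- match.arg(mode)
  block <- as.matrix(block)
  vals <- block[!is.na(block)]
  if (!all(vals %in% c(0, 1)))
    stop("block entries must be 0/1 (or NA)", call. = FALSE)
  block[is.na(block)] <- na_value
  w <- switch(mode,
    logical_or = rep(1, ncol(block)),
    sum = rep(1, ncol(block)),
    zscore_sum = {
      if (is.null(outcome))
        stop("`outcome` is required for mode = \"zscore_sum\"",
             call. = FALSE)
      z <- univariable_cox_z(block, outcome)
      z[is.na(z)] <- 0
      z
    })
  weights <- structure(
    list(feature_names = colnames(block), weights = unname(w),
         mode = mode),
    class = "merge_weights")
  list(score = apply_merge_weights(weights, block), weights = weights)
}

#' @rdname merge_binary_block
#' @param weights a `merge_weights` object from a previous merge.
#' @export
apply_merge_weights <- function(weights, block, na_value = 0) {
  stopifnot(inherits(weights, "merge_weights"))
  block <- as.matrix(block)
  if (ncol(block) != length(weights$weights))
    stop("block has ", ncol(block), " columns but weights cover ",
         length(weights$weights), call. = FALSE)
  block[is.na(block)] <- na_value
  if (weights$mode == "logical_or")
    apply(block, 1, max)
  else
    drop(block %*% weights$weights)
}

#' @export
print.merge_weights <- function(x, ...) {
  cat(sprintf("<merge_weights> mode = %s, %d features\n", x$mode,
              length(x$weights)))
  invisible(x)
}

#' Label binary features protective, harmful or neutral
#'
#' Each feature is fitted alone against the outcome; its univariable
#' Cox Wald z-score is compared against a threshold (default 1.64, the
#' two-sided 10% normal quantile): z strictly greater than +threshold is
#' labelled `protective`, z strictly smaller than -threshold `harmful`,
#' anything else (including exactly the threshold) `neutral`. The
#' labelling follows the printed convention literally; because a
#' positive Cox coefficient on a presence indicator means higher hazard,
#' `flip_sign = TRUE` is provided to swap the two labels if the opposite
#' clinical reading is intended. Constant features are neutral with a
#' warning.
#'
#' @param features binary matrix (patients x features).
#' @param outcome a [surv_outcome()].
#' @param threshold positive z cutoff.
#' @param flip_sign swap the protective/harmful labels.
#' @return data.frame with columns `feature`, `z`, `label`.
#' @export
classify_protective_harmful <- function(features, outcome,
                                        threshold = 1.64,
                                        flip_sign = FALSE) {
  stopifnot(threshold > 0)
  features <- as.matrix(features)
  z <- univariable_cox_z(features, outcome)
  lab <- ifelse(is.na(z), "neutral",
         ifelse(z > threshold, "protective",
         ifelse(z < -threshold, "harmful", "neutral")))
  if (flip_sign)
    lab <- ifelse(lab == "protective", "harmful",
           ifelse(lab == "harmful", "protective", lab))
  data.frame(feature = colnames(features) %||%
               paste0("f", seq_along(z)),
             z = as.numeric(z), label = lab, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Composite harmful/protective risk feature
#'
#' Jointly fits the per-patient counts of harmful and protective items
#' against the outcome with a Cox model (optionally adjusted for extra
#' covariates) and combines them into one score weighted by their Wald
#' z-statistics: `z_harm * sum_harmful + z_pro * sum_protective`. With an
#' empty adjustment set this is the plain two-variable composite; with
#' adjustment covariates the z-scores come from the adjusted fit.
#'
#' @param sum_protective,sum_harmful per-patient counts.
#' @param outcome a [surv_outcome()].
#' @param adjustment optional numeric matrix of extra covariates for the
#'   initial fit (its coefficients are not used in the score).
#' @return list with `score`, `z_harm`, `z_pro`; the z's allow the
#'   feature to be recomputed on new data.
#' @export
derive_harm_pro <- function(sum_protective, sum_harmful, outcome,
                            adjustment = NULL) {
  stopifnot(inherits(outcome, "surv_outcome"))
  sum_protective <- as.numeric(sum_protective)
  sum_harmful <- as.numeric(sum_harmful)
  X <- cbind(harm = sum_harmful, pro = sum_protective)
  keep <- apply(X, 2, var) > 0
  if (!is.null(adjustment)) {
    adjustment <- as.matrix(adjustment)
    X <- cbind(X, adjustment)
    keep <- c(keep, rep(TRUE, ncol(adjustment)))
  }
  Xf <- X[, keep, drop = FALSE]
  if (ncol(Xf) == 0)
    stop("both summation variables are constant; nothing to fit",
         call. = FALSE)
  if (qr(Xf)$rank < ncol(Xf))
    stop("collinear variables in harm_pro fit: design is rank deficient",
         call. = FALSE)
  fit <- cpp_coxfit(sweep(Xf, 2, colMeans(Xf)), outcome$time,
                    outcome$event)
  if (!isTRUE(fit$converged))
    stop("harm_pro Cox fit did not converge", call. = FALSE)
  z <- setNames(rep(0, ncol(X)), colnames(X))
  z[keep] <- as.numeric(fit$coef) / as.numeric(fit$se)
  list(score = z[["harm"]] * sum_harmful + z[["pro"]] * sum_protective,
       z_harm = z[["harm"]], z_pro = z[["pro"]])
}
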