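#' Smooth mapping from risk score to time of event
#'
#' Point predictions of days to death are obtained by regressing the
#' observed death times on the risk score with a penalised cubic
#' regression spline, `TTE = f(risk) + error`, fitted via
#' [mgcv::gam()] with the smoothing parameter chosen by generalised
#' cross-validation. Only patients whose death was observed enter the
#' fit; censored rows are ignored entirely.
#'
#' @param risk per-patient risk scores.
#' @param outcome a [surv_outcome()]; rows with `event == 1` are used.
#' @param k spline basis dimension (default 10; reduced automatically
#'   when there are fewer distinct risk values).
#' @param min_deaths minimum number of observed deaths required.
#' @return a `tte_map`: the fitted gam, the fit domain
#'   `[risk_min, risk_max]` and `n_fit`.
#' @export
fit_tte_map <- function(risk, outcome, k = 10, min_deaths = 10) {
  stopifnot(inherits(outcome, "surv_outcome"))
  risk <- as.numeric(risk)
  if (length(risk) != length(outcome))
    stop("`risk` must have one value per patient", call. = FALSE)
  dead <- outcome$event == 1
  if (sum(dead) < min_deaths)
    stop("need at least ", min_deaths, " observed deaths; have ",
         sum(dead), call. = FALSE)
  df <- data.frame(time = outcome$time[dead], risk = risk[dead])
  k_use <- min(k, length(unique(df$risk)))
  fit <- if (k_use >= 3) {
    mgcv::gam(time ~ s(risk, k = k_use, bs = "cr"), data = df,
              method = "GCV.Cp")
  } else {
    # too few distinct risks to support a spline: linear (or constant)
    stats::lm(time ~ risk, data = df)
  }
  structure(list(fit = fit, risk_min = min(df$risk),
                 risk_max = max(df$risk), n_fit = nrow(df)),
            class = "tte_map")
}

#' @export
print.tte_map <- function(x, ...) {
  cat(sprintf("<tte_map> fitted on %d deaths, risk domain [%.3f, %.3f]\n",
              x$n_fit, x$risk_min, x$risk_max))
  invisible(x)
}

#' Predict days to death from risk scores
#'
#' Evaluates the fitted smooth. Risks outside the fitted domain are
#' clamped to its boundary (spline extrapolation of death times is
#' unsafe); predictions are floored at 1 day so every output is a
#' positive time.
#'
#' @param map a `tte_map` from [fit_tte_map()].
#' @param risk per-patient risk scores.
#' @return positive numeric vector of predicted days.
#' @export
predict_tte <- function(map, risk) {
  stopifnot(inherits(map, "tte_map"))
  risk <- pmin(pmax(as.numeric(risk), map$risk_min), map$risk_max)
  pred <- as.numeric(predict(map$fit, newdata = data.frame(risk = risk)))
  pmax(pred, 1)
}
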