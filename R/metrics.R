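#' Evaluation time grid
#'
#' Window and time points over which the time-dependent AUC is
#' integrated. The default window is 6 to 30 months (182.625 to 913.125
#' days at 30.4375 days/month). When `eval_times` is `NULL`, the
#' distinct observed event times inside the closed window are used at
#' integration time.
#'
#' @param t_lo,t_hi window bounds in days, `t_lo < t_hi`.
#' @param eval_times optional sorted evaluation times inside the window.
#' @return a `time_grid` object.
#' @export
time_grid <- function(t_lo = months_to_days(6), t_hi = months_to_days(30),
                      eval_times = NULL) {
  stopifnot(is.numeric(t_lo), is.numeric(t_hi), t_lo > 0, t_lo < t_hi)
  if (!is.null(eval_times)) {
    eval_times <- sort(unique(as.numeric(eval_times)))
    if (!length(eval_times))
      stop("`eval_times` must be nonempty when supplied", call. = FALSE)
    if (any(eval_times < t_lo | eval_times > t_hi))
      stop("`eval_times` must lie within [t_lo, t_hi]", call. = FALSE)
  }
  structure(list(t_lo = t_lo, t_hi = t_hi, eval_times = eval_times),
            class = "time_grid")
}

grid_times <- function(grid, outcome) {
  if (!is.null(grid$eval_times)) return(grid$eval_times)
  et <- sort(unique(outcome$time[outcome$event == 1]))
  et[et >= grid$t_lo & et <= grid$t_hi]
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Probability that a patient who died by time `t` carries a higher risk
#' score than a patient still under observation beyond `t`. Censoring is
#' handled by inverse-probability-of-censoring weights from a
#' Kaplan-Meier estimate of the censoring distribution (cases weighted
#' by 1/G(T-)); risk ties count 1/2. Without censoring this reduces
#' exactly to the two-sample Mann-Whitney statistic between the died-by-t
#' and surviving groups.
#'
#' @param risk per-patient risk score (higher = worse prognosis).
#' @param outcome a [surv_outcome()].
#' @param t evaluation time(s) in days.
#' @return AUC in \[0,1\] per time, `NA` where no case or no control
#'   exists.
#' @export
auc_cumulative <- function(risk, outcome, t) {
  stopifnot(inherits(outcome, "surv_outcome"))
  risk <- as.numeric(risk)
  if (length(risk) != length(outcome))
    stop("`risk` must have one value per patient", call. = FALSE)
  if (anyNA(risk)) stop("`risk` contains missing values", call. = FALSE)
  as.numeric(cpp_cum_auc(risk, outcome$time, outcome$event,
                         as.numeric(t)))
}

#' Integrated time-dependent AUC
#'
#' Trapezoidal integral of the cumulative/dynamic AUC over the grid's
#' evaluation times, normalised by the spanned interval so a constant
#' AUC integrates to itself. Time points where the AUC is undefined are
#' dropped.
#'
#' @inheritParams auc_cumulative
#' @param grid a [time_grid()].
#' @return scalar iAUC.
#' @export
integrated_auc <- function(risk, outcome, grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  times <- grid_times(grid, outcome)
  if (length(times) < 2)
    stop("need at least 2 evaluation times inside the window",
         call. = FALSE)
  auc <- auc_cumulative(risk, outcome, times)
  ok <- !is.na(auc)
  if (sum(ok) < 2)
    stop("AUC defined at fewer than 2 time points", call. = FALSE)
  trapz_mean(times[ok], auc[ok])
}

# normalised trapezoid: integral / (t_last - t_first)
trapz_mean <- function(x, y) {
  dx <- diff(x)
  sum(dx * (head(y, -1) + y[-1]) / 2) / (x[length(x)] - x[1])
}

#' Harrell's concordance index
#'
#' Fraction of censoring-comparable patient pairs (the earlier time is
#' an observed event) in which the higher risk score accompanies the
#' shorter survival; risk ties count 1/2. Delegates to
#' [survival::concordance()].
#'
#' @inheritParams auc_cumulative
#' @return c-index in \[0,1\].
#' @export
concordance_index <- function(risk, outcome) {
  stopifnot(inherits(outcome, "surv_outcome"))
  risk <- as.numeric(risk)
  if (length(risk) != length(outcome))
    stop("`risk` must have one value per patient", call. = FALSE)
  fit <- survival::concordance(
    survival::Surv(outcome$time, outcome$event) ~ risk, reverse = TRUE)
  npairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0)
    stop("no comparable pairs under censoring", call. = FALSE)
  unname(fit$concordance)
}

#' RMSE of predicted days to death
#'
#' Root mean squared error between predicted and observed death times,
#' computed over patients with an observed death only; censored patients
#' are excluded.
#'
#' @param predicted_days per-patient predicted time to event (days).
#' @inheritParams auc_cumulative
#' @return RMSE in days.
#' @export
rmse_on_deaths <- function(predicted_days, outcome) {
  stopifnot(inherits(outcome, "surv_outcome"))
  predicted_days <- as.numeric(predicted_days)
  if (length(predicted_days) != length(outcome))
    stop("`predicted_days` must have one value per patient", call. = FALSE)
  dead <- outcome$event == 1
  if (!any(dead)) stop("no observed deaths", call. = FALSE)
  sqrt(mean((predicted_days[dead] - outcome$time[dead])^2))
}

#' Score a set of survival predictions
#'
#' Bundles the package's evaluation metrics into one report: iAUC over
#' the grid, per-time AUCs, concordance and (when time-to-event
#' predictions are supplied) RMSE on observed deaths.
#'
#' @inheritParams integrated_auc
#' @param predicted_days optional per-patient predicted days to death.
#' @return a `score_report` list with elements `iAUC`, `auc_at`,
#'   `c_index`, `rmse_days`.
#' @export
score_predictions <- function(risk, outcome, grid = time_grid(),
                              predicted_days = NULL) {
  times <- grid_times(grid, outcome)
  auc <- auc_cumulative(risk, outcome, times)
  rep <- list(
    iAUC = integrated_auc(risk, outcome, grid),
    auc_at = setNames(as.numeric(auc), format(times, trim = TRUE)),
    c_index = concordance_index(risk, outcome),
    rmse_days = if (!is.null(predicted_days))
      rmse_on_deaths(predicted_days, outcome))
  structure(rep, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> iAUC = %.4f | cIndex = %.4f", x$iAUC,
              x$c_index))
  if (!is.null(x$rmse_days)) cat(sprintf(" | RMSE = %.1f days", x$rmse_days))
  cat(sprintf(" | %d AUC time points\n", length(x$auc_at)))
  invisible(x)
}
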