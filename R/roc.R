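
# Kaplan-Meier estimate of the censoring survival function G(t), with a
# left-limit evaluator G(t-) used for IPCW weights
censoring_km <- function(clinical) {
  fit <- survival::survfit(survival::Surv(clinical$time, 1 - clinical$event) ~ 1)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(
    at = function(t) pmax(step(t), 1e-12),
    at_minus = function(t) {
      # left limit: value just before t
      pmax(vapply(t, function(ti) {
        if (any(fit$time < ti)) {
          min(c(1, fit$surv[fit$time < ti]))
        } else 1
      }, numeric(1L)), 1e-12)
    }
  )
}

#' Time-dependent ROC at a fixed horizon (IPCW, cumulative/dynamic)
#'
#' Cases at horizon `T` are subjects with an observed event by `T`
#' (weighted by `1/G(t_i-)`, `G` the Kaplan-Meier censoring survival
#' estimator); controls are subjects still event-free beyond `T`. A subject
#' is test-positive at threshold `c` when `RS >= c`. With no censoring
#' before `T` this reduces to the plain ROC of RS against the event-by-T
#' indicator. AUC is the trapezoidal integral of the curve.
#'
#' @param rs Named numeric vector of risk scores.
#' @param clinical A `clinical_tbl` aligned with `rs` (same sample order).
#' @param horizon Evaluation time, in the table's time unit.
#' @return A `time_roc` tibble (`threshold`, `sensitivity`, `specificity`)
#'   with attributes `auc` and `horizon`.
#' @export
time_dependent_roc <- function(rs, clinical, horizon) {
  check_scalar_number(horizon, "horizon", min = 0)
  if (length(rs) != nrow(clinical)) abort("`rs` must align with `clinical`.")
  is_case <- clinical$time <= horizon & clinical$event == 1L
  is_control <- clinical$time > horizon
  if (!any(is_case)) abort("No events before the horizon; ROC undefined.")
  if (!any(is_control)) abort("No subjects at risk beyond the horizon.")
  G <- censoring_km(clinical)
  w <- numeric(length(rs))
  w[is_case] <- 1 / G$at_minus(clinical$time[is_case])
  w[is_control] <- 1 / G$at(horizon)

  thresholds <- sort(unique(rs))
  W_case <- sum(w[is_case])
  W_ctrl <- sum(w[is_control])
  sens <- vapply(thresholds, function(cth) {
    sum(w[is_case & rs >= cth]) / W_case
  }, numeric(1L))
  spec <- vapply(thresholds, function(cth) {
    sum(w[is_control & rs < cth]) / W_ctrl
  }, numeric(1L))
  out <- tibble(threshold = thresholds, sensitivity = sens, specificity = spec)
  # trapezoidal AUC over (FPR, TPR), anchored at (0,0) and (1,1)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(out, auc = auc, horizon = horizon,
            class = c("time_roc", class(out)))
}

#' Maximum-Youden cutoff from a ROC curve
#'
#' `J = sensitivity + specificity - 1`, maximized over the observed
#' thresholds; ties are broken toward the smaller threshold so the high-risk
#' group is as large as possible.
#'
#' @param roc A `time_roc` tibble.
#' @return The cutoff threshold, with the achieved `J` as attribute
#'   `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "time_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j > max(j) - 1e-12)
  pick <- best[which.min(roc$threshold[best])]
  structure(roc$threshold[pick], youden = j[pick])
}
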