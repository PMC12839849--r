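
#' Tidy a subtype classifier's training history
#'
#' @param x A `subtype_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_accuracy`.
#' @method tidy subtype_classifier
#' @export
tidy.subtype_classifier <- function(x, ...) {
  x$history
}

#' One-row summary of a subtype classifier
#'
#' @inheritParams tidy.subtype_classifier
#' @return Tibble with architecture, class count, epochs trained and
#'   held-out accuracy.
#' @method glance subtype_classifier
#' @export
glance.subtype_classifier <- function(x, ...) {
  tibble(
    n_features = length(x$set_names),
    n_classes = length(x$classes),
    deep_features = x$config$hidden_layer_widths[length(x$config$hidden_layer_widths)],
    epochs = max(x$history$epoch),
    heldout_accuracy = x$heldout_accuracy
  )
}

#' Tidy the coefficients of a Cox risk model
#'
#' @param x A `cox_risk_model`.
#' @param ... Unused.
#' @return Tibble `feature_id`, `estimate` (log hazard per SD), `hr`,
#'   `std_error`, `p`.
#' @method tidy cox_risk_model
#' @export
tidy.cox_risk_model <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(
    feature_id = x$feature_ids,
    estimate = unname(x$coefficients),
    hr = unname(exp(x$coefficients)),
    std_error = unname(se),
    p = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' One-row summary of a Cox risk model
#'
#' @inheritParams tidy.cox_risk_model
#' @return Tibble with size, events, log-likelihood, cutoff and horizon.
#' @method glance cox_risk_model
#' @export
glance.cox_risk_model <- function(x, ...) {
  tibble(
    n = x$n,
    n_events = x$n_events,
    n_features = length(x$feature_ids),
    loglik = x$loglik[length(x$loglik)],
    cutoff = x$cutoff %||% NA_real_,
    cutoff_horizon = x$cutoff_horizon %||% NA_real_
  )
}

#' Tidy a risk report
#'
#' @param x A `risk_report`.
#' @param ... Unused.
#' @return The per-sample assignment tibble joined with waterfall rank.
#' @method tidy risk_report
#' @export
tidy.risk_report <- function(x, ...) {
  x$waterfall
}

#' One-row summary of a risk report
#'
#' @inheritParams tidy.risk_report
#' @return Tibble with group sizes, log-rank p, HR and CI, C-index and the
#'   AUC at each horizon (wide columns `auc_<horizon>`).
#' @method glance risk_report
#' @export
glance.risk_report <- function(x, ...) {
  aucs <- setNames(x$auc$auc, paste0("auc_", x$auc$horizon))
  dplyr::bind_cols(
    tibble(
      n_high = sum(x$assignment$group == "high"),
      n_low = sum(x$assignment$group == "low"),
      cutoff = x$cutoff,
      logrank_p = x$logrank$p,
      hr = x$hazard_ratio$hr,
      hr_ci_low = x$hazard_ratio$ci_low,
      hr_ci_high = x$hazard_ratio$ci_high,
      c_index = x$c_index
    ),
    as_tibble(as.list(aucs))
  )
}
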