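
surv_object <- function(clinical) {
  survival::Surv(clinical$time, clinical$event)
}

check_matched_samples <- function(features, clinical) {
  if (is.null(rownames(features)) ||
      !identical(rownames(features), clinical$sample_id)) {
    abort("Row names of `features` must equal `clinical$sample_id` (same order).")
  }
}

#' Univariate Cox screen
#'
#' Each feature is z-scored on the supplied cohort and fitted alone in a Cox
#' proportional hazards model (Efron ties); features with Wald p below
#' `alpha_keep` are retained. Zero-variance features are excluded before
#' fitting and reported as skipped.
#'
#' @param features Samples x features numeric matrix (row names = sample
#'   ids, matching `clinical`).
#' @param clinical A `clinical_tbl` for the same samples.
#' @param alpha_keep Wald significance level for retention.
#' @param adjust `"none"` (default, mirroring common practice) or `"BH"` to
#'   screen on Benjamini-Hochberg adjusted p-values instead.
#' @return Tibble with `feature_id`, `beta`, `hr`, `se`, `p`, (`q` when
#'   adjusted), `retained`, `skipped`; retained ids in attribute `retained`.
#' @export
univariate_cox_screen <- function(features, clinical, alpha_keep = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_matched_samples(features, clinical)
  check_scalar_number(alpha_keep, "alpha_keep", 0, 1)
  if (sum(clinical$event) == 0L) abort("No events present; cannot screen features.")
  y <- surv_object(clinical)
  sds <- apply(features, 2L, sd)
  rows <- lapply(colnames(features), function(f) {
    if (sds[f] < 1e-12) {
      return(tibble(feature_id = f, beta = NA_real_, hr = NA_real_,
                    se = NA_real_, p = NA_real_, skipped = TRUE))
    }
    z <- (features[, f] - mean(features[, f])) / sds[f]
    fit <- survival::coxph(y ~ z, ties = "efron")
    s <- summary(fit)
    tibble(feature_id = f, beta = unname(coef(fit)),
           hr = unname(exp(coef(fit))), se = s$coefficients[1L, "se(coef)"],
           p = s$coefficients[1L, "Pr(>|z|)"], skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  p_screen <- if (adjust == "BH") p.adjust(out$p, method = "BH") else out$p
  if (adjust == "BH") out$q <- p_screen
  out$retained <- !out$skipped & !is.na(p_screen) & p_screen < alpha_keep
  if (!any(out$retained)) abort("Empty signature after screening.")
  attr(out, "retained") <- out$feature_id[out$retained]
  out
}

#' Fit the multivariate Cox risk model
#'
#' Retained features are z-scored with cohort statistics (stored on the model
#' so validation cohorts reuse them without refitting) and fitted jointly by
#' partial-likelihood maximization with Efron tie handling.
#'
#' @inheritParams univariate_cox_screen
#' @param feature_ids Features to include (e.g. the screen's `retained`
#'   attribute); defaults to all columns.
#' @param ties Tie handling for the partial likelihood. `"efron"` (default)
#'   is the finer approximation under heavy ties; `"breslow"` is coarser but
#'   exactly invariant to record replication.
#' @return A `cox_risk_model` (no cutoff yet; see [calibrate_cutoff()]).
#' @export
fit_cox_model <- function(features, clinical, feature_ids = colnames(features),
                          ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_matched_samples(features, clinical)
  if (length(feature_ids) == 0L) abort("No features supplied to the Cox model.")
  missing <- setdiff(feature_ids, colnames(features))
  if (length(missing) > 0L) {
    abort(glue("Feature(s) absent from matrix: {paste(head(missing, 5L), collapse = ', ')}."))
  }
  n_events <- sum(clinical$event)
  if (n_events <= length(feature_ids)) {
    abort(glue(
      "Only {n_events} events for {length(feature_ids)} features; ",
      "use fewer features than events."
    ))
  }
  X <- features[, feature_ids, drop = FALSE]
  mu <- colMeans(X)
  sds <- apply(X, 2L, sd)
  if (any(sds < 1e-12)) {
    abort(glue("Zero-variance feature in Cox fit: {feature_ids[which(sds < 1e-12)[1L]]}."))
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sds, `/`)
  fit <- withCallingHandlers(
    survival::coxph(surv_object(clinical) ~ Z, ties = ties,
                    control = survival::coxph.control(eps = 1e-10, iter.max = 100L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        abort(glue("Cox fit failed to converge: {conditionMessage(w)}"))
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(coef(fit))
  if (any(abs(beta) > 15)) {
    abort(glue(
      "Apparent separation: |coefficient| diverging for feature ",
      "'{feature_ids[which.max(abs(beta))]}'."
    ))
  }
  structure(list(
    feature_ids = feature_ids,
    coefficients = setNames(beta, feature_ids),
    center = mu,
    scale = sds,
    cutoff = NULL,
    cutoff_horizon = NULL,
    loglik = fit$loglik,
    n = nrow(X),
    n_events = n_events,
    vcov = stats::vcov(fit),
    time_unit = attr(clinical, "time_unit")
  ), class = "cox_risk_model")
}

#' Risk scores from a fitted model
#'
#' `RS_i = sum_j beta_j z_ij`, with `z` standardized by the model's stored
#' training parameters. Note that shifting a raw feature of the scoring data
#' by `c` shifts every RS by `beta_j * c / sd_j`, because standardization
#' uses the stored training mean, not the scoring cohort's.
#'
#' @param model A `cox_risk_model`.
#' @param features Samples x features matrix containing all model features.
#' @return Named numeric vector of risk scores.
#' @export
risk_scores <- function(model, features) {
  stopifnot(inherits(model, "cox_risk_model"))
  missing <- setdiff(model$feature_ids, colnames(features))
  if (length(missing) > 0L) {
    abort(glue("Missing model feature(s): {paste(head(missing, 5L), collapse = ', ')}."))
  }
  X <- features[, model$feature_ids, drop = FALSE]
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  rs <- drop(Z %*% model$coefficients)
  setNames(rs, rownames(features))
}

#' Calibrate the high/low-risk cutoff
#'
#' Computes training-cohort risk scores, runs time-dependent ROC analysis at
#' `horizon`, and stores the maximum-Youden threshold on the model.
#'
#' @param model A `cox_risk_model`.
#' @param features Training-cohort feature matrix.
#' @param clinical Training-cohort clinical table.
#' @param horizon Cutoff horizon, in the clinical table's time unit.
#' @return The model with `cutoff` and `cutoff_horizon` set.
#' @export
calibrate_cutoff <- function(model, features, clinical, horizon) {
  check_matched_samples(features, clinical)
  rs <- risk_scores(model, features)
  roc <- time_dependent_roc(rs, clinical, horizon)
  model$cutoff <- youden_cutoff(roc)
  model$cutoff_horizon <- horizon
  model
}

#' Assign high/low risk groups
#'
#' High risk is `RS >= cutoff` (the boundary falls into the high-risk
#' group).
#'
#' @param model A calibrated `cox_risk_model`.
#' @param features Samples x features matrix.
#' @return Tibble `sample_id`, `risk_score`, `group` (`"high"`/`"low"`).
#' @export
assign_risk_groups <- function(model, features) {
  if (is.null(model$cutoff)) abort("Model has no cutoff; run calibrate_cutoff() first.")
  rs <- risk_scores(model, features)
  tibble(
    sample_id = names(rs),
    risk_score = unname(rs),
    group = unname(ifelse(rs >= model$cutoff, "high", "low"))
  )
}
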