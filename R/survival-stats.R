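
#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over event times; censored-only
#' times reduce the at-risk count without a survival drop.
#'
#' @param clinical A `clinical_tbl` (or any data frame with `time`/`event`).
#' @param groups Optional vector splitting the samples into curves.
#' @return Tibble with `group` (if any), `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_curve <- function(clinical, groups = NULL) {
  if (nrow(clinical) == 0L) abort("Empty clinical subset.")
  if (is.null(groups)) {
    fit <- survival::survfit(surv_object(clinical) ~ 1)
    return(tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, surv = fit$surv))
  }
  stopifnot(length(groups) == nrow(clinical))
  grp <- factor(groups)
  fit <- survival::survfit(surv_object(clinical) ~ grp)
  lv <- sub("^grp=", "", rep(names(fit$strata), fit$strata))
  tibble(group = lv, time = fit$time, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic over the pooled event times with the
#' hypergeometric variance; p from a chi-square with 1 df.
#'
#' @param clinical A `clinical_tbl`.
#' @param groups Two-level grouping vector.
#' @return Tibble `statistic`, `df`, `p`.
#' @export
logrank_test <- function(clinical, groups) {
  grp <- factor(groups)
  if (nlevels(grp) != 2L || any(table(grp) == 0L)) {
    abort("Log-rank test needs exactly 2 non-empty groups.")
  }
  fit <- survival::survdiff(surv_object(clinical) ~ grp)
  tibble(statistic = unname(fit$chisq), df = 1L,
         p = pchisq(fit$chisq, df = 1L, lower.tail = FALSE))
}

#' Hazard ratio between risk groups
#'
#' Univariate Cox fit on the high-vs-low indicator: `HR = exp(beta)` with a
#' Wald 95% confidence interval.
#'
#' @param clinical A `clinical_tbl`.
#' @param groups Vector with levels `"high"` and `"low"` (low = reference).
#' @return Tibble `hr`, `ci_low`, `ci_high`, `p`.
#' @export
group_hazard_ratio <- function(clinical, groups) {
  grp <- factor(groups, levels = c("low", "high"))
  if (any(table(grp) == 0L)) abort("Both risk groups must be non-empty.")
  if (sum(clinical$event) == 0L) abort("No events; hazard ratio undefined.")
  fit <- survival::coxph(surv_object(clinical) ~ grp, ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  tibble(
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = summary(fit)$coefficients[1L, "Pr(>|z|)"]
  )
}

#' Harrell's concordance index
#'
#' Among usable pairs (the earlier observed time is an event), the fraction
#' where the earlier-failing subject carries the higher risk score; risk-score
#' ties count 1/2.
#'
#' @param rs Numeric risk scores.
#' @param clinical A `clinical_tbl` aligned with `rs`.
#' @return Scalar concordance.
#' @export
concordance_index <- function(rs, clinical) {
  if (length(rs) != nrow(clinical)) abort("`rs` must align with `clinical`.")
  fit <- survival::concordance(surv_object(clinical) ~ rs, reverse = TRUE)
  counts <- fit$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) abort("No comparable pairs; concordance undefined.")
  unname(fit$concordance)
}

#' Full survival validation report for a risk model
#'
#' Applies a calibrated risk model to a cohort and assembles the standard
#' validation outputs: risk groups, per-group Kaplan-Meier tables, log-rank
#' test, hazard ratio with CI, concordance, time-dependent AUC at the
#' requested horizons, and the waterfall ordering of risk scores.
#'
#' @param model A calibrated `cox_risk_model`.
#' @param features Samples x features matrix for the cohort.
#' @param clinical The cohort's `clinical_tbl`.
#' @param horizons Numeric AUC horizons (clinical time unit); defaults to
#'   2/3/5 years expressed in months.
#' @return A `risk_report` list of tibbles.
#' @export
survival_report <- function(model, features, clinical,
                            horizons = c(24, 36, 60)) {
  check_matched_samples(features, clinical)
  assignment <- assign_risk_groups(model, features)
  if (length(unique(assignment$group)) < 2L) {
    abort("Cutoff puts every sample in one risk group; report undefined.")
  }
  rs <- setNames(assignment$risk_score, assignment$sample_id)
  km <- km_curve(clinical, assignment$group)
  aucs <- purrr::map_dfr(horizons, function(h) {
    roc <- tryCatch(time_dependent_roc(rs, clinical, h), error = function(e) NULL)
    tibble(horizon = h, auc = if (is.null(roc)) NA_real_ else attr(roc, "auc"))
  })
  waterfall <- assignment |>
    dplyr::mutate(event = clinical$event[match(.data$sample_id, clinical$sample_id)]) |>
    dplyr::arrange(.data$risk_score) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(
    assignment = assignment,
    km = km,
    logrank = logrank_test(clinical, assignment$group),
    hazard_ratio = group_hazard_ratio(clinical, assignment$group),
    c_index = concordance_index(rs, clinical),
    auc = aucs,
    waterfall = waterfall,
    cutoff = model$cutoff,
    horizons = horizons
  ), class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report>\n")
  cat(glue("  groups: {sum(x$assignment$group == 'high')} high / ",
           "{sum(x$assignment$group == 'low')} low (cutoff {signif(x$cutoff, 3)})"), "\n")
  cat(glue("  log-rank p = {signif(x$logrank$p, 3)}; HR = ",
           "{signif(x$hazard_ratio$hr, 3)} ",
           "[{signif(x$hazard_ratio$ci_low, 3)}-{signif(x$hazard_ratio$ci_high, 3)}]"), "\n")
  cat(glue("  C-index = {signif(x$c_index, 3)}"), "\n")
  invisible(x)
}
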