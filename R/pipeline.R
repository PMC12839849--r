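
#' Patient sex counts across the study cohorts (worked example)
#'
#' The 2 x 6 sex-by-cohort contingency table of the multi-cohort CRC study
#' population, bundled as the package's worked example for
#' [compare_groups_categorical()] (chi-square routing: all expected counts
#' exceed 5).
#'
#' @return A 2 x 6 integer matrix (rows Male/Female, columns cohorts).
#' @export
cohort_sex_counts <- function() {
  path <- system.file("extdata", "cohort_sex_counts.csv", package = "cmsdistill")
  df <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$sex
  m
}

#' Run the full subtype-to-signature distillation pipeline
#'
#' End-to-end convenience wrapper over the module functions: ssGSEA spectra
#' on the cohort's gene sets, subtype classifier training, deep-feature
#' extraction, correlation/MAD signature distillation, univariate screen,
#' multivariate Cox risk model with Youden-calibrated cutoff, survival
#' report and target-subtype enrichment of the high-risk group.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()] (or any list
#'   with `expression`, `clinical`, `sets` of those classes).
#' @param alpha ssGSEA weight exponent.
#' @param classifier A [classifier_config()].
#' @param n_top,n_keep Signature distillation budgets per deep feature.
#' @param alpha_keep Univariate screen significance level.
#' @param cutoff_horizon Youden cutoff horizon (clinical time unit).
#' @param auc_horizons AUC horizons for the report.
#' @param target_subtype Subtype tested for high-risk enrichment.
#' @return A `distillation_result` list: `spectra`, `classifier`, `deep`,
#'   `signature`, `screen`, `model`, `report`, `enrichment`.
#' @export
run_distillation_pipeline <- function(cohort,
                                      alpha = 0.25,
                                      classifier = classifier_config(),
                                      n_top = 10L, n_keep = 3L,
                                      alpha_keep = 0.05,
                                      cutoff_horizon = 60,
                                      auc_horizons = c(24, 36, 60),
                                      target_subtype = "CMS4") {
  expr <- cohort$expression
  clinical <- cohort$clinical
  spectra <- ssgsea_spectra(expr, cohort$sets, alpha = alpha, normalize = TRUE)
  model_cls <- train_classifier(spectra, clinical$subtype, classifier)
  deep <- extract_deep_features(model_cls, spectra)
  raw <- t(unclass(expr))
  corr <- correlate_features(raw, deep)
  signature <- select_signature(corr, raw, n_top = n_top, n_keep = n_keep,
                                modality = "gene")
  sig_mat <- raw[, signature$feature_id, drop = FALSE]
  screen <- univariate_cox_screen(sig_mat, clinical, alpha_keep = alpha_keep)
  model <- fit_cox_model(sig_mat, clinical, attr(screen, "retained"))
  model <- calibrate_cutoff(model, sig_mat, clinical, horizon = cutoff_horizon)
  report <- survival_report(model, sig_mat, clinical, horizons = auc_horizons)
  enrichment <- subtype_enrichment(report$assignment$group, clinical$subtype,
                                   target = target_subtype)
  structure(list(
    spectra = spectra, classifier = model_cls, deep = deep,
    signature = signature, screen = screen, model = model,
    report = report, enrichment = enrichment
  ), class = "distillation_result")
}

#' Serialize a fitted classifier or risk model into a bundle
#'
#' @param model A `subtype_classifier` or `cox_risk_model`.
#' @return A `model_bundle` that [unbundle_model()] inverts.
#' @export
bundle_model <- function(model) {
  if (inherits(model, "subtype_classifier")) {
    params <- list(
      set_names = model$set_names, classes = model$classes,
      input_center = model$input_center, input_scale = model$input_scale,
      class_weights = model$class_weights,
      hidden_layer_widths = model$config$hidden_layer_widths,
      n_layers = length(model$layers)
    )
    for (l in seq_along(model$layers)) {
      params[[paste0("W", l)]] <- model$layers[[l]]$W
      params[[paste0("b", l)]] <- model$layers[[l]]$b
    }
    model_bundle("subtype_classifier", params, seed = model$config$seed)
  } else if (inherits(model, "cox_risk_model")) {
    model_bundle("cox_risk_model", list(
      feature_ids = model$feature_ids,
      coefficients = unname(model$coefficients),
      center = unname(model$center), scale = unname(model$scale),
      cutoff = model$cutoff %||% NA_real_,
      cutoff_horizon = model$cutoff_horizon %||% NA_real_,
      n = model$n, n_events = model$n_events,
      time_unit = model$time_unit %||% "months"
    ))
  } else {
    abort("`model` must be a subtype_classifier or cox_risk_model.")
  }
}

#' @rdname bundle_model
#' @param bundle A `model_bundle` produced by [bundle_model()].
#' @export
unbundle_model <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  p <- bundle$parameters
  if (identical(bundle$stage, "subtype_classifier")) {
    layers <- lapply(seq_len(p$n_layers), function(l) {
      list(W = p[[paste0("W", l)]], b = p[[paste0("b", l)]])
    })
    structure(list(
      layers = layers, set_names = p$set_names, classes = p$classes,
      input_center = setNames(p$input_center, p$set_names),
      input_scale = setNames(p$input_scale, p$set_names),
      class_weights = p$class_weights,
      config = classifier_config(
        hidden_layer_widths = p$hidden_layer_widths,
        seed = bundle$provenance$seed %||% 1L
      ),
      history = tibble(), heldout_accuracy = NA_real_,
      validation_samples = character()
    ), class = "subtype_classifier")
  } else if (identical(bundle$stage, "cox_risk_model")) {
    cut <- p$cutoff
    structure(list(
      feature_ids = p$feature_ids,
      coefficients = setNames(p$coefficients, p$feature_ids),
      center = setNames(p$center, p$feature_ids),
      scale = setNames(p$scale, p$feature_ids),
      cutoff = if (is.na(cut)) NULL else cut,
      cutoff_horizon = if (is.na(p$cutoff_horizon)) NULL else p$cutoff_horizon,
      loglik = NA_real_, n = p$n, n_events = p$n_events,
      vcov = diag(NA_real_, length(p$feature_ids)),
      time_unit = p$time_unit
    ), class = "cox_risk_model")
  } else {
    abort(glue("Unknown bundle stage '{bundle$stage}'."))
  }
}
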