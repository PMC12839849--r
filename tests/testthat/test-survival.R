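feat_matrix <- function(x, ids = NULL) {
  m <- as.matrix(x)
  rownames(m) <- ids %||% sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
  m
}
`%||%` <- rlang::`%||%`

test_that("univariate screen retains planted features and skips degenerate ones", {
  withr::with_seed(21, {
    n <- 60L
    loghaz <- rnorm(n)
    time <- rexp(n, rate = 0.05 * exp(loghaz))
    event <- rep(1L, n)
    clin <- toy_clinical(time, event)
    X <- feat_matrix(cbind(
      planted = loghaz + rnorm(n, sd = 0.2),
      flat = rep(2, n),
      noise = rnorm(n)
    ))
  })
  scr <- univariate_cox_screen(X, clin)
  expect_true(scr$skipped[scr$feature_id == "flat"])
  expect_true(scr$retained[scr$feature_id == "planted"])
  expect_lt(scr$p[scr$feature_id == "planted"], 0.01)
  # the reported coefficient maximizes the 1-feature Efron partial likelihood
  z <- scale(X[, "planted"])[, 1L]
  grid <- seq(-2, 2, by = 5e-4)
  ll <- vapply(grid, function(b) {
    oracle_efron_loglik(b, matrix(z, ncol = 1L), clin$time, clin$event)
  }, numeric(1L))
  expect_equal(scr$beta[scr$feature_id == "planted"], grid[which.max(ll)],
               tolerance = 2e-3)
})

test_that("screen type-I retention stays near its nominal level", {
  retained <- vapply(1:50, function(s) {
    withr::with_seed(1000 + s, {
      n <- 600L
      clin <- toy_clinical(rexp(n, 0.02), rbinom(n, 1L, 0.7),
                           subtype = NULL)
      X <- feat_matrix(matrix(rnorm(n), ncol = 1L))
    })
    out <- tryCatch(univariate_cox_screen(X, clin)$retained[1L],
                    error = function(e) FALSE)
    out
  }, logical(1L))
  expect_lte(mean(retained), 0.10)
})

test_that("multivariate Cox fit matches a dense Efron grid search", {
  withr::with_seed(31, {
    X <- feat_matrix(matrix(rnorm(24), ncol = 2L))
    eta <- 0.8 * X[, 1L] - 0.5 * X[, 2L]
    clin <- toy_clinical(rexp(12, exp(eta) * 0.1),
                         rbinom(12, 1L, 0.85))
  })
  clin$event[1:3] <- 1L  # ensure enough events
  model <- fit_cox_model(X, clin)
  Z <- scale(X)
  oracle <- oracle_cox_grid(Z, clin$time, clin$event)
  expect_lt(max(abs(unname(model$coefficients) - oracle)), 1e-3)
})

test_that("record replication: Breslow is invariant, Efron follows its likelihood", {
  withr::with_seed(32, {
    X <- feat_matrix(matrix(rnorm(60), ncol = 2L))
    clin <- toy_clinical(rexp(30, 0.1), rbinom(30, 1L, 0.8))
  })
  m1 <- fit_cox_model(X, clin)  # tie-free data: efron == breslow
  expect_equal(unname(m1$coefficients),
               unname(fit_cox_model(X, clin, ties = "breslow")$coefficients),
               tolerance = 1e-8)
  X2 <- rbind(X, X)
  rownames(X2) <- sprintf("P%02d", 1:60)
  clin2 <- toy_clinical(rep(clin$time, 2L), rep(clin$event, 2L))
  # replication invariance is exact for the Breslow partial likelihood
  # (compared on the raw-feature scale: the stored z-scale itself shrinks
  # slightly under duplication through the n-1 variance denominator)
  m2b <- fit_cox_model(X2, clin2, ties = "breslow")
  expect_equal(unname(m2b$coefficients / m2b$scale),
               unname(m1$coefficients / m1$scale), tolerance = 1e-6)
  # Efron's tie correction deliberately deviates on the duplicated ties;
  # certify it against the independent Efron grid-search oracle instead
  m2e <- fit_cox_model(X2, clin2)
  oracle <- oracle_cox_grid(scale(X2), clin2$time, clin2$event)
  expect_lt(max(abs(unname(m2e$coefficients) - oracle)), 1e-3)
})

test_that("null features yield small coefficients at scale", {
  ok <- vapply(1:20, function(s) {
    withr::with_seed(2000 + s, {
      n <- 400L
      X <- feat_matrix(matrix(rnorm(n * 3L), ncol = 3L))
      clin <- toy_clinical(rexp(n, 0.03), rbinom(n, 1L, 0.7))
    })
    all(abs(fit_cox_model(X, clin)$coefficients) < 0.2)
  }, logical(1L))
  expect_gte(mean(ok), 0.9)
})

test_that("risk scores are the stored-parameter linear combination", {
  withr::with_seed(33, {
    X <- feat_matrix(matrix(rnorm(90), ncol = 3L))
    clin <- toy_clinical(rexp(30, 0.1), rep(1L, 30))
  })
  model <- fit_cox_model(X, clin)
  rs <- risk_scores(model, X)
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  expect_equal(unname(rs), unname(drop(Z %*% model$coefficients)),
               tolerance = 1e-12)
  # zero model
  model0 <- model
  model0$coefficients[] <- 0
  expect_identical(unname(risk_scores(model0, X)), rep(0, 30L))
  # shifting a raw feature in the scoring data moves RS by beta * shift / sd
  X_shift <- X
  X_shift[, 1L] <- X_shift[, 1L] + 5
  delta <- risk_scores(model, X_shift) - rs
  expect_equal(unname(delta),
               rep(unname(model$coefficients[1L]) * 5 / model$scale[[1L]], 30L),
               tolerance = 1e-12)
  expect_error(risk_scores(model, X[, 1:2]), "Missing model feature")
})

test_that("uncensored time-dependent ROC equals exhaustive counting", {
  clin <- toy_clinical(c(1, 2, 3, 8, 9, 10), rep(1L, 6L))
  rs <- c(2.5, 1.5, 3.5, 0.5, 1.0, -1)
  roc <- time_dependent_roc(rs, clin, horizon = 5)
  label <- clin$time <= 5  # all events: plain binary ROC
  for (i in seq_len(nrow(roc))) {
    cth <- roc$threshold[i]
    expect_equal(roc$sensitivity[i], mean(rs[label] >= cth), tolerance = 1e-12)
    expect_equal(roc$specificity[i], mean(rs[!label] < cth), tolerance = 1e-12)
  }
  # perfect ordering gives AUC 1; constant scores give 0.5
  expect_equal(attr(time_dependent_roc(-clin$time, clin, 5), "auc"), 1,
               tolerance = 1e-12)
  expect_equal(attr(time_dependent_roc(rep(1, 6L), clin, 5), "auc"), 0.5,
               tolerance = 1e-12)
  expect_error(time_dependent_roc(rs, clin, 0.5), "No events")
})

test_that("IPCW weights reduce to the plain ROC when censoring is absent", {
  withr::with_seed(41, {
    n <- 80L
    rs <- rnorm(n)
    clin <- toy_clinical(rexp(n, 0.05 * exp(rs)), rep(1L, n))
  })
  roc <- time_dependent_roc(rs, clin, horizon = 15)
  label <- clin$time <= 15
  idx <- sample(seq_len(nrow(roc)), 10L)
  for (i in idx) {
    cth <- roc$threshold[i]
    expect_equal(roc$sensitivity[i], mean(rs[label] >= cth), tolerance = 1e-9)
    expect_equal(roc$specificity[i], mean(rs[!label] < cth), tolerance = 1e-9)
  }
})

test_that("Youden cutoff equals exhaustive threshold search", {
  withr::with_seed(42, {
    rs <- rnorm(50)
    clin <- toy_clinical(rexp(50, 0.04 * exp(rs)), rbinom(50, 1L, 0.8))
  })
  roc <- time_dependent_roc(rs, clin, horizon = 20)
  cut <- youden_cutoff(roc)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(abs(j - max(j)) < 1e-12)
  expect_equal(as.numeric(cut), min(roc$threshold[best]), tolerance = 1e-15)
  expect_equal(attr(cut, "youden"), max(j), tolerance = 1e-12)
  # perfectly separated groups: J = 1, tie rule picks the smaller threshold
  clin2 <- toy_clinical(c(1, 2, 3, 50, 60, 70), rep(1L, 6L))
  roc2 <- time_dependent_roc(c(5, 4, 6, -1, -2, 0), clin2, horizon = 10)
  cut2 <- youden_cutoff(roc2)
  expect_equal(attr(cut2, "youden"), 1, tolerance = 1e-12)
  expect_equal(as.numeric(cut2), 4, tolerance = 1e-15)
  # constant scores: J = 0
  roc3 <- time_dependent_roc(rep(2, 6L), clin2, horizon = 10)
  expect_equal(attr(youden_cutoff(roc3), "youden"), 0, tolerance = 1e-12)
})

test_that("Kaplan-Meier estimate matches the hand product-limit toy", {
  clin <- toy_clinical(1:6, c(1L, 1L, 0L, 1L, 0L, 1L))
  km <- km_curve(clin)
  surv_at <- function(t) km$surv[match(t, km$time)]
  expect_equal(surv_at(1), 5 / 6, tolerance = 1e-12)
  expect_equal(surv_at(2), 2 / 3, tolerance = 1e-12)
  expect_equal(surv_at(4), 4 / 9, tolerance = 1e-12)
  expect_equal(surv_at(6), 0, tolerance = 1e-12)
  # all censored: survival stays at 1
  expect_true(all(km_curve(toy_clinical(1:5, rep(0L, 5L)))$surv == 1))
  # all events at distinct times: survival reaches 0
  km2 <- km_curve(toy_clinical(c(3, 1, 4, 2), rep(1L, 4L)))
  expect_equal(km2$surv[km2$time == 4], 0, tolerance = 1e-12)
})

test_that("log-rank test matches hand tabulation and its symmetries", {
  clin <- toy_clinical(c(2, 4, 6, 8, 10, 12, 14, 16),
                       c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L))
  grp <- rep(c("A", "B"), 4L)
  lr <- logrank_test(clin, grp)
  expect_equal(lr$statistic,
               oracle_logrank_chisq(clin$time, clin$event, grp),
               tolerance = 1e-9)
  grp_sw <- ifelse(grp == "A", "B", "A")
  expect_equal(logrank_test(clin, grp_sw)$statistic, lr$statistic,
               tolerance = 1e-12)
  # identical survival experience in both groups: statistic 0, p = 1
  clin2 <- toy_clinical(rep(c(1, 3, 5, 7), 2L), rep(c(1L, 0L, 1L, 1L), 2L))
  lr2 <- logrank_test(clin2, rep(c("A", "B"), each = 4L))
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(clin2, rep("A", 8L)), "2 non-empty")
})

test_that("group hazard ratio recovers planted rate ratios and nulls", {
  hrs <- vapply(1:20, function(s) {
    n <- 600L
    grp <- rep(c("high", "low"), each = n / 2L)
    rate <- ifelse(grp == "high", 0.025, 0.01)  # planted rate ratio 2.5
    withr::with_seed(3000 + s, {
      t_ev <- rexp(n, rate)
      clin <- toy_clinical(pmin(t_ev, 120), as.integer(t_ev <= 120))
    })
    group_hazard_ratio(clin, grp)$hr
  }, numeric(1L))
  expect_gt(mean(hrs), 2.0)
  expect_lt(mean(hrs), 3.1)
  # identical groups: HR near 1
  withr::with_seed(77, {
    t_ev <- rexp(600, 0.02)
    clin0 <- toy_clinical(pmin(t_ev, 100), as.integer(t_ev <= 100))
  })
  hr0 <- group_hazard_ratio(clin0, rep(c("high", "low"), 300L))
  expect_gt(hr0$hr, 0.8)
  expect_lt(hr0$hr, 1.25)
  expect_true(hr0$ci_low <= hr0$hr && hr0$hr <= hr0$ci_high)
})

test_that("concordance index equals the all-pairs oracle", {
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- 30L
      rs <- sample(rnorm(20), n, replace = TRUE)  # force some score ties
      t_ev <- rexp(n, 0.05 * exp(rs))
      cens <- runif(n, 0, 30)
      clin <- toy_clinical(pmin(t_ev, cens), as.integer(t_ev <= cens))
      expect_equal(concordance_index(rs, clin),
                   oracle_cindex(rs, clin$time, clin$event),
                   tolerance = 1e-12)
    }
  })
  clin <- toy_clinical(c(5, 3, 9, 1), rep(1L, 4L))
  expect_equal(concordance_index(-clin$time, clin), 1, tolerance = 1e-12)
  expect_equal(concordance_index(rep(1, 4L), clin), 0.5, tolerance = 1e-12)
})

test_that("report assembly and Youden-invariance under score rescaling", {
  co <- simulate_cohort(small_cohort_config(seed = 13L))
  raw <- t(unclass(co$expression))
  sig_genes <- unlist(lapply(co$truth$program_genes, head, 3L))
  model <- fit_cox_model(raw[, sig_genes], co$clinical, sig_genes)
  model <- calibrate_cutoff(model, raw[, sig_genes], co$clinical, horizon = 60)
  rep1 <- survival_report(model, raw[, sig_genes], co$clinical)
  expect_s3_class(rep1, "risk_report")
  expect_true(all(rep1$km$surv >= 0 & rep1$km$surv <= 1))
  expect_true(all(rep1$auc$auc > 0 & rep1$auc$auc < 1, na.rm = TRUE))
  # scaling all coefficients by c > 0 and recomputing the cutoff leaves the
  # grouping unchanged (Youden J is invariant to monotone RS transforms)
  model2 <- model
  model2$coefficients <- model$coefficients * 3
  model2 <- calibrate_cutoff(model2, raw[, sig_genes], co$clinical, horizon = 60)
  rep2 <- survival_report(model2, raw[, sig_genes], co$clinical)
  expect_identical(rep1$assignment$group, rep2$assignment$group)
  # glance exposes the headline numbers
  g <- glance(rep1)
  expect_true(all(c("hr", "c_index", "logrank_p", "auc_60") %in% names(g)))
})
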