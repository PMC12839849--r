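test_that("subtype enrichment reproduces the cross-product OR and exact tail", {
  groups <- rep(c("high", "low"), each = 40L)
  subtypes <- c(rep("CMS4", 30L), rep("CMS2", 10L),
                rep("CMS4", 10L), rep("CMS2", 30L))
  res <- subtype_enrichment(groups, subtypes, target = "CMS4")
  expect_equal(res$odds_ratio, 9, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_upper(30L, 10L, 10L, 30L), tolerance = 1e-12)
  # balanced table sits at the independence point
  bal <- subtype_enrichment(rep(c("high", "low"), each = 40L),
                            rep(rep(c("CMS4", "CMS2"), each = 20L), 2L))
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction keeps the OR finite and > 1
  zc <- subtype_enrichment(
    c(rep("high", 10L), rep("low", 10L)),
    c(rep("CMS4", 10L), rep("CMS4", 5L), rep("CMS1", 5L))
  )
  expect_true(is.finite(zc$odds_ratio) && zc$odds_ratio > 1)
  # NOLBL samples are excluded before collapsing
  res2 <- subtype_enrichment(c(groups, "high"), c(subtypes, "NOLBL"))
  expect_equal(res2$p, res$p, tolerance = 1e-15)
})

test_that("hypergeometric tail equals exhaustive enumeration on random tables", {
  withr::with_seed(61, {
    for (i in 1:200) {
      repeat {
        cells <- as.integer(rmultinom(1L, sample(10:40, 1L), rep(0.25, 4L)))
        if (all(cells[c(1, 3)] + cells[c(2, 4)] > 0L) &&
            cells[1] + cells[2] > 0L && cells[3] + cells[4] > 0L &&
            cells[1] + cells[3] > 0L && cells[2] + cells[4] > 0L) break
      }
      groups <- c(rep("high", cells[1] + cells[2]), rep("low", cells[3] + cells[4]))
      subtypes <- c(rep("CMS4", cells[1]), rep("CMS2", cells[2]),
                    rep("CMS4", cells[3]), rep("CMS2", cells[4]))
      res <- subtype_enrichment(groups, subtypes, target = "CMS4")
      expect_equal(res$p,
                   oracle_hyper_upper(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum comparisons follow the exact/approximate routing", {
  # a group against an exact copy of itself: fully tied, p = 1
  x <- withr::with_seed(62, rnorm(15))
  res <- compare_groups_continuous(c(x, x), rep(c("a", "b"), each = 15L))
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_match(res$method, "normal")
  # n1 = n2 = 4 with no ties: exact enumeration over all 70 assignments
  withr::with_seed(63, {
    for (i in 1:10) {
      v <- sample(seq(1, 40), 8L)
      g <- rep(c("a", "b"), each = 4L)
      res <- compare_groups_continuous(v, g)
      expect_match(res$method, "exact")
      expect_equal(res$p, oracle_wilcox_exact_p(v[1:4], v[5:8]),
                   tolerance = 1e-9)
    }
  })
  # statistic is invariant under strictly monotone transforms
  v <- withr::with_seed(64, rnorm(30))
  g <- rep(c("a", "b"), 15L)
  expect_equal(compare_groups_continuous(v, g)$statistic,
               compare_groups_continuous(exp(v), g)$statistic,
               tolerance = 1e-12)
})

test_that("categorical tests route on expected counts and match enumeration", {
  balanced <- matrix(c(5, 5, 5, 5), nrow = 2L)
  res <- compare_groups_categorical(balanced)
  expect_identical(res$method, "chi-square")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # low expected count routes to Fisher; p matches exhaustive enumeration
  sparse <- matrix(c(1, 9, 6, 4), nrow = 2L, byrow = TRUE)
  expect_lt(min(outer(rowSums(sparse), colSums(sparse)) / sum(sparse)), 5)
  res2 <- compare_groups_categorical(sparse)
  expect_identical(res2$method, "fisher")
  expect_equal(res2$p, oracle_fisher_p(sparse), tolerance = 1e-9)
  # chi-square equals the direct sum(O-E)^2/E formula on any table
  tab <- matrix(c(30, 20, 25, 15, 40, 10), nrow = 2L)
  res3 <- compare_groups_categorical(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res3$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_error(compare_groups_categorical(matrix(c(1, 1, 1, 1, 1, 1), 2L)),
               "2x2 only")
})

test_that("Fisher p matches enumeration on random small-margin tables", {
  withr::with_seed(65, {
    n_checked <- 0L
    while (n_checked < 50L) {
      tab <- matrix(rpois(4L, 4L), nrow = 2L)
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) next
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (all(expected >= 5)) next
      res <- compare_groups_categorical(tab)
      expect_equal(res$p, oracle_fisher_p(tab), tolerance = 1e-9)
      n_checked <- n_checked + 1L
    }
  })
})

test_that("immune infiltration scores 28 cell types and finds planted signal", {
  co <- simulate_cohort(cohort_config(seed = 14L, n_samples = 300L,
                                      n_genes = 1000L))
  groups <- ifelse(co$truth$subtype == "CMS1", "high", "low")
  imm_sets <- co$sets[grep("^immune_cell_", names(co$sets))]
  class(imm_sets) <- "gene_sets"
  res <- immune_infiltration(co$expression, imm_sets, groups)
  expect_identical(ncol(res$scores), 28L)
  expect_identical(nrow(res$contrasts), 28L)
  expect_true(all(res$contrasts$q >= res$contrasts$p))
  # the two immune programs embedded in the CMS1-like program score higher
  planted <- res$contrasts[res$contrasts$cell_type %in%
                             c("immune_cell_01", "immune_cell_02"), ]
  expect_true(all(planted$p < 0.01))
  expect_true(all(planted$direction == "higher in high-risk"))
})

test_that("BH adjustment is monotone and never below the raw p", {
  withr::with_seed(66, {
    p <- runif(40L)^2
    q <- p.adjust(p, method = "BH")
  })
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("pathway-feature correlation maps flag degenerate columns", {
  withr::with_seed(67, {
    feats <- matrix(rnorm(50 * 3L), nrow = 50,
                    dimnames = list(sprintf("s%02d", 1:50), c("fa", "fb", "fc")))
    paths <- matrix(rnorm(50 * 2L), nrow = 50,
                    dimnames = list(rownames(feats), c("wnt", "emt")))
  })
  feats[, "fa"] <- paths[, "wnt"]
  feats[, "fc"] <- 2
  cm <- pathway_feature_correlation(feats, paths)
  expect_equal(cm$r[cm$feature_id == "fa" & cm$pathway == "wnt"], 1,
               tolerance = 1e-12)
  expect_false("fc" %in% cm$feature_id)
  expect_identical(attr(cm, "flagged"), "fc")
  expect_true(all(cm$q >= cm$p))
})

test_that("linked radiomic features recover their planted pathway", {
  hits <- unlist(lapply(1:10, function(s) {
    cfg <- cohort_config(seed = 100L + s, n_samples = 300L, n_genes = 800L,
                         radiomic_loading = 3, radiomic_noise_sd = 0.5)
    co <- simulate_cohort(cfg)
    rad <- simulate_radiomic(co$expression, co$truth, cfg)
    acts <- program_activity(co$expression, co$truth)
    cm <- pathway_feature_correlation(rad, acts)
    nominal <- co$truth$radiomic$program
    vapply(names(nominal)[!is.na(nominal)], function(f) {
      sub <- cm[cm$feature_id == f, ]
      sub$pathway[which.max(abs(sub$r))] == nominal[[f]]
    }, logical(1L))
  }))
  expect_gte(mean(hits), 0.9)
})
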