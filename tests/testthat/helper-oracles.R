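# Independent oracles used across the suite. Each one is a deliberately
# naive re-derivation (literal running sums, O(n^2) pair counting, exhaustive
# enumeration, brute-force likelihood search) kept free of any package
# internals so it can certify them.

# literal position-by-position running-sum enrichment score for one sample
oracle_ssgsea_es <- function(values, gene_ids, set_members, alpha) {
  g <- length(values)
  ord <- order(-values, seq_len(g))
  ranked_ids <- gene_ids[ord]
  in_set <- ranked_ids %in% set_members
  rank_value <- g - seq_len(g) + 1
  w <- abs(rank_value)^alpha
  w[!in_set] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / sum(!in_set)
  sum(p_in - p_out)
}

# all-pairs Harrell C with risk-score ties counting 1/2
oracle_cindex <- function(rs, time, event) {
  num <- 0; den <- 0
  n <- length(rs)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      earlier <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
      if (is.na(earlier)) next            # tied times: not a usable pair here
      later <- if (earlier == i) j else i
      if (event[earlier] != 1L) next      # usable only if earlier time is an event
      den <- den + 1
      if (rs[earlier] > rs[later]) num <- num + 1
      else if (rs[earlier] == rs[later]) num <- num + 0.5
    }
  }
  num / den
}

# Efron-tie Cox partial log-likelihood, literal formula
oracle_efron_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1L]))) {
    D <- which(time == t & event == 1L)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(eta[R]))
    sum_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# two-stage dense grid search maximizing the Efron partial likelihood
oracle_cox_grid <- function(X, time, event, span = 2.5, coarse = 0.05,
                            fine = 5e-4) {
  grid_best <- function(centers, step, width) {
    b1 <- seq(centers[1L] - width, centers[1L] + width, by = step)
    b2 <- seq(centers[2L] - width, centers[2L] + width, by = step)
    best <- c(NA, NA); best_ll <- -Inf
    for (x1 in b1) {
      for (x2 in b2) {
        ll <- oracle_efron_loglik(c(x1, x2), X, time, event)
        if (ll > best_ll) {
          best_ll <- ll
          best <- c(x1, x2)
        }
      }
    }
    best
  }
  rough <- grid_best(c(0, 0), coarse, span)
  grid_best(rough, fine, 2 * coarse)
}

# hand O-E / hypergeometric-variance log-rank tabulation
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1L]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1L) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# exhaustive upper-tail hypergeometric probability via binomial coefficients
oracle_hyper_upper <- function(a, b, c, d) {
  # margins: target total a+c, other total b+d, high-group draw a+b
  m <- a + c; n_other <- b + d; k <- a + b
  support <- max(0L, k - n_other):min(k, m)
  probs <- choose(m, support) * choose(n_other, k - support) / choose(m + n_other, k)
  sum(probs[support >= a])
}

# exhaustive two-sided Fisher p for a 2x2 table
oracle_fisher_p <- function(tab) {
  a <- tab[1L, 1L]
  m <- sum(tab[, 1L]); n_other <- sum(tab[, 2L]); k <- sum(tab[1L, ])
  support <- max(0L, k - n_other):min(k, m)
  probs <- choose(m, support) * choose(n_other, k - support) / choose(m + n_other, k)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcox_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  r_all <- apply(combos, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  # symmetric two-sided rule: as or more extreme in |R - E[R]|
  mean(abs(r_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# small fast cohort for unit tests (full structure, reduced scale)
small_cohort_config <- function(seed = 1L, ...) {
  cohort_config(
    n_samples = 150L, n_genes = 400L, genes_per_program = 40L,
    sets_per_program = 3L, n_background_sets = 8L, gene_set_size = 20L,
    immune_set_size = 8L, n_radiomic = 12L, linked_per_program = 2L,
    seed = seed, ...
  )
}

small_classifier_config <- function(seed = 1L, ...) {
  classifier_config(hidden_layer_widths = c(32L, 16L, 10L), max_epochs = 60L,
                    patience = 10L, seed = seed, ...)
}

# deterministic toy clinical table
toy_clinical <- function(time, event, subtype = NULL) {
  df <- tibble::tibble(
    sample_id = sprintf("P%02d", seq_along(time)),
    time = time, event = event
  )
  if (!is.null(subtype)) df$subtype <- subtype
  as_clinical_table(df, time_unit = "months")
}
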