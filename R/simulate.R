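
#' Configuration for the synthetic multi-subtype cohort
#'
#' The generator plants the statistical structure the downstream analysis
#' assumes: four disjoint subtype expression programs on a log-scale
#' background, subtype-dependent exponential survival, 28 disjoint immune-cell
#' gene programs (two embedded in the CMS1-like immune program), and
#' pathway-linked radiomic features. Defaults describe a comfortably
#' recoverable but non-trivial cohort; every knob is exposed.
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes; must admit the four disjoint programs.
#' @param subtype_proportions Length-4 multinomial probabilities for
#'   CMS1..CMS4 membership (must sum to 1). Default reflects the skewed
#'   CMS mix typical of labelled CRC discovery cohorts.
#' @param genes_per_program Genes per subtype program (disjoint blocks).
#' @param program_effect Log-scale mean shift added to a program gene in
#'   samples of its subtype.
#' @param noise_sd Residual expression standard deviation.
#' @param baseline_mean_range Range of per-gene baseline means (uniform).
#' @param hazard_log_multipliers Length-4 log hazard multipliers per subtype;
#'   the default plants a poor-prognosis CMS4-like subtype (log 2.5).
#' @param baseline_hazard Exponential baseline event rate per month.
#' @param censoring_window Upper bound `C` of the Uniform(0, C) censoring
#'   time, months.
#' @param admin_horizon Administrative follow-up cap, months.
#' @param sets_per_program Program-tagging gene sets generated per subtype
#'   (each drawn 80% from the program, 20% from background genes).
#' @param n_background_sets Uninformative random gene sets.
#' @param gene_set_size Size of program and background sets.
#' @param n_immune_sets Disjoint immune-cell programs (first two embedded in
#'   the CMS1-like program).
#' @param immune_set_size Genes per immune-cell program.
#' @param label_mask_rate Fraction of subtype labels masked to `NOLBL`,
#'   emulating unlabelled samples of real cohorts.
#' @param n_radiomic Number of radiomic features.
#' @param linked_per_program Radiomic features linked to each subtype
#'   program; the remainder are pure noise.
#' @param radiomic_loading Linear loading of a linked radiomic feature on its
#'   (standardized) pathway activity.
#' @param radiomic_noise_sd Radiomic residual standard deviation.
#' @param seed Master seed; one sub-seed per generator component is derived
#'   from it so later stages never perturb earlier draws.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 600L,
                          n_genes = 2000L,
                          subtype_proportions = c(0.15, 0.45, 0.14, 0.26),
                          genes_per_program = 100L,
                          program_effect = 2,
                          noise_sd = 1,
                          baseline_mean_range = c(2, 12),
                          hazard_log_multipliers = c(0, -0.2, 0, log(2.5)),
                          baseline_hazard = 0.01,
                          censoring_window = 240,
                          admin_horizon = 120,
                          sets_per_program = 5L,
                          n_background_sets = 30L,
                          gene_set_size = 50L,
                          n_immune_sets = 28L,
                          immune_set_size = 15L,
                          label_mask_rate = 0.1,
                          n_radiomic = 30L,
                          linked_per_program = 5L,
                          radiomic_loading = 1.5,
                          radiomic_noise_sd = 1,
                          seed = 1L) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", 8L),
    n_genes = check_count(n_genes, "n_genes", 8L),
    subtype_proportions = subtype_proportions,
    genes_per_program = check_count(genes_per_program, "genes_per_program"),
    program_effect = check_scalar_number(program_effect, "program_effect", min = 0),
    noise_sd = check_scalar_number(noise_sd, "noise_sd"),
    baseline_mean_range = baseline_mean_range,
    hazard_log_multipliers = hazard_log_multipliers,
    baseline_hazard = check_scalar_number(baseline_hazard, "baseline_hazard"),
    censoring_window = check_scalar_number(censoring_window, "censoring_window"),
    admin_horizon = check_scalar_number(admin_horizon, "admin_horizon"),
    sets_per_program = check_count(sets_per_program, "sets_per_program"),
    n_background_sets = check_count(n_background_sets, "n_background_sets", 0L),
    gene_set_size = check_count(gene_set_size, "gene_set_size", 4L),
    n_immune_sets = check_count(n_immune_sets, "n_immune_sets", 2L),
    immune_set_size = check_count(immune_set_size, "immune_set_size", 2L),
    label_mask_rate = check_scalar_number(label_mask_rate, "label_mask_rate", 0, 1),
    n_radiomic = check_count(n_radiomic, "n_radiomic", 1L),
    linked_per_program = check_count(linked_per_program, "linked_per_program", 0L),
    radiomic_loading = check_scalar_number(radiomic_loading, "radiomic_loading", 0),
    radiomic_noise_sd = check_scalar_number(radiomic_noise_sd, "radiomic_noise_sd"),
    seed = check_count(seed, "seed")
  )
  pi <- cfg$subtype_proportions
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    abort("`subtype_proportions` must be 4 non-negative values summing to 1.")
  }
  if (cfg$noise_sd <= 0 || cfg$radiomic_noise_sd <= 0) {
    abort("Noise standard deviations must be > 0.")
  }
  if (4L * cfg$genes_per_program > cfg$n_genes) {
    abort("Infeasible block sizes: 4 * genes_per_program exceeds n_genes.")
  }
  n_bg_genes <- cfg$n_genes - 4L * cfg$genes_per_program
  if (2L * cfg$immune_set_size > cfg$genes_per_program) {
    abort("Infeasible block sizes: two immune sets do not fit in the CMS1 program.")
  }
  if ((cfg$n_immune_sets - 2L) * cfg$immune_set_size > n_bg_genes) {
    abort("Infeasible block sizes: background cannot host the disjoint immune sets.")
  }
  if (4L * cfg$linked_per_program > cfg$n_radiomic) {
    abort("Infeasible radiomic layout: 4 * linked_per_program exceeds n_radiomic.")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a multi-subtype expression cohort with survival and ground truth
#'
#' Expression follows `x_gj = baseline_g + effect * [g in program(subtype_j)]
#' + N(0, sd^2)`. Event times are exponential with rate
#' `baseline_hazard * exp(multiplier[subtype])`, censored by an independent
#' Uniform(0, C) dropout time and an administrative horizon. The generated
#' gene set collection holds `sets_per_program` program-tagging sets per
#' subtype, random background sets, and 28 disjoint immune-cell sets of which
#' the first two live inside the CMS1-like program. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `expression` (genes x samples),
#'   `clinical` (`clinical_tbl` with masked labels), `sets` (`gene_sets`),
#'   `truth` (planted memberships, program genes, hazard multipliers, immune
#'   program, radiomic layout).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- component_seeds(config$seed,
                           c("expression", "survival", "sets", "mask", "radiomic"))
  n <- config$n_samples
  g <- config$n_genes
  m <- config$genes_per_program
  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- sprintf("S%04d", seq_len(n))
  subtype_levels <- SUBTYPE_LEVELS[1:4]
  program_genes <- setNames(
    lapply(0:3, function(k) gene_ids[(k * m + 1L):((k + 1L) * m)]),
    subtype_levels
  )
  background_genes <- gene_ids[(4L * m + 1L):g]

  expr_truth <- with_seed(seeds[["expression"]], {
    subtype <- subtype_levels[
      sample.int(4L, n, replace = TRUE, prob = config$subtype_proportions)
    ]
    baseline <- runif(g, config$baseline_mean_range[1L], config$baseline_mean_range[2L])
    x <- matrix(rnorm(g * n, sd = config$noise_sd), nrow = g,
                dimnames = list(gene_ids, sample_ids))
    x <- x + baseline
    for (k in 1:4) {
      in_sub <- subtype == subtype_levels[k]
      if (any(in_sub)) {
        rows <- (k - 1L) * m + seq_len(m)
        x[rows, in_sub] <- x[rows, in_sub] + config$program_effect
      }
    }
    list(x = x, subtype = subtype)
  })

  surv <- with_seed(seeds[["survival"]], {
    rate <- config$baseline_hazard *
      exp(config$hazard_log_multipliers[match(expr_truth$subtype, subtype_levels)])
    t_event <- rexp(n, rate = rate)
    t_cens <- pmin(runif(n, 0, config$censoring_window), config$admin_horizon)
    tibble(
      sample_id = sample_ids,
      time = pmax(pmin(t_event, t_cens), 1e-6),
      event = as.integer(t_event <= t_cens)
    )
  })

  sets <- with_seed(seeds[["sets"]], {
    collection <- list()
    desc <- character()
    n_prog <- ceiling(0.8 * config$gene_set_size)
    for (k in 1:4) {
      for (s in seq_len(config$sets_per_program)) {
        members <- c(
          sample(program_genes[[k]], min(n_prog, m)),
          sample(background_genes, config$gene_set_size - min(n_prog, m))
        )
        nm <- sprintf("program_%s_set%02d", subtype_levels[k], s)
        collection[[nm]] <- members
        desc <- c(desc, sprintf("%s program tagging set", subtype_levels[k]))
      }
    }
    for (s in seq_len(config$n_background_sets)) {
      nm <- sprintf("background_set%02d", s)
      collection[[nm]] <- sample(gene_ids, config$gene_set_size)
      desc <- c(desc, "random background set")
    }
    # 28 disjoint immune-cell programs; cells 1-2 are embedded in the
    # CMS1-like program so immune infiltration tracks the immune subtype
    cms1_pool <- sample(program_genes[["CMS1"]])
    bg_pool <- sample(background_genes)
    for (s in seq_len(config$n_immune_sets)) {
      nm <- sprintf("immune_cell_%02d", s)
      if (s <= 2L) {
        idx <- ((s - 1L) * config$immune_set_size + 1L):(s * config$immune_set_size)
        collection[[nm]] <- cms1_pool[idx]
      } else {
        idx <- ((s - 3L) * config$immune_set_size + 1L):((s - 2L) * config$immune_set_size)
        collection[[nm]] <- bg_pool[idx]
      }
      desc <- c(desc, sprintf("immune cell program %02d", s))
    }
    gene_sets(collection, desc)
  })

  subtype_lbl <- with_seed(seeds[["mask"]], {
    lbl <- expr_truth$subtype
    if (config$label_mask_rate > 0) {
      masked <- runif(n) < config$label_mask_rate
      lbl[masked] <- "NOLBL"
    }
    lbl
  })

  clinical <- as_clinical_table(
    dplyr::mutate(surv, subtype = subtype_lbl, cohort = "synthetic"),
    time_unit = "months"
  )

  radiomic_layout <- radiomic_plan(config, seeds[["radiomic"]])

  truth <- structure(list(
    subtype = setNames(expr_truth$subtype, sample_ids),
    program_genes = program_genes,
    background_genes = background_genes,
    hazard_log_multipliers = setNames(config$hazard_log_multipliers, subtype_levels),
    immune_program_sets = names(sets)[grepl("^immune_cell_0[12]$", names(sets))],
    immune_program_genes = unique(unlist(sets[grepl("^immune_cell_0[12]$", names(sets))])),
    radiomic = radiomic_layout,
    seeds = seeds
  ), class = "synthetic_truth")

  structure(list(
    expression = as_expression_matrix(expr_truth$x),
    clinical = clinical,
    sets = sets,
    truth = truth,
    config = config
  ), class = "synthetic_cohort")
}

# fixed assignment of radiomic features to programs plus the per-feature
# loading matrix recorded as ground truth; `program` keeps the nominal
# assignment even when the loading is zero (null simulations)
radiomic_plan <- function(config, seed) {
  feats <- sprintf("radiomic_f%02d", seq_len(config$n_radiomic))
  programs <- SUBTYPE_LEVELS[1:4]
  loading <- matrix(0, nrow = config$n_radiomic, ncol = 4L,
                    dimnames = list(feats, programs))
  assignment <- setNames(rep(NA_character_, config$n_radiomic), feats)
  k <- config$linked_per_program
  if (k > 0L) {
    for (p in 1:4) {
      rows <- ((p - 1L) * k + 1L):(p * k)
      loading[rows, p] <- config$radiomic_loading
      assignment[rows] <- programs[p]
    }
  }
  list(feature_ids = feats, loading = loading, program = assignment,
       seed = unname(seed))
}

#' Mean program expression per sample, standardized across samples
#'
#' The "pathway activity" that linked radiomic features load on: for each
#' subtype program, the mean expression of its genes in each sample, z-scored
#' across the cohort.
#'
#' @param expr Genes x samples expression matrix.
#' @param truth A `synthetic_truth` object.
#' @return Samples x 4 matrix of standardized program activities.
#' @export
program_activity <- function(expr, truth) {
  acts <- vapply(truth$program_genes, function(gs) {
    v <- colMeans(expr[gs, , drop = FALSE])
    as.vector(scale(v))
  }, numeric(ncol(expr)))
  rownames(acts) <- colnames(expr)
  acts
}

#' Simulate pathway-linked radiomic features
#'
#' A linked feature is `loading * activity(program, sample) + noise`; the
#' remaining features are pure noise. Deterministic given the cohort's seed.
#'
#' @param expr Genes x samples expression matrix of the same cohort.
#' @param truth The cohort's `synthetic_truth`.
#' @param config The cohort's `cohort_config`.
#' @return Samples x radiomic-features numeric matrix.
#' @export
simulate_radiomic <- function(expr, truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "cohort_config"))
  if (!identical(colnames(expr), names(truth$subtype))) {
    abort("Sample mismatch between expression matrix and synthetic truth.")
  }
  acts <- program_activity(expr, truth)
  loading <- truth$radiomic$loading
  with_seed(truth$radiomic$seed, {
    noise <- matrix(rnorm(ncol(expr) * nrow(loading), sd = config$radiomic_noise_sd),
                    nrow = ncol(expr),
                    dimnames = list(colnames(expr), rownames(loading)))
    acts %*% t(loading) + noise
  })
}
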