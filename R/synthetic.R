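#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with pathway-level planted signal. Informative gene sets
#' are co-expressed blocks driven by a per-sample latent factor
#' (`member = loading * factor + noise_sd * eps`, plus a per-gene baseline
#' mean and scale), and the hazard acts on the latent factors, so each
#' member gene is individually noisy while the set as a whole is
#' informative. Decoy sets draw random noise genes. The orphan fraction
#' plants *hidden* informative blocks — latent-factor pathways whose genes
#' are excluded from the gene-set collection — emulating incomplete
#' biological annotation: `round(orphan_fraction / (1 - orphan_fraction) *
#' n_informative)` hidden blocks, so the requested fraction of signal genes
#' belongs to no set. `n_orphan_genes` additionally plants standalone
#' single genes with a direct hazard effect.
#'
#' Survival times are exponential with rate `baseline_rate * exp(eta)`;
#' independent exponential censoring has its rate solved numerically so the
#' expected censoring fraction matches `censoring_rate`.
#'
#' @param n_genes total genes in the matrix.
#' @param n_train,n_test training / test cohort sizes.
#' @param n_sets number of annotated gene sets (informative + decoy).
#' @param set_size_range inclusive range member counts are drawn from.
#' @param n_informative number of annotated sets carrying a latent hazard
#'   factor.
#' @param loading latent-factor loading of informative members; within-set
#'   correlation is `loading^2 / (loading^2 + noise_sd^2)`.
#' @param factor_cor correlation between any two latent pathway factors,
#'   induced by a shared per-sample severity axis (factors of co-affected
#'   pathways are not independent in real cohorts).
#' @param noise_sd residual SD of member expression around the factor.
#' @param beta_factor log hazard ratio per unit of each visible latent factor.
#' @param orphan_fraction fraction of signal genes excluded from every set.
#' @param beta_orphan log hazard ratio per unit of each hidden factor /
#'   standalone orphan gene.
#' @param n_orphan_genes standalone signal genes with a direct hazard effect.
#' @param baseline_rate exponential baseline hazard rate.
#' @param censoring_rate target censoring fraction, in \[0, 1).
#' @param seed integer seed; one seed drives the whole draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3000, n_train = 150, n_test = 150,
                       n_sets = 200, set_size_range = c(10, 50),
                       n_informative = 5, loading = 0.3, noise_sd = 1,
                       factor_cor = 0.3, beta_factor = 0.6, orphan_fraction = 0,
                       beta_orphan = 0.6, n_orphan_genes = 0,
                       baseline_rate = 0.1, censoring_rate = 0.3, seed = 1) {
  cfg <- list(n_genes = n_genes, n_train = n_train, n_test = n_test,
              n_sets = n_sets, set_size_range = set_size_range,
              n_informative = n_informative, loading = loading,
              noise_sd = noise_sd, factor_cor = factor_cor,
              beta_factor = beta_factor,
              orphan_fraction = orphan_fraction, beta_orphan = beta_orphan,
              n_orphan_genes = n_orphan_genes, baseline_rate = baseline_rate,
              censoring_rate = censoring_rate, seed = seed)
  with(cfg, {
    stopifnot(n_genes >= 1, n_train >= 4, n_test >= 2, n_sets >= 1,
              n_informative >= 0, n_informative <= n_sets,
              length(set_size_range) == 2, set_size_range[1] >= 1,
              set_size_range[2] >= set_size_range[1],
              loading >= 0, noise_sd > 0, baseline_rate > 0,
              factor_cor >= 0, factor_cor <= 1,
              n_orphan_genes >= 0)
    if (orphan_fraction < 0 || orphan_fraction >= 1) {
      abort("orphan_fraction must be in [0, 1)")
    }
    if (censoring_rate < 0 || censoring_rate >= 1) {
      abort("censoring_rate must be in [0, 1): heavier censoring is infeasible")
    }
  })
  structure(cfg, class = "sim_config")
}

# sample that never collapses a length-1 vector into 1:x
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# censoring rate c such that mean_j c / (c + lambda_j) = target, for
# exponential event rates lambda_j and independent exponential censoring.
solve_censoring_rate <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) - target
  uniroot(f, lower = log(min(lambda)) - 20, upper = log(max(lambda)) + 20,
          tol = 1e-10)$root |> exp()
}

draw_survival <- function(eta, baseline_rate, censoring_rate, prefix) {
  lambda <- baseline_rate * exp(eta)
  t_event <- rexp(length(eta), rate = lambda)
  if (censoring_rate > 0) {
    cr <- solve_censoring_rate(lambda, censoring_rate)
    t_cens <- rexp(length(eta), rate = cr)
    time <- pmin(t_event, t_cens)
    event <- as.numeric(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1, length(eta))
  }
  survival_data(sprintf("%s%03d", prefix, seq_along(eta)), time, event)
}

#' Generate a synthetic cohort with planted pathway-level signal
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_cohort`: `expr_train`, `expr_test` (genes x
#'   samples matrices), `surv_train`, `surv_test` (`survival_data`),
#'   `collection` (annotated [gene_set_collection()]), and `truth` — the
#'   planted structure (`informative_sets`, `orphan_genes`,
#'   `factors_train/test`, `eta_train/test`, per-gene block assignment).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)

  n_hidden <- if (cfg$orphan_fraction > 0) {
    max(1L, round(cfg$orphan_fraction / (1 - cfg$orphan_fraction) * cfg$n_informative))
  } else 0L
  size_pool <- seq(cfg$set_size_range[1], cfg$set_size_range[2])
  sizes_vis <- resample(size_pool, cfg$n_informative)
  sizes_hid <- if (n_hidden > 0) resample(size_pool, n_hidden) else integer()
  n_signal <- sum(sizes_vis) + sum(sizes_hid) + cfg$n_orphan_genes
  if (n_signal > cfg$n_genes) {
    abort("n_genes too small for the requested signal structure")
  }

  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  # signal genes occupy a random subset of gene ids (position uninformative)
  signal_pos <- sample(cfg$n_genes, n_signal)
  blocks <- c(rep(seq_len(cfg$n_informative), sizes_vis),
              if (n_hidden > 0) rep(cfg$n_informative + seq_len(n_hidden), sizes_hid))
  vis_genes <- split(gene_ids[signal_pos[seq_along(blocks)]], blocks)
  orphan_single <- if (cfg$n_orphan_genes > 0) {
    gene_ids[signal_pos[length(blocks) + seq_len(cfg$n_orphan_genes)]]
  } else character()
  decoy_pool <- setdiff(gene_ids, c(unlist(vis_genes), orphan_single))

  # annotated collection: informative sets first, then decoys on noise genes
  sets <- list()
  for (s in seq_len(cfg$n_informative)) sets[[sprintf("SET%04d", s)]] <- vis_genes[[s]]
  for (s in seq_len(cfg$n_sets - cfg$n_informative)) {
    m <- resample(size_pool, 1)
    sets[[sprintf("SET%04d", cfg$n_informative + s)]] <-
      sample(decoy_pool, min(m, length(decoy_pool)))
  }
  collection <- gene_set_collection(sets, name = "synthetic")
  informative_sets <- names(sets)[seq_len(cfg$n_informative)]

  # per-gene baseline mean and scale, shared by train and test
  base_mu <- rnorm(cfg$n_genes, mean = 7, sd = 2)
  base_sc <- runif(cfg$n_genes, 0.5, 1.5)
  # latent factors: one per hazard block (visible + hidden, correlated via a
  # shared severity axis) and one per decoy set (independent co-expression
  # modules — annotated pathways are coherent whether or not they relate to
  # outcome, and a realistic transcriptome is full of non-prognostic modules)
  n_haz <- cfg$n_informative + n_hidden
  factor_genes <- c(
    if (n_haz > 0) split(gene_ids[signal_pos[seq_along(blocks)]], blocks)
    else list(),
    unname(sets[setdiff(names(sets), informative_sets)]))
  n_factors <- length(factor_genes)
  L <- if (n_factors > 0) {
    gidx <- match(unlist(factor_genes, use.names = FALSE), gene_ids)
    Matrix::sparseMatrix(i = gidx,
                         j = rep.int(seq_len(n_factors), lengths(factor_genes)),
                         x = cfg$loading,
                         dims = c(cfg$n_genes, n_factors))
  }

  draw_cohort <- function(n, prefix) {
    Fm <- matrix(rnorm(n_factors * n), nrow = n_factors, ncol = n)
    if (n_haz > 0 && cfg$factor_cor > 0) {
      common <- rnorm(n)  # shared severity axis across hazard pathways
      Fm[seq_len(n_haz), ] <-
        sqrt(cfg$factor_cor) * matrix(common, nrow = n_haz, ncol = n, byrow = TRUE) +
        sqrt(1 - cfg$factor_cor) * Fm[seq_len(n_haz), , drop = FALSE]
    }
    raw <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd), nrow = cfg$n_genes)
    if (n_factors > 0) raw <- raw + as.matrix(L %*% Fm)
    z_orphan <- if (cfg$n_orphan_genes > 0) {
      idx <- match(orphan_single, gene_ids)
      z <- matrix(rnorm(cfg$n_orphan_genes * n), nrow = cfg$n_orphan_genes)
      raw[idx, ] <- z  # orphan singles: unit-variance signal, no extra noise
      z
    } else matrix(0, nrow = 0, ncol = n)
    expr <- base_mu + base_sc * raw
    rownames(expr) <- gene_ids
    colnames(expr) <- sprintf("%s%03d", prefix, seq_len(n))
    beta <- c(rep(cfg$beta_factor, cfg$n_informative),
              rep(cfg$beta_orphan, n_hidden))
    Fh <- Fm[seq_len(n_haz), , drop = FALSE]
    eta <- as.numeric(crossprod(Fh, beta))
    if (length(eta) == 0) eta <- rep(0, n)
    if (cfg$n_orphan_genes > 0) {
      eta <- eta + cfg$beta_orphan * colSums(z_orphan) / sqrt(cfg$n_orphan_genes)
    }
    list(expr = expr, eta = eta, factors = Fh)
  }

  tr <- draw_cohort(cfg$n_train, "TR")
  te <- draw_cohort(cfg$n_test, "TE")
  surv_train <- draw_survival(tr$eta, cfg$baseline_rate, cfg$censoring_rate, "TR")
  surv_test <- draw_survival(te$eta, cfg$baseline_rate, cfg$censoring_rate, "TE")

  orphan_genes <- c(if (n_hidden > 0) unlist(factor_genes[cfg$n_informative + seq_len(n_hidden)],
                                             use.names = FALSE),
                    orphan_single)
  structure(list(
    expr_train = tr$expr, expr_test = te$expr,
    surv_train = surv_train, surv_test = surv_test,
    collection = collection,
    truth = list(informative_sets = informative_sets,
                 orphan_genes = orphan_genes,
                 hidden_blocks = if (n_hidden > 0)
                   factor_genes[cfg$n_informative + seq_len(n_hidden)] else list(),
                 factors_train = tr$factors, factors_test = te$factors,
                 eta_train = tr$eta, eta_test = te$eta),
    config = cfg),
    class = "sim_cohort")
}

#' Realized summary statistics of a simulated cohort
#'
#' @param sim a [simulate_cohort()] result.
#' @return A list: `censoring_train`, `censoring_test` (realized censoring
#'   fractions), `mean_within_set_cor` (mean pairwise Pearson correlation
#'   within informative sets, training samples), and `gene_scores` (tibble
#'   of marginal per-gene Cox scores on the training cohort).
#' @export
realized_stats <- function(sim) {
  stopifnot(inherits(sim, "sim_cohort"))
  info_sets <- sim$truth$informative_sets
  cors <- vapply(info_sets, function(s) {
    g <- sim$collection$sets[[s]]
    cm <- cor(t(sim$expr_train[g, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  s <- cox_score_matrix(sim$expr_train, sim$surv_train$time, sim$surv_train$event)
  list(censoring_train = mean(sim$surv_train$event == 0),
       censoring_test = mean(sim$surv_test$event == 0),
       mean_within_set_cor = if (length(cors)) mean(cors) else NA_real_,
       gene_scores = tibble::tibble(gene_id = rownames(sim$expr_train),
                                    score = as.numeric(s)))
}
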