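fit_fixture <- function(seed = 61, n_genes = 40, n_samples = 50, n_sets = 6) {
  withr::local_seed(seed)
  expr <- random_expr(n_genes, n_samples)
  sets <- replicate(n_sets, sample(rownames(expr), sample(3:8, 1)), simplify = FALSE)
  names(sets) <- paste0("S", seq_len(n_sets))
  surv <- random_surv_instance(n_samples)
  surv$sample_id <- colnames(expr)
  fm <- feature_matrix(expr, gene_set_collection(sets))
  list(expr = expr, surv = surv, fm = fm)
}

test_that("with unit weights the predictor is conventional first-PC scores", {
  fx <- fit_fixture()
  sg_ids <- fx$fm$info$feature_id[fx$fm$info$kind == "single_gene"]
  fm_sg <- subset_features(fx$fm, sg_ids)
  p <- fit_predictor(fm_sg, fx$surv)
  pc1 <- prcomp(t(fm_sg$values), center = TRUE, scale. = FALSE)$x[, 1]
  risk <- p$train_risk
  # align the arbitrary PC sign before comparing
  if (cor(risk, pc1) < 0) pc1 <- -pc1
  expect_equal(unname(risk), unname(pc1), tolerance = 1e-10)
})

test_that("a single selected feature yields an affine copy of that feature", {
  fx <- fit_fixture(seed = 62)
  one <- subset_features(fx$fm, fx$fm$info$feature_id[1])
  p <- fit_predictor(one, fx$surv)
  risk <- p$train_risk
  feat <- one$values[1, ]
  expect_equal(abs(cor(risk, feat)), 1, tolerance = 1e-10)
  c_risk <- harrell_c(risk, fx$surv)
  c_feat <- harrell_c(feat, fx$surv)
  # up to orientation, the predictor's C is the feature's C
  expect_true(any(abs(c_risk - c(c_feat, 1 - c_feat)) < 1e-10))
})

test_that("the weighted first PC matches a brute-force SVD oracle", {
  # 2 features with member counts (3, 1) on 4 samples, computed explicitly
  X <- rbind(f1 = c(1, 2, 3, 4), f2 = c(2, 1, 0, 2))
  colnames(X) <- paste0("s", 1:4)
  surv <- survival_data(colnames(X), c(4, 3, 2, 1), rep(1, 4))
  fm <- structure(list(
    values = X,
    info = tibble::tibble(feature_id = c("f1", "f2"),
                          kind = "gene_set", name = c("f1", "f2"),
                          n_members = c(3L, 1L)),
    model = structure(list(mu = numeric(), sigma = numeric(),
                           dropped = character()),
                      class = "standardization_model"),
    sets = list(), set_params = NULL, include_single_genes = FALSE,
    collection = NULL, expr = NULL), class = "feature_matrix")
  p <- fit_predictor(fm, surv)

  A <- diag(c(3, 1)) %*% (X - rowMeans(X))   # the weighted centered matrix
  full <- svd(A)                             # brute-force full SVD
  oracle_scores <- full$d[1] * full$v[, 1]
  if (cor(p$train_risk, oracle_scores) < 0) oracle_scores <- -oracle_scores
  expect_equal(unname(p$train_risk), oracle_scores, tolerance = 1e-10)
  expect_equal(sum(p$w^2), 1, tolerance = 1e-12)
})

test_that("predicting on the training matrix reproduces the training scores", {
  fx <- fit_fixture(seed = 63)
  ids <- score_all(fx$fm, fx$surv)
  sel <- select_features(ids, quantile(ids$abs_score, 0.7))
  p <- fit_predictor(subset_features(fx$fm, sel), fx$surv)
  r <- predict_risk(p, fx$expr)
  expect_equal(r$risk, unname(p$train_risk), tolerance = 1e-10)
  expect_identical(r$sample_id, colnames(fx$expr))
})

test_that("duplicated test samples get identical risks and missing genes are named", {
  fx <- fit_fixture(seed = 64)
  p <- fit_predictor(subset_features(fx$fm, fx$fm$info$feature_id[1:5]), fx$surv)
  test_expr <- fx$expr[, c(1, 1, 2), drop = FALSE]
  colnames(test_expr) <- c("d1", "d2", "x")
  r <- predict_risk(p, test_expr)
  expect_equal(r$risk[1], r$risk[2], tolerance = 1e-14)
  dropped <- fx$expr[-1, , drop = FALSE]
  expect_error(predict_risk(p, dropped), rownames(fx$expr)[1])
})

test_that("scaling all member counts rescales risks without reordering", {
  fx <- fit_fixture(seed = 65)
  ids <- fx$fm$info$feature_id[c(1:4, 10:15)]
  fm_sel <- subset_features(fx$fm, ids)
  p1 <- fit_predictor(fm_sel, fx$surv)
  fm_scaled <- fm_sel
  fm_scaled$info$n_members <- fm_sel$info$n_members * 7L
  p2 <- fit_predictor(fm_scaled, fx$surv)
  r1 <- p1$train_risk
  r2 <- p2$train_risk
  expect_equal(unname(r2), unname(7 * r1), tolerance = 1e-8)
  expect_identical(order(r1), order(r2))
})

test_that("orientation makes the training Cox coefficient non-negative", {
  for (s in 1:10) {
    fx <- fit_fixture(seed = 70 + s, n_genes = 25, n_samples = 40)
    p <- fit_predictor(subset_features(fx$fm, fx$fm$info$feature_id[1:6]), fx$surv)
    cf <- survival::coxph(
      survival::Surv(fx$surv$time, fx$surv$event) ~ p$train_risk,
      ties = "breslow")$coefficients[1]
    expect_gte(unname(cf), 0)
  }
})

test_that("hybrid beats the pure pools when annotation is incomplete", {
  n_rep <- 8
  c_h <- c_g <- c_s <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_cohort(sim_config(
      n_genes = 250, n_train = 100, n_test = 120, n_sets = 40,
      set_size_range = c(8, 20), n_informative = 4, orphan_fraction = 0.3,
      seed = 400 + r))
    for (m in c("hybrid", "geneset_only", "single_gene_only")) {
      fit <- train_risk_model(sim$expr_train, sim$surv_train, sim$collection,
                              mode = m, n_repeats = 4, grid_size = 6, seed = r)
      cc <- harrell_c(predict(fit, sim$expr_test)$risk, sim$surv_test)
      if (m == "hybrid") c_h[r] <- cc
      else if (m == "geneset_only") c_g[r] <- cc
      else c_s[r] <- cc
    }
  }
  expect_gte(mean(c_h), mean(c_g) - 0.01)
  expect_gte(mean(c_h), mean(c_s) - 0.01)
  expect_gt(mean(c_h), 0.5)
})

test_that("predictors serialize to JSON and back without changing predictions", {
  fx <- fit_fixture(seed = 80)
  ids <- fx$fm$info$feature_id[c(1:3, 12:20)]
  p <- fit_predictor(subset_features(fx$fm, ids), fx$surv)
  path <- withr::local_tempfile(fileext = ".json")
  write_predictor(p, path)
  p2 <- read_predictor(path)
  withr::local_seed(1)
  test_expr <- random_expr(40, 10)
  rownames(test_expr) <- rownames(fx$expr)
  expect_equal(predict_risk(p2, test_expr)$risk,
               predict_risk(p, test_expr)$risk, tolerance = 1e-12)
})
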