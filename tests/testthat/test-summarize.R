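test_that("standardization uses sample SD, drops constant genes, and is training-frozen", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, 4, 9))
  colnames(expr) <- c("a", "b", "c")
  expect_warning(model <- fit_standardization(expr), "constant")
  expect_equal(unname(model$mu["g1"]), 2)
  expect_equal(unname(model$sigma["g1"]), 1)  # sample SD, n-1 denominator
  expect_identical(model$dropped, "g2")

  # applying the model to its own training data gives mean-0, SD-1 rows
  withr::local_seed(2)
  big <- random_expr(50, 20)
  m <- fit_standardization(big)
  e1 <- apply_standardization(big, m)
  expect_lt(max(abs(rowMeans(e1))), 1e-10)
  expect_lt(max(abs(apply(e1, 1, sd) - 1)), 1e-10)

  # test data standardized with the *training* parameters keeps its shift
  shifted <- big + 3
  e2 <- apply_standardization(shifted, m)
  expect_true(all(abs(rowMeans(e2)) > 0.5))

  expect_equal(unname(apply_standardization(
    matrix(4, 1, 2, dimnames = list("g", c("x", "y"))),
    structure(list(mu = c(g = 2), sigma = c(g = 1), dropped = character()),
              class = "standardization_model"))[1, 1]), 2)
  expect_error(fit_standardization(matrix(1, 3, 3, dimnames = list(letters[1:3], letters[4:6]))),
               "constant")
})

test_that("maxmean matches hand-evaluated values and its sign properties", {
  expect_equal(maxmean(c(0, 0, 0)), 0)
  expect_equal(maxmean(c(1.0, -0.5, 0.25)), 1.25 / 3)
  expect_equal(maxmean(c(-1.0, -1.0, 0.5)), -2 / 3)
  # tie between positive and negative mean parts resolves to the positive part
  expect_equal(maxmean(c(1, -1)), 0.5)
  expect_error(maxmean(matrix(numeric(0), nrow = 0)), "empty")

  withr::local_seed(3)
  for (i in 1:20) {
    v <- rnorm(7)
    expect_equal(maxmean(v), maxmean(sample(v)))      # permutation invariance
    expect_gte(maxmean(abs(v)), 0)                    # sign coherence
    expect_lte(maxmean(-abs(v)), 0)
  }
})

test_that("gene-set features conserve the average member mean and variance", {
  withr::local_seed(4)
  expr <- random_expr(60, 100)
  sets <- replicate(8, sample(rownames(expr), 5), simplify = FALSE)
  names(sets) <- paste0("S", 1:8)
  col <- gene_set_collection(sets)
  fm <- feature_matrix(expr, col, include_single_genes = FALSE)
  for (k in seq_len(nrow(fm$values))) {
    members <- fm$sets[[fm$info$name[k]]]
    expect_equal(mean(fm$values[k, ]), mean(rowMeans(expr[members, ])),
                 tolerance = 1e-8)
    expect_equal(var(fm$values[k, ]), mean(apply(expr[members, ], 1, var)),
                 tolerance = 1e-8)
  }
})

test_that("rescale contract forces shared member scale and rejects degenerate summaries", {
  withr::local_seed(5)
  u <- rnorm(40)
  r <- rescale_geneset(u, member_mu = c(3, 3, 3), member_sigma = c(2, 2, 2))
  expect_equal(mean(r$x), 3, tolerance = 1e-10)
  expect_equal(sd(r$x), 2, tolerance = 1e-10)
  expect_null(rescale_geneset(rep(1, 10), 0, 1))
})

test_that("a one-member gene set reproduces the raw expression exactly", {
  withr::local_seed(6)
  expr <- random_expr(30, 25)
  singles <- setNames(as.list(rownames(expr)), paste0("ONE_", rownames(expr)))
  fm <- feature_matrix(expr, gene_set_collection(singles),
                       include_single_genes = FALSE)
  for (k in seq_len(nrow(fm$values))) {
    gene <- fm$sets[[fm$info$name[k]]]
    expect_equal(unname(fm$values[k, ]), unname(expr[gene, ]), tolerance = 1e-12)
  }
})

test_that("feature counts follow the hybrid flag and ids are namespaced", {
  withr::local_seed(7)
  expr <- random_expr(10, 20)
  sets <- list(A = rownames(expr)[1:3], B = rownames(expr)[4:6],
               C = rownames(expr)[7:9])
  col <- gene_set_collection(sets)
  fm_h <- feature_matrix(expr, col, include_single_genes = TRUE)
  expect_equal(nrow(fm_h$values), 13)
  expect_setequal(unique(fm_h$info$kind), c("gene_set", "single_gene"))
  fm_g <- feature_matrix(expr, col, include_single_genes = FALSE)
  expect_equal(nrow(fm_g$values), 3)
  expect_true(all(startsWith(fm_g$info$feature_id, "GS:")))
  # set members absent from the matrix are intersected out; N reflects it
  col2 <- gene_set_collection(list(A = c(rownames(expr)[1:3], "ABSENT")))
  fm2 <- feature_matrix(expr, col2, include_single_genes = FALSE)
  expect_equal(unname(fm2$info$n_members), 3L)
  # a set with no member present is dropped entirely
  col3 <- gene_set_collection(list(A = rownames(expr)[1:3], GONE = "NOPE"))
  expect_equal(nrow(feature_matrix(expr, col3, include_single_genes = FALSE)$values), 1)
})

test_that("test features rebuilt from stored parameters match a literal recomputation", {
  withr::local_seed(8)
  sim <- simulate_cohort(quick_cfg(seed = 21))
  fm <- feature_matrix(sim$expr_train, sim$collection)
  rebuilt <- rebuild_features(fm, sim$expr_test)

  # literal feature-by-feature recomputation from the stored recipe
  for (k in sample(nrow(rebuilt), 10)) {
    id <- fm$info$feature_id[k]
    if (fm$info$kind[k] == "single_gene") {
      expect_equal(rebuilt[id, ], sim$expr_test[fm$info$name[k], ],
                   tolerance = 1e-12)
    } else {
      members <- fm$sets[[fm$info$name[k]]]
      p <- fm$set_params[fm$set_params$name == fm$info$name[k], ]
      ep <- (sim$expr_test[members, , drop = FALSE] - fm$model$mu[members]) /
        fm$model$sigma[members]
      u <- apply(ep, 2, function(v) {
        pp <- mean(pmax(v, 0)); nn <- mean(pmin(v, 0))
        if (abs(pp) >= abs(nn)) pp else nn
      })
      x <- (u - p$u_mean) / p$u_sd * p$scale + p$center
      expect_equal(unname(rebuilt[id, ]), unname(x), tolerance = 1e-12)
    }
  }
  # training self-rebuild reproduces the stored training values
  expect_equal(rebuild_features(fm, sim$expr_train), fm$values, tolerance = 1e-12)
})
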