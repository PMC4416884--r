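#' Train a hybrid gene-set / single-gene survival risk model
#'
#' Runs the full training pipeline: build the feature matrix (gene-set
#' maxmean indices and/or single-gene pseudo sets), score every feature with
#' the Cox score statistic, tune the score threshold by repeated
#' event-stratified 3-fold cross-validation, select the surviving features
#' on the full training scores, and fit the membership-weighted first-PC
#' predictor.
#'
#' @param expr numeric matrix, genes x samples (training cohort).
#' @param surv `survival_data` for the same samples (any order; sample sets
#'   must match exactly).
#' @param collection a [gene_set_collection()]; may be `NULL` for
#'   `mode = "single_gene_only"`.
#' @param mode feature pool: `"hybrid"` (gene sets + single genes),
#'   `"geneset_only"`, or `"single_gene_only"`.
#' @param n_folds,n_repeats,grid_size cross-validation settings (defaults:
#'   3 folds, 100 repeats, 20 thresholds).
#' @param seed integer seed for the CV fold draws.
#' @param weight predictor weighting, see [fit_predictor()].
#' @return An object of class `risk_model`: `features` (the training
#'   [feature_matrix()]), `scores`, `search` (the [cv_select_threshold()]
#'   result), `selected` (tibble of surviving features with scores),
#'   `predictor` ([fit_predictor()] result) and the call settings.
#' @export
train_risk_model <- function(expr, surv, collection = NULL,
                             mode = c("hybrid", "geneset_only", "single_gene_only"),
                             n_folds = 3, n_repeats = 100, grid_size = 20,
                             seed = NULL, weight = "n_members") {
  mode <- match.arg(mode)
  if (mode != "single_gene_only" && is.null(collection)) {
    abort(sprintf("mode '%s' needs a gene-set collection", mode))
  }
  surv <- align_samples(expr, surv)
  fm <- feature_matrix(expr,
                       collection = if (mode == "single_gene_only") NULL else collection,
                       include_single_genes = mode != "geneset_only")
  scores <- score_all(fm, surv)
  search <- cv_select_threshold(fm, surv, n_folds = n_folds,
                                n_repeats = n_repeats, grid_size = grid_size,
                                seed = seed, weight = weight)
  sel_ids <- select_features(scores, search$threshold)
  selected <- scores[match(sel_ids, scores$feature_id), ]
  predictor <- fit_predictor(subset_features(fm, sel_ids), surv, weight = weight)
  structure(list(features = fm, scores = scores, search = search,
                 selected = selected, predictor = predictor,
                 mode = mode, seed = seed,
                 surv = surv),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> mode = %s\n", x$mode))
  cat(sprintf("  %d candidate features, |score| threshold %.4g -> %d selected (%d gene sets, %d single genes)\n",
              nrow(x$scores), x$search$threshold, nrow(x$selected),
              sum(x$selected$kind == "gene_set"),
              sum(x$selected$kind == "single_gene")))
  invisible(x)
}

#' Predict risk scores for new samples
#'
#' @param object a [train_risk_model()] fit.
#' @param expr_test numeric matrix, genes x samples.
#' @param ... unused.
#' @return A tibble with columns `sample_id`, `risk`.
#' @export
predict.risk_model <- function(object, expr_test, ...) {
  predict_risk(object$predictor, expr_test)
}

#' Tidy the selected features of a risk model
#'
#' @param x a [train_risk_model()] fit.
#' @param ... unused.
#' @return A tibble with one row per selected feature: `feature_id`, `kind`,
#'   `name`, `n_members`, `score`, `abs_score`, `loading` (entry of the unit
#'   first-PC loading vector).
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  dplyr::left_join(
    x$selected,
    tibble::tibble(feature_id = names(x$predictor$w),
                   name = x$predictor$info$name,
                   loading = unname(x$predictor$w)),
    by = "feature_id")
}

#' One-row summary of a risk model
#'
#' @param x a [train_risk_model()] fit.
#' @param ... unused.
#' @return A one-row tibble: `mode`, `n_features`, `n_selected`,
#'   `n_gene_sets`, `n_single_genes`, `threshold`, `cv_performance` (mean
#'   held-out likelihood ratio at the chosen threshold), `train_cox_coef`.
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  g <- x$search$grid
  tibble::tibble(
    mode = x$mode,
    n_features = nrow(x$scores),
    n_selected = nrow(x$selected),
    n_gene_sets = sum(x$selected$kind == "gene_set"),
    n_single_genes = sum(x$selected$kind == "single_gene"),
    threshold = x$search$threshold,
    cv_performance = g$mean_performance[which(g$threshold == x$search$threshold)[1]],
    train_cox_coef = x$predictor$train_cox_coef)
}
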