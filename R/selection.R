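#' Select features whose score magnitude exceeds a threshold
#'
#' @param scores a `feature_scores` tibble from [score_all()].
#' @param threshold non-negative score threshold; features with
#'   `|score| > threshold` survive.
#' @return Character vector of feature identifiers, ordered by decreasing
#'   `|score|`.
#' @export
select_features <- function(scores, threshold) {
  if (!is.numeric(threshold) || threshold < 0) abort("threshold must be >= 0")
  keep <- scores[scores$abs_score > threshold, ]
  if (nrow(keep) == 0) abort("no feature exceeds the threshold")
  keep$feature_id[order(keep$abs_score, decreasing = TRUE)]
}

# Random event-stratified n-fold partition: events and censored samples are
# partitioned separately so every fold carries events. Returns an integer
# fold label per sample, or NULL if some fold has < min_events events.
make_event_stratified_folds <- function(event, n_folds, min_events = 2) {
  fold <- integer(length(event))
  for (grp in list(which(event == 1), which(event == 0))) {
    if (length(grp) == 0) next
    fold[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
  }
  tab <- tabulate(fold[event == 1], nbins = n_folds)
  if (any(tab < min_events)) return(NULL)
  fold
}

# Train the fold pipeline on `train_idx` columns only and evaluate each
# candidate threshold on the held-out columns. Standardization, set
# summarization, scoring and the PC fit are all re-estimated inside the fold.
# Returns per-threshold held-out Cox likelihood-ratio statistics (0 when the
# selection is empty or the held-out risk is degenerate). With
# `return_fit = TRUE` also returns the per-threshold fold predictors, which
# lets tests verify that held-out data never enters the fit.
eval_fold <- function(fm, surv, train_idx, test_idx, grid, weight = "n_members",
                      return_fit = FALSE) {
  expr_tr <- fm$expr[, train_idx, drop = FALSE]
  surv_tr <- surv[train_idx, ]
  fm_tr <- feature_matrix(expr_tr, fm$collection, fm$include_single_genes)
  sc <- score_all(fm_tr, surv_tr)
  expr_te <- fm$expr[, test_idx, drop = FALSE]
  surv_te <- surv[test_idx, ]
  perf <- numeric(length(grid))
  fits <- if (return_fit) vector("list", length(grid))
  for (k in seq_along(grid)) {
    ids <- sc$feature_id[sc$abs_score > grid[k]]
    if (length(ids) == 0) next
    ids <- ids[order(sc$abs_score[match(ids, sc$feature_id)], decreasing = TRUE)]
    p <- fit_predictor(subset_features(fm_tr, ids), surv_tr, weight = weight)
    if (return_fit) fits[[k]] <- p
    risk <- predict_risk(p, expr_te)$risk
    perf[k] <- tryCatch(likelihood_ratio(risk, surv_te), error = function(e) 0)
  }
  if (return_fit) list(perf = perf, fits = fits) else perf
}

#' Choose the feature-score threshold by repeated cross-validation
#'
#' Candidate thresholds are `grid_size` evenly spaced quantiles (50th to 99th
#' percentile) of the full-training `|score|` distribution. For each of
#' `n_repeats` repeats the training samples are randomly partitioned into
#' `n_folds` event-stratified folds; for every fold and threshold the whole
#' pipeline (standardization, summarization, scoring, selection, weighted-PC
#' fit) is re-estimated on the in-fold samples and the held-out third is
#' scored by the Cox likelihood-ratio statistic of its predicted risk.
#' Performance is averaged over folds and repeats; the threshold with the
#' best mean wins, ties going to the larger (more parsimonious) threshold.
#'
#' @param fm the training [feature_matrix()].
#' @param surv training `survival_data`, sample-aligned with `fm`.
#' @param n_folds number of CV folds (default 3).
#' @param n_repeats number of random re-partitions (default 100).
#' @param grid_size number of candidate thresholds (default 20).
#' @param seed integer seed making the fold draws reproducible.
#' @param weight predictor weighting passed through to [fit_predictor()].
#' @param retry_cap redraws allowed per repeat when a fold lacks events.
#' @return An object of class `threshold_search`: `grid` tibble
#'   (`threshold`, `mean_performance`), `performance` matrix
#'   (repeats x thresholds, fold-averaged), `threshold` (chosen), `seed`.
#' @export
cv_select_threshold <- function(fm, surv, n_folds = 3, n_repeats = 100,
                                grid_size = 20, seed = NULL,
                                weight = "n_members", retry_cap = 20) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != nrow(surv)) abort("feature matrix and survival data are not aligned")
  if (!is.null(seed)) withr::local_seed(seed)
  full_scores <- score_all(fm, surv)
  grid <- unname(quantile(full_scores$abs_score,
                          probs = seq(0.50, 0.99, length.out = grid_size),
                          type = 7))
  perf <- matrix(NA_real_, nrow = n_repeats, ncol = length(grid))
  for (r in seq_len(n_repeats)) {
    fold <- NULL
    for (try in seq_len(retry_cap)) {
      fold <- make_event_stratified_folds(surv$event, n_folds)
      if (!is.null(fold)) break
    }
    if (is.null(fold)) {
      abort(sprintf("could not draw %d folds with >= 2 events each (too few events)", n_folds))
    }
    fold_perf <- matrix(0, nrow = n_folds, ncol = length(grid))
    for (f in seq_len(n_folds)) {
      fold_perf[f, ] <- eval_fold(fm, surv,
                                  train_idx = which(fold != f),
                                  test_idx = which(fold == f),
                                  grid = grid, weight = weight)
    }
    perf[r, ] <- colMeans(fold_perf)
  }
  mean_perf <- colMeans(perf)
  if (all(mean_perf == 0)) {
    # no threshold ever produced a usable predictor in any fold
    if (all(perf == 0)) abort("grid too strict: no threshold selected any feature in any fold")
  }
  best <- which(mean_perf == max(mean_perf))
  chosen <- max(grid[best])
  structure(list(grid = tibble::tibble(threshold = grid,
                                       mean_performance = mean_perf),
                 performance = perf,
                 threshold = chosen,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search>: %d thresholds x %d repeats (x %d folds)\n",
              nrow(x$grid), x$n_repeats, x$n_folds))
  cat(sprintf("  chosen |score| threshold: %.4g (mean held-out LR %.4g)\n",
              x$threshold,
              x$grid$mean_performance[which.max(x$grid$threshold == x$threshold)]))
  invisible(x)
}
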