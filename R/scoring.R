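#' Cox score statistic of one feature against censored survival
#'
#' The standardized score-test statistic of the Cox partial likelihood at
#' beta = 0: `s = U(0) / sqrt(I(0))`, with `U(0)` the sum over event times of
#' the event sample's value minus the risk-set mean, and `I(0)` the sum over
#' event times of the risk-set variance, using the Breslow convention for
#' tied event times. Censored observations remain in the risk set at their
#' own time. Asymptotically standard normal when the feature is unrelated to
#' survival; its magnitude is the feature-screening score of the method.
#'
#' @param x numeric vector of per-sample feature values.
#' @param surv a `survival_data` tibble aligned with `x`.
#' @return The signed score statistic (a single number).
#' @export
cox_score <- function(x, surv) {
  if (length(x) != nrow(surv)) abort("x and surv lengths differ")
  s <- cox_score_matrix(matrix(x, nrow = 1), surv$time, surv$event)
  if (is.na(s)) abort("zero information: feature is constant within risk sets")
  as.numeric(s)
}

# Vectorized score statistic for a features x samples matrix.
# Returns NA for rows with (numerically) zero information.
cox_score_matrix <- function(X, time, event) {
  if (sum(event) < 1) abort("no events: Cox score undefined")
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  # n x K risk-set and tied-event indicators
  R <- outer(time, ut, `>=`) * 1
  E <- (event == 1) * (outer(time, ut, `==`) * 1)
  d <- colSums(E)
  nk <- colSums(R)
  XR <- X %*% R
  X2R <- (X * X) %*% R
  XE <- X %*% E
  mean_k <- sweep(XR, 2, nk, "/")
  U <- rowSums(XE - sweep(mean_k, 2, d, "*"))
  I <- rowSums(sweep(sweep(X2R, 2, nk, "/") - mean_k^2, 2, d, "*"))
  scale2 <- rowMeans(X * X) + 1e-300
  ifelse(I > 1e-12 * scale2 * sum(d), U / sqrt(I), NA_real_)
}

#' Score every feature of a feature matrix
#'
#' Applies [cox_score()] to each feature row. Features whose score is
#' undefined (constant within risk sets) are dropped with a message.
#'
#' @param fm a [feature_matrix()], sample-aligned with `surv`.
#' @param surv a `survival_data` tibble.
#' @param verbose message about skipped features?
#' @return A tibble of class `feature_scores` with columns `feature_id`,
#'   `kind`, `n_members`, `score`, `abs_score`.
#' @export
score_all <- function(fm, surv, verbose = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != nrow(surv)) abort("feature matrix and survival data are not aligned")
  s <- cox_score_matrix(fm$values, surv$time, surv$event)
  out <- tibble::tibble(feature_id = fm$info$feature_id,
                        kind = fm$info$kind,
                        n_members = fm$info$n_members,
                        score = as.numeric(s),
                        abs_score = abs(as.numeric(s)))
  bad <- is.na(out$score)
  if (any(bad) && verbose) {
    inform(sprintf("skipping %d feature(s) with undefined Cox score", sum(bad)))
  }
  out <- out[!bad, ]
  class(out) <- c("feature_scores", class(out))
  out
}

#' Rank-correlation of feature scores across two exclusive data splits
#'
#' Scores the common features independently in two disjoint sample splits and
#' returns the Spearman rank correlation of the absolute scores — the
#' stability measure behind the observation that gene-set features rank more
#' reproducibly than single-gene features. Absolute scores are correlated
#' because feature selection thresholds on magnitude.
#'
#' @param fm_a,fm_b trained [feature_matrix()] objects on the two splits.
#' @param surv_a,surv_b matching `survival_data`.
#' @param ids optional feature identifiers to restrict to; default: all
#'   features scored in both splits.
#' @param by_kind if `TRUE`, return one correlation per feature kind.
#' @return A tibble with columns `kind` (`"all"` unless `by_kind`),
#'   `spearman`, `n_features`.
#' @export
split_robustness <- function(fm_a, surv_a, fm_b, surv_b, ids = NULL,
                             by_kind = FALSE) {
  if (length(intersect(colnames(fm_a$values), colnames(fm_b$values))) > 0) {
    abort("splits share samples; they must be exclusive")
  }
  sa <- score_all(fm_a, surv_a)
  sb <- score_all(fm_b, surv_b)
  common <- dplyr::inner_join(
    dplyr::select(sa, "feature_id", "kind", a = "abs_score"),
    dplyr::select(sb, "feature_id", b = "abs_score"),
    by = "feature_id")
  if (!is.null(ids)) common <- common[common$feature_id %in% ids, ]
  groups <- if (by_kind) split(common, common$kind) else list(all = common)
  out <- purrr::imap_dfr(groups, function(g, nm) {
    if (nrow(g) < 3) abort("fewer than 3 common features; correlation is meaningless")
    tibble::tibble(kind = nm,
                   spearman = cor(g$a, g$b, method = "spearman"),
                   n_features = nrow(g))
  })
  out
}
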