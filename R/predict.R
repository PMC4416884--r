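#' Fit the membership-weighted principal-component predictor
#'
#' Each selected feature row is centered at its training mean and multiplied
#' by its member count `N_i` (single genes have `N_i = 1`), a generalized PCA
#' in which gene-set features summarized from more member genes carry more
#' weight; with all `N_i = 1` it reduces to conventional PCA. The first
#' right-singular direction of the weighted, centered features x samples
#' matrix gives the per-sample predictor scores and the unit loading vector.
#' The orientation sign is fixed so that higher score means higher risk: the
#' Cox coefficient of the returned training risk is non-negative.
#'
#' @param fm_selected a [feature_matrix()] restricted (via
#'   [subset_features()]) to the selected features.
#' @param surv training `survival_data`, sample-aligned.
#' @param weight `"n_members"` (the method's weighting) or `"sqrt_n_members"`,
#'   a variance-tempered variant not part of the original method.
#' @return An object of class `risk_predictor`: feature info, per-feature
#'   training centers, unit loading vector `w`, orientation `sign`, training
#'   Cox coefficient, and the standardization/summarization parameters needed
#'   to rebuild features on new samples.
#' @export
fit_predictor <- function(fm_selected, surv, weight = c("n_members", "sqrt_n_members")) {
  stopifnot(inherits(fm_selected, "feature_matrix"))
  weight <- match.arg(weight)
  X <- fm_selected$values
  if (nrow(X) < 1) abort("need at least one selected feature")
  if (ncol(X) < 2) abort("need at least 2 samples")
  centers <- rowMeans(X)
  w_i <- fm_selected$info$n_members
  if (weight == "sqrt_n_members") w_i <- sqrt(w_i)
  A <- (X - centers) * w_i
  if (all(abs(A) < 1e-300)) abort("all centered features are zero; no principal component")
  sv <- svd(A, nu = 1, nv = 1)
  w <- sv$u[, 1]
  scores <- as.numeric(sv$d[1] * sv$v[, 1])  # == t(w) %*% A
  cf <- train_cox_coef(scores, surv)
  s <- if (is.na(cf)) {
    sgn <- sign(cox_score_matrix(matrix(scores, nrow = 1), surv$time, surv$event))
    if (is.na(sgn) || sgn == 0) 1 else sgn
  } else if (cf < 0) -1 else 1
  structure(list(
    info = fm_selected$info,
    centers = setNames(as.numeric(centers), fm_selected$info$feature_id),
    weights = setNames(as.numeric(w_i), fm_selected$info$feature_id),
    weight_type = weight,
    w = setNames(as.numeric(w), fm_selected$info$feature_id),
    sign = as.numeric(s),
    train_cox_coef = if (is.na(cf)) NA_real_ else abs(cf),
    model = list(mu = fm_selected$model$mu, sigma = fm_selected$model$sigma),
    sets = fm_selected$sets,
    set_params = fm_selected$set_params,
    sg_genes = fm_selected$sg_genes %||%
      fm_selected$info$name[fm_selected$info$kind == "single_gene"],
    train_risk = setNames(as.numeric(s) * scores, colnames(X))),
    class = "risk_predictor")
}

# univariate CoxPH coefficient of risk on training survival (Breslow ties);
# NA when the fit fails.
train_cox_coef <- function(risk, surv) {
  tryCatch({
    fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ risk,
                           ties = "breslow")
    unname(fit$coefficients[1])
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
}

#' @export
print.risk_predictor <- function(x, ...) {
  cat(sprintf("<risk_predictor>: %d features (%d gene sets, %d single genes), weight = %s\n",
              nrow(x$info), sum(x$info$kind == "gene_set"),
              sum(x$info$kind == "single_gene"), x$weight_type))
  invisible(x)
}

#' Project new samples onto a fitted predictor
#'
#' Rebuilds the predictor's features for the test samples from the stored
#' training parameters (no re-estimation), centers them at the training
#' means, applies the membership weights, and projects onto the stored unit
#' loading: `risk_j = sign * w . (weighted centered feature column j)`.
#'
#' @param p a [fit_predictor()] result.
#' @param expr_test numeric matrix, genes x samples, containing every gene
#'   the selected features require (a missing gene is an error naming it).
#' @return A tibble with columns `sample_id`, `risk`; higher risk predicts
#'   shorter survival.
#' @export
predict_risk <- function(p, expr_test) {
  stopifnot(inherits(p, "risk_predictor"))
  vals <- rebuild_feature_values(
    list(model = p$model, sets = p$sets, set_params = p$set_params,
         sg_genes = p$sg_genes, include_single_genes = length(p$sg_genes) > 0),
    expr_test)
  vals <- vals[p$info$feature_id, , drop = FALSE]
  A <- (vals - p$centers) * p$weights
  risk <- p$sign * as.numeric(crossprod(p$w, A))
  tibble::tibble(sample_id = colnames(expr_test), risk = risk)
}

#' Serialize a predictor to JSON
#'
#' Everything needed to rebuild risk scores on new expression data (feature
#' identifiers and member counts, loading vector, orientation sign, training
#' centers, per-gene standardization parameters and per-set summarization
#' parameters) is written as a single JSON document, so training and
#' prediction can run as separate invocations.
#'
#' @param p a [fit_predictor()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictor <- function(p, path) {
  stopifnot(inherits(p, "risk_predictor"))
  doc <- list(
    format = "pathrisk_predictor",
    version = 1L,
    weight_type = p$weight_type,
    sign = p$sign,
    train_cox_coef = p$train_cox_coef,
    features = list(
      feature_id = p$info$feature_id,
      kind = p$info$kind,
      name = p$info$name,
      n_members = p$info$n_members,
      center = unname(p$centers),
      weight = unname(p$weights),
      loading = unname(p$w)),
    standardization = list(
      gene = names(p$model$mu),
      mu = unname(p$model$mu),
      sigma = unname(p$model$sigma)),
    sets = p$sets,
    set_params = if (!is.null(p$set_params)) as.list(p$set_params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized predictor
#'
#' @param path path to a JSON file written by [write_predictor()].
#' @return A `risk_predictor` object.
#' @export
read_predictor <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pathrisk_predictor")) {
    abort("not a pathrisk predictor file")
  }
  f <- doc$features
  info <- tibble::tibble(feature_id = f$feature_id, kind = f$kind,
                         name = f$name, n_members = as.integer(f$n_members))
  sets <- lapply(doc$sets, as.character)
  structure(list(
    info = info,
    centers = setNames(as.numeric(f$center), f$feature_id),
    weights = setNames(as.numeric(f$weight), f$feature_id),
    weight_type = doc$weight_type,
    w = setNames(as.numeric(f$loading), f$feature_id),
    sign = as.numeric(doc$sign),
    train_cox_coef = as.numeric(doc$train_cox_coef %||% NA_real_),
    model = list(mu = setNames(as.numeric(doc$standardization$mu),
                               doc$standardization$gene),
                 sigma = setNames(as.numeric(doc$standardization$sigma),
                                  doc$standardization$gene)),
    sets = sets,
    set_params = if (!is.null(doc$set_params) && length(doc$set_params))
      tibble::as_tibble(doc$set_params),
    sg_genes = info$name[info$kind == "single_gene"],
    train_risk = NULL),
    class = "risk_predictor")
}
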