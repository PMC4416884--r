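#' Fit per-gene standardization parameters on training samples
#'
#' Estimates each gene's mean and standard deviation (sample SD, n-1
#' denominator) from the supplied samples. Genes with zero variance cannot be
#' standardized and are excluded, with a warning naming how many were dropped.
#'
#' @param expr numeric matrix, genes x samples (training samples only).
#' @return An object of class `standardization_model` with fields `mu`,
#'   `sigma` (named numeric vectors over retained genes) and `dropped`
#'   (identifiers of constant genes).
#' @export
fit_standardization <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2) abort("need at least 2 samples to estimate standard deviations")
  mu <- rowMeans(expr)
  sigma <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1))
  constant <- sigma <= 0
  if (all(constant)) abort("all genes are constant; nothing can be standardized")
  if (any(constant)) {
    warn(sprintf("dropping %d constant gene(s) with zero variance", sum(constant)))
  }
  structure(list(mu = mu[!constant], sigma = sigma[!constant],
                 dropped = rownames(expr)[constant]),
            class = "standardization_model")
}

#' Apply a fitted standardization model
#'
#' Returns `(e - mu) / sigma` using the model's (training) parameters, for
#' the model's genes only. Applied to the training matrix every row has mean
#' 0 and SD 1; applied to test data the rows generally do not (no refitting).
#'
#' @param expr numeric matrix, genes x samples; must contain every model gene.
#' @param model a [fit_standardization()] result.
#' @return Standardized matrix over the model's genes.
#' @export
apply_standardization <- function(expr, model) {
  stopifnot(inherits(model, "standardization_model"))
  genes <- names(model$mu)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort(paste0("gene(s) in standardization model missing from expression: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..." else ""))
  }
  (expr[genes, , drop = FALSE] - model$mu) / model$sigma
}

#' Maxmean summary of one gene set in each sample
#'
#' For standardized member values e' of one set, the per-sample summary is
#' `absmax[mean((e')+), mean((e')-)]` where `(x)+ = max(x, 0)`,
#' `(x)- = min(x, 0)` and `absmax` returns whichever argument has the larger
#' absolute value (the first, i.e. the positive part, on a tie). The
#' denominator is the number of member genes present in the matrix.
#'
#' @param e_members numeric matrix (members x samples) or vector (one sample)
#'   of standardized member expression.
#' @return Numeric vector of per-sample maxmean values.
#' @export
maxmean <- function(e_members) {
  if (is.null(dim(e_members))) e_members <- matrix(e_members, ncol = 1)
  if (nrow(e_members) == 0) abort("empty member list")
  pos <- colMeans(pmax(e_members, 0))
  neg <- colMeans(pmin(e_members, 0))
  ifelse(abs(pos) >= abs(neg), pos, neg)
}

# maxmean for every set at once: M is a sparse membership indicator
# (sets x genes over eprime's rows), ng the per-set present-member counts.
maxmean_all <- function(eprime, M, ng) {
  pos <- as.matrix(M %*% pmax(eprime, 0)) / ng
  neg <- as.matrix(M %*% pmin(eprime, 0)) / ng
  ifelse(abs(pos) >= abs(neg), pos, neg)
}

#' Rescale a summarized gene-set vector to its members' scale
#'
#' The maxmean summary `u` is standardized across training samples and then
#' scaled so the resulting feature has the average mean and the average
#' variance of its member genes: `x = u' * sqrt(mean(sigma_i^2)) +
#' mean(mu_i)`. The standardization parameters of `u` (its training mean and
#' SD) are part of the returned recipe so the identical transform can be
#' replayed on test samples.
#'
#' @param u numeric vector of per-sample maxmean values (training samples).
#' @param member_mu,member_sigma numeric vectors of the member genes' training
#'   means and SDs.
#' @return A list with `x` (rescaled training values), `u_mean`, `u_sd`,
#'   `center` (= mean member mean) and `scale` (= sqrt of mean member
#'   variance), or `NULL` if `u` has zero variance (feature must be dropped).
#' @export
rescale_geneset <- function(u, member_mu, member_sigma) {
  u_mean <- mean(u)
  u_sd <- sd(u)
  if (!is.finite(u_sd) || u_sd <= 0) return(NULL)
  center <- mean(member_mu)
  scale <- sqrt(mean(member_sigma^2))
  list(x = (u - u_mean) / u_sd * scale + center,
       u_mean = u_mean, u_sd = u_sd, center = center, scale = scale)
}

#' Build the hybrid feature matrix
#'
#' Converts an expression matrix into prediction features: one row per
#' surviving gene set (maxmean summary of standardized members, rescaled to
#' the members' average mean and variance) and, when
#' `include_single_genes = TRUE`, one row per non-constant gene carrying its
#' raw expression as a pseudo gene set with a single member. Feature
#' identifiers are namespaced `GS:` / `SG:`.
#'
#' Set members absent from the expression matrix are intersected out (with an
#' informational message giving the count); sets left empty, and sets whose
#' summary is constant across training samples, are dropped. All training
#' parameters (per-gene standardization, per-set summary standardization and
#' rescaling targets) are stored so the identical features can be rebuilt on
#' new samples with [rebuild_features()].
#'
#' @param expr numeric matrix, genes x samples (training samples).
#' @param collection a [gene_set_collection()], or `NULL` for a single-gene
#'   only feature pool.
#' @param include_single_genes add every gene as a pseudo gene set of size 1?
#' @param verbose emit messages about dropped genes/sets?
#' @return An object of class `feature_matrix`: fields `values`
#'   (features x samples), `info` (tibble: `feature_id`, `kind`, `name`,
#'   `n_members`), `model`, `collection`, `set_params`, plus the training
#'   expression needed for cross-validated refits.
#' @export
feature_matrix <- function(expr, collection = NULL, include_single_genes = TRUE,
                           verbose = FALSE) {
  validate_expression(expr)
  if (is.null(collection) && !include_single_genes) {
    abort("no features requested: supply a collection and/or include single genes")
  }
  model <- withCallingHandlers(
    fit_standardization(expr),
    warning = function(w) if (!verbose) invokeRestart("muffleWarning")
  )
  genes <- names(model$mu)

  gs_values <- NULL
  set_params <- NULL
  kept_sets <- list()
  if (!is.null(collection)) {
    stopifnot(inherits(collection, "gene_set_collection"))
    eprime <- apply_standardization(expr, model)
    members <- lapply(collection$sets, intersect, y = genes)
    n_absent <- sum(lengths(collection$sets) - lengths(members))
    present <- lengths(members) > 0
    if (verbose && n_absent > 0) {
      inform(sprintf("%d set-member gene(s) absent from the expression matrix were intersected out", n_absent))
    }
    if (verbose && any(!present)) {
      inform(sprintf("dropping %d gene set(s) with no member present in the matrix", sum(!present)))
    }
    members <- members[present]
    if (length(members) > 0) {
      gidx <- match(unlist(members, use.names = FALSE), genes)
      M <- Matrix::sparseMatrix(
        i = rep.int(seq_along(members), lengths(members)),
        j = gidx, x = 1,
        dims = c(length(members), length(genes)))
      ng <- lengths(members)
      u <- maxmean_all(eprime, M, ng)
      u_mean <- rowMeans(u)
      u_sd <- apply(u, 1, sd)
      ok <- is.finite(u_sd) & u_sd > 0
      if (verbose && any(!ok)) {
        inform(sprintf("dropping %d gene set(s) with constant maxmean summary", sum(!ok)))
      }
      if (any(ok)) {
        members <- members[ok]
        mu_bar <- vapply(members, function(m) mean(model$mu[m]), numeric(1))
        var_bar <- vapply(members, function(m) mean(model$sigma[m]^2), numeric(1))
        u <- u[ok, , drop = FALSE]
        gs_values <- (u - u_mean[ok]) / u_sd[ok] * sqrt(var_bar) + mu_bar
        rownames(gs_values) <- paste0("GS:", names(members))
        set_params <- tibble::tibble(
          name = names(members),
          n_members = lengths(members),
          u_mean = unname(u_mean[ok]), u_sd = unname(u_sd[ok]),
          center = unname(mu_bar), scale = unname(sqrt(var_bar)))
        kept_sets <- members
      }
    }
  }

  sg_values <- NULL
  if (include_single_genes) {
    sg_values <- expr[genes, , drop = FALSE]
    rownames(sg_values) <- paste0("SG:", genes)
  }

  values <- rbind(gs_values, sg_values)
  if (is.null(values) || nrow(values) == 0) abort("no surviving features")
  info <- tibble::tibble(
    feature_id = rownames(values),
    kind = c(rep("gene_set", if (is.null(gs_values)) 0 else nrow(gs_values)),
             rep("single_gene", if (is.null(sg_values)) 0 else nrow(sg_values))),
    name = sub("^(GS|SG):", "", rownames(values)),
    n_members = c(if (is.null(set_params)) integer() else set_params$n_members,
                  rep(1L, if (is.null(sg_values)) 0 else nrow(sg_values))))

  structure(list(values = values, info = info, model = model,
                 sets = kept_sets, set_params = set_params,
                 include_single_genes = include_single_genes,
                 collection = collection, expr = expr),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix>: %d features (%d gene sets, %d single genes) x %d samples\n",
              nrow(x$values), sum(x$info$kind == "gene_set"),
              sum(x$info$kind == "single_gene"), ncol(x$values)))
  invisible(x)
}

#' Rebuild the features of a trained feature matrix on new samples
#'
#' Applies the stored training parameters (per-gene standardization, maxmean
#' summary standardization, rescaling targets) to a test expression matrix.
#' No parameter is re-estimated, so the predictor never references test data.
#'
#' @param fm a trained [feature_matrix()].
#' @param expr numeric matrix, genes x samples, containing every gene the
#'   trained features require.
#' @return Numeric matrix, features x samples, with the same feature rows as
#'   `fm$values`.
#' @export
rebuild_features <- function(fm, expr) {
  stopifnot(inherits(fm, "feature_matrix"))
  validate_expression(expr)
  out <- rebuild_feature_values(
    list(model = fm$model, sets = fm$sets, set_params = fm$set_params,
         include_single_genes = fm$include_single_genes,
         sg_genes = fm$sg_genes),
    expr)
  out[fm$info$feature_id, , drop = FALSE]
}

# shared by rebuild_features() and predict_risk(); `spec` carries model,
# sets, set_params, include_single_genes (and optionally sg_genes to restrict
# the single-gene rows).
rebuild_feature_values <- function(spec, expr) {
  genes_needed <- unique(c(unlist(spec$sets, use.names = FALSE),
                           spec$sg_genes %||%
                             (if (isTRUE(spec$include_single_genes)) names(spec$model$mu) else character())))
  missing <- setdiff(genes_needed, rownames(expr))
  if (length(missing)) {
    abort(paste0("required gene(s) missing from expression: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..." else ""))
  }
  gs_values <- NULL
  if (length(spec$sets) > 0) {
    sub_model <- structure(
      list(mu = spec$model$mu, sigma = spec$model$sigma, dropped = character()),
      class = "standardization_model")
    need <- unique(unlist(spec$sets, use.names = FALSE))
    sub_model$mu <- sub_model$mu[need]
    sub_model$sigma <- sub_model$sigma[need]
    eprime <- apply_standardization(expr, sub_model)
    gidx <- match(unlist(spec$sets, use.names = FALSE), need)
    M <- Matrix::sparseMatrix(
      i = rep.int(seq_along(spec$sets), lengths(spec$sets)),
      j = gidx, x = 1, dims = c(length(spec$sets), length(need)))
    u <- maxmean_all(eprime, M, lengths(spec$sets))
    p <- spec$set_params
    gs_values <- (u - p$u_mean) / p$u_sd * p$scale + p$center
    rownames(gs_values) <- paste0("GS:", p$name)
  }
  sg_values <- NULL
  sg <- spec$sg_genes %||%
    (if (isTRUE(spec$include_single_genes)) names(spec$model$mu) else character())
  if (length(sg) > 0) {
    sg_values <- expr[sg, , drop = FALSE]
    rownames(sg_values) <- paste0("SG:", sg)
  }
  out <- rbind(gs_values, sg_values)
  colnames(out) <- colnames(expr)
  out
}

#' Restrict a feature matrix to a subset of features
#'
#' @param fm a [feature_matrix()].
#' @param feature_ids feature identifiers to keep (order preserved).
#' @return A `feature_matrix` over the selected features only.
#' @export
subset_features <- function(fm, feature_ids) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(feature_ids, fm$info$feature_id)
  if (length(missing)) {
    abort(paste0("unknown feature id(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  keep <- match(feature_ids, fm$info$feature_id)
  out <- fm
  out$values <- fm$values[keep, , drop = FALSE]
  out$info <- fm$info[keep, ]
  gs_names <- out$info$name[out$info$kind == "gene_set"]
  out$sets <- fm$sets[gs_names]
  out$set_params <- if (!is.null(fm$set_params)) {
    fm$set_params[match(gs_names, fm$set_params$name), ]
  }
  out$sg_genes <- out$info$name[out$info$kind == "single_gene"]
  out
}
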