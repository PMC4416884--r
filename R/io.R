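#' Read a gene expression matrix from a tab-delimited file
#'
#' Expects a header row of sample identifiers; the first column holds gene
#' identifiers and the remaining columns numeric expression indices (assumed
#' already log-scale/normalized upstream). Missing or non-numeric cells are an
#' error, reported with their row and column coordinates.
#'
#' @param path path to a TSV file, genes in rows, samples in columns.
#' @return A numeric matrix, genes x samples, with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) abort("expression table needs a gene-id column and at least 2 samples")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf("non-numeric or missing expression value at gene row %d ('%s'), sample column '%s'",
                  b[1], genes[b[1]], colnames(vals)[b[2]]))
  }
  rownames(num) <- genes
  validate_expression(num)
}

#' @keywords internal
#' @noRd
validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) abort("expression must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0("duplicate gene identifier(s): ",
                 paste(head(unique(rownames(values)[duplicated(rownames(values))]), 5),
                       collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste0("duplicate sample identifier(s): ",
                 paste(head(unique(colnames(values)[duplicated(colnames(values))]), 5),
                       collapse = ", ")))
  }
  if (anyNA(values)) abort("expression matrix contains missing values")
  if (nrow(values) < 1 || ncol(values) < 2) abort("need at least 1 gene and 2 samples")
  values
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read censored survival outcomes
#'
#' Expects a tab-delimited file with columns `sample_id`, `time`, `event`
#' (1 = event observed, 0 = right-censored). Every time must be positive and
#' at least one event must be observed.
#'
#' @param path path to a TSV file.
#' @return A tibble with columns `sample_id`, `time`, `event`
#'   (class `survival_data`).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("survival table missing column(s): ", paste(miss, collapse = ", ")))
  survival_data(as.character(df$sample_id), df$time, df$event)
}

#' Construct and validate survival data
#'
#' @param sample_id character sample identifiers (unique).
#' @param time positive follow-up times.
#' @param event event indicators, 1 = event observed, 0 = censored.
#' @return A tibble of class `survival_data`.
#' @export
survival_data <- function(sample_id, time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(sample_id)) abort("duplicate sample_id in survival data")
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    abort(sprintf("survival time must be positive and finite: row %d (sample '%s') has time %s",
                  bad_t[1], sample_id[bad_t[1]], format(time[bad_t[1]])))
  }
  bad_e <- which(!(event %in% c(0, 1)))
  if (length(bad_e)) {
    abort(sprintf("event indicator must be 0 or 1: row %d (sample '%s') has event %s",
                  bad_e[1], sample_id[bad_e[1]], format(event[bad_e[1]])))
  }
  if (sum(event) < 1) abort("survival data must contain at least one observed event")
  out <- tibble::tibble(sample_id = as.character(sample_id), time = time, event = event)
  class(out) <- c("survival_data", class(out))
  out
}

#' Write survival data as TSV
#'
#' @param surv a `survival_data` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  readr::write_tsv(tibble::as_tibble(surv)[, c("sample_id", "time", "event")], path)
  invisible(path)
}

#' Write per-sample risk scores as TSV
#'
#' @param path output path.
#' @param sample_ids character sample identifiers.
#' @param risks numeric risk scores, one per sample.
#' @return `path`, invisibly.
#' @export
write_risk_scores <- function(path, sample_ids, risks) {
  if (length(sample_ids) != length(risks)) abort("sample_ids and risks lengths differ")
  readr::write_tsv(tibble::tibble(sample_id = as.character(sample_ids),
                                  risk = as.numeric(risks)), path)
  invisible(path)
}

#' Read per-sample risk scores
#'
#' @param path path to a TSV with columns `sample_id`, `risk`.
#' @return A tibble with columns `sample_id`, `risk`.
#' @export
read_risk_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  miss <- setdiff(c("sample_id", "risk"), names(df))
  if (length(miss)) abort(paste0("risk table missing column(s): ", paste(miss, collapse = ", ")))
  tibble::tibble(sample_id = as.character(df$sample_id), risk = as.numeric(df$risk))
}

#' Align an expression matrix with survival data
#'
#' The two inputs must describe exactly the same samples; any mismatch is an
#' error (a silent join could misalign Cox scores undetectably). On success
#' the survival rows are reordered to the expression column order.
#'
#' @param expr numeric expression matrix, genes x samples.
#' @param surv a `survival_data` tibble.
#' @return The reordered `survival_data`.
#' @export
align_samples <- function(expr, surv) {
  e_ids <- colnames(expr)
  s_ids <- surv$sample_id
  only_e <- setdiff(e_ids, s_ids)
  only_s <- setdiff(s_ids, e_ids)
  if (length(only_e) || length(only_s)) {
    abort(paste0(
      "expression and survival sample sets differ; ",
      if (length(only_e)) paste0("only in expression: ",
                                 paste(head(only_e, 5), collapse = ", "),
                                 if (length(only_e) > 5) " ..." else "", "; ") else "",
      if (length(only_s)) paste0("only in survival: ",
                                 paste(head(only_s, 5), collapse = ", "),
                                 if (length(only_s) > 5) " ..." else "") else ""))
  }
  surv[match(e_ids, s_ids), ]
}
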