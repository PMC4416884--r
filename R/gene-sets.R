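#' Gene-set collections
#'
#' A `gene_set_collection` is a named list of character vectors (member gene
#' identifiers) plus a collection name and optional per-set provenance labels.
#' It is the in-memory form of a GMT file.
#'
#' @param sets named list of character vectors; one element per gene set.
#' @param name collection name (used to disambiguate set-name collisions when
#'   collections are merged).
#' @param provenance optional character vector, one label per set (recycled
#'   from the GMT description column).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection", provenance = NULL) {
  if (!is.list(sets) || length(sets) == 0) {
    abort("`sets` must be a non-empty named list of character vectors.")
  }
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0L)) {
    abort("every gene set must be non-empty")
  }
  if (is.null(provenance)) provenance <- rep("", length(sets))
  provenance <- rep_len(as.character(provenance), length(sets))
  names(provenance) <- nm
  structure(list(name = name, sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("<gene_set_collection '%s'>: %d sets, member counts %d-%d (median %g)\n",
              x$name, length(x$sets), min(sz), max(sz), median(sz)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Parses the MSigDB-dialect GMT format: one set per line, tab-separated
#' fields `name`, `description`, then member gene identifiers. Duplicate
#' members within a line are deduplicated; the description is kept as the
#' set's provenance label.
#'
#' @param path path to a GMT file.
#' @param name collection name; defaults to the file name without extension.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("no gene sets: GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  prov <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(f) < 3 || length(members) == 0) {
      abort(sprintf("malformed GMT line %d: need name, description and at least one member", i))
    }
    nms[i] <- f[1]
    prov[i] <- f[2]
    sets[[i]] <- unique(members)
  }
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate set name(s) in GMT: ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  names(sets) <- nms
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set_collection(sets, name = name, provenance = prov)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i],
            collection$provenance[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge gene-set collections into an integrated super collection
#'
#' Takes the union of all sets across collections. Two entries with the same
#' set name and identical membership are merged into one; entries that share
#' a name but differ in membership are kept separately under names prefixed
#' with their source collection (`<collection>.<set>`).
#'
#' @param collections a list of [gene_set_collection()] objects.
#' @param name name for the merged collection (default `"IS"`).
#' @return A [gene_set_collection()] whose provenance records each set's
#'   source collection.
#' @export
build_super_collection <- function(collections, name = "IS") {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  if (length(collections) == 0) abort("need at least one collection")
  ok <- vapply(collections, inherits, logical(1), "gene_set_collection")
  if (!all(ok)) abort("all elements must be gene_set_collection objects")

  entries <- purrr::map_dfr(collections, function(cl) {
    tibble::tibble(source = cl$name,
                   set = names(cl$sets),
                   members = unname(cl$sets))
  })
  out_sets <- list()
  out_prov <- character()
  for (nm in unique(entries$set)) {
    grp <- entries[entries$set == nm, ]
    # merge occurrences with identical membership, keep distinct ones apart
    keep <- rep(TRUE, nrow(grp))
    for (i in seq_len(nrow(grp))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(grp))) {
        if (j <= i || !keep[j]) next
        if (setequal(grp$members[[i]], grp$members[[j]])) keep[j] <- FALSE
      }
    }
    grp <- grp[keep, ]
    if (nrow(grp) == 1) {
      out_sets[[nm]] <- grp$members[[1]]
      out_prov[nm] <- grp$source[1]
    } else {
      for (i in seq_len(nrow(grp))) {
        pn <- paste0(grp$source[i], ".", nm)
        out_sets[[pn]] <- grp$members[[i]]
        out_prov[pn] <- grp$source[i]
      }
    }
  }
  gene_set_collection(out_sets, name = name, provenance = out_prov)
}
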