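# Containers and file readers/writers for expression matrices, gene-set
# collections and phenotype labels.
#
# Conventions: expression values are kept in the canonical samples x genes
# orientation; labels are integer 0 (normal) / 1 (disease); gene matching is
# exact, case-sensitive string equality.

#' Construct an expression dataset
#'
#' Bundles a samples \eqn{\times} genes matrix of (already normalized)
#' expression values with sample identifiers, gene identifiers, and optional
#' binary phenotype labels.  The package performs no normalization itself:
#' values are used as supplied.
#'
#' @param values Numeric matrix, n samples \eqn{\times} p genes.
#' @param gene_ids Character vector of p unique gene identifiers.
#' @param sample_ids Character vector of n unique sample identifiers.
#' @param labels Optional integer vector of n labels, 1 = disease, 0 = normal.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_ids, sample_ids, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (length(gene_ids) != ncol(values)) {
    stop(sprintf("gene_ids length (%d) does not match gene columns (%d)",
                 length(gene_ids), ncol(values)))
  }
  if (length(sample_ids) != nrow(values)) {
    stop(sprintf("sample_ids length (%d) does not match sample rows (%d)",
                 length(sample_ids), nrow(values)))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ID(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  out <- structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         sample_ids = as.character(sample_ids),
         labels = NULL),
    class = "expression_dataset")
  if (!is.null(labels)) out <- attach_labels(out, labels, warn_positional = FALSE)
  out
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes; labels %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "unset"
              else sprintf("attached (%d disease / %d normal)",
                           sum(x$labels == 1), sum(x$labels == 0))))
  invisible(x)
}

#' Attach binary phenotype labels to a dataset
#'
#' Named label vectors are matched to samples by name; bare vectors attach
#' positionally (with a warning, since positional attachment silently trusts
#' file order).
#'
#' @param dataset An `expression_dataset`.
#' @param labels Integer vector of 0/1 labels, optionally named by sample ID.
#' @param warn_positional Warn when attaching an unnamed vector by position.
#' @return The dataset with `labels` set.
#' @export
attach_labels <- function(dataset, labels, warn_positional = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!all(labels %in% c(0, 1))) stop("labels must contain only 0 and 1")
  if (!is.null(names(labels))) {
    idx <- match(dataset$sample_ids, names(labels))
    if (anyNA(idx)) {
      stop("no label for sample(s): ",
           paste(dataset$sample_ids[is.na(idx)], collapse = ", "))
    }
    labels <- unname(labels[idx])
  } else {
    if (length(labels) != nrow(dataset$values)) {
      stop(sprintf("label length (%d) does not match sample count (%d)",
                   length(labels), nrow(dataset$values)))
    }
    if (warn_positional) {
      warning("attaching unnamed labels positionally; ensure the label file ",
              "lists samples in the same order as the expression matrix")
    }
  }
  dataset$labels <- as.integer(labels)
  dataset
}

#' Read a tab-delimited expression matrix
#'
#' Expects one header row of identifiers and one leading identifier column.
#' The file orientation must be stated explicitly; no auto-detection is
#' attempted, because a silently transposed matrix corrupts every downstream
#' statistic.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes_in_rows"` (one row per gene) or
#'   `"samples_in_rows"`.
#' @return An `expression_dataset` (labels unset) in samples x genes layout.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows",
                                                "samples_in_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) == 1L]
  if (length(lines) < 2L) stop("expression file needs a header and >=1 data row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L] + 1L
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad, widths[bad - 1L], widths[1L]))
  }
  ncol_body <- widths[1L]
  # header either matches the body width (corner label present) or is one
  # field short (no corner label)
  if (length(header) == ncol_body) {
    col_ids <- header[-1L]
  } else if (length(header) == ncol_body - 1L) {
    col_ids <- header
  } else {
    stop(sprintf("header has %d fields but data rows have %d",
                 length(header), ncol_body))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- lapply(body, function(f) f[-1L])
  values <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(body), byrow = TRUE))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at data row %d (id '%s'), column %d (id '%s')",
                 bad[1L], row_ids[bad[1L]], bad[2L], col_ids[bad[2L]]))
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicated row ID(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicated column ID(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  if (orientation == "genes_in_rows") {
    expression_dataset(t(values), gene_ids = row_ids, sample_ids = col_ids)
  } else {
    expression_dataset(values, gene_ids = col_ids, sample_ids = row_ids)
  }
}

#' Write an expression dataset to TSV
#'
#' Values are written with full double precision so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param dataset An `expression_dataset`.
#' @param path Output path.
#' @param orientation Layout of the written file.
#' @export
write_expression_tsv <- function(dataset, path,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (orientation == "genes_in_rows") {
    m <- t(dataset$values)
    row_ids <- dataset$gene_ids
    col_ids <- dataset$sample_ids
  } else {
    m <- dataset$values
    row_ids <- dataset$sample_ids
    col_ids <- dataset$gene_ids
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", col_ids), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(row_ids[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param entries List of lists, each with `pathway_id`, `pathway_name`,
#'   and `gene_ids`.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(entries) {
  ids <- vapply(entries, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stop("duplicated pathway ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sizes <- vapply(entries, function(e) length(e$gene_ids), integer(1))
  if (any(sizes < 1L)) {
    stop("pathway with no genes: ", paste(ids[sizes < 1L], collapse = ", "))
  }
  structure(list(entries = entries), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x$entries, function(e) length(e$gene_ids), integer(1))
  cat(sprintf("pathway_collection: %d gene sets (sizes %d-%d)\n",
              length(x$entries), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$entries)

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one gene set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Genes repeated within a
#' line are kept once, preserving first occurrence.
#'
#' @param path Path to a GMT file.
#' @return A `pathway_collection` in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty GMT file")
  entries <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need at least 3 (name, description, >=1 gene)",
                   i, length(f)))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    list(pathway_id = f[1L], pathway_name = f[2L],
         gene_ids = genes[!duplicated(genes)])
  })
  pathway_collection(entries)
}

#' Write a pathway collection to GMT
#' @param collection A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$entries, function(e) {
    paste(c(e$pathway_id, e$pathway_name, e$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CLS phenotype file
#'
#' Standard three-line GSEA CLS dialect with exactly two classes.  The
#' first-listed class maps to 0, the second to 1.  The label line may use
#' class names or the indices 0/1.  Bare CLS files carry no sample names, so
#' the returned vector is unnamed and attaches positionally.
#'
#' @param path Path to a CLS file.
#' @return Unnamed integer vector of 0/1 labels.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) != 3L) stop("CLS file must have exactly 3 non-empty lines")
  hdr <- as.integer(strsplit(lines[1L], "[ \t]+")[[1L]])
  if (length(hdr) != 3L || anyNA(hdr)) stop("malformed CLS header line")
  n <- hdr[1L]
  if (hdr[2L] != 2L) {
    stop(sprintf("CLS file declares %d classes; exactly 2 are required", hdr[2L]))
  }
  cls_line <- strsplit(sub("^#[ \t]*", "", lines[2L]), "[ \t]+")[[1L]]
  if (length(cls_line) != 2L) {
    stop(sprintf("CLS class-name line lists %d classes; exactly 2 are required",
                 length(cls_line)))
  }
  toks <- strsplit(lines[3L], "[ \t]+")[[1L]]
  if (length(toks) != n) {
    stop(sprintf("CLS label line has %d entries but header declares %d",
                 length(toks), n))
  }
  if (all(toks %in% cls_line)) {
    labels <- as.integer(toks == cls_line[2L])
  } else if (all(toks %in% c("0", "1"))) {
    labels <- as.integer(toks)
  } else {
    bad <- setdiff(toks, c(cls_line, "0", "1"))
    stop("CLS labels not among declared classes: ",
         paste(unique(bad), collapse = ", "))
  }
  labels
}

#' Write 0/1 labels as a CLS file
#' @param labels Integer 0/1 vector.
#' @param path Output path.
#' @param class_names Names for classes 0 and 1, in that order.
#' @export
write_cls <- function(labels, path, class_names = c("normal", "disease")) {
  if (!all(labels %in% c(0, 1))) stop("labels must contain only 0 and 1")
  writeLines(c(
    sprintf("%d 2 1", length(labels)),
    paste("#", class_names[1L], class_names[2L]),
    paste(class_names[labels + 1L], collapse = " ")
  ), path)
  invisible(path)
}

#' Read a two-column sample/label TSV
#'
#' Alternative to bare CLS: `sample_id<TAB>label` per line (label 0 or 1),
#' attaching by sample name rather than position.
#'
#' @param path Path to the file.
#' @return Named integer vector of labels.
#' @export
read_labels_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("label file must have exactly two tab-separated columns per line")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  lab <- vapply(fields, `[[`, character(1), 2L)
  # tolerate a header line
  if (suppressWarnings(is.na(as.integer(lab[1L])))) {
    ids <- ids[-1L]; lab <- lab[-1L]
  }
  labels <- as.integer(lab)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  names(labels) <- ids
  labels
}

#' Extract the expression submatrix for one pathway
#'
#' Columns are the pathway's genes found in the dataset, kept in pathway
#' order.  Genes absent from the dataset are dropped and counted in
#' `n_missing`.  A pathway with no genes in the dataset signals a classed
#' error (`pathweight_empty_pathway`) the caller is expected to catch and
#' log, rather than returning a degenerate matrix.
#'
#' @param dataset An `expression_dataset` with labels attached.
#' @param entry One element of a `pathway_collection`'s `entries`.
#' @return A `pathway_matrix`: list with `values` (n x m), `gene_ids`,
#'   `labels`, `n_missing`, `pathway_id`.
#' @export
extract_pathway_matrix <- function(dataset, entry) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$labels)) stop("dataset has no labels attached")
  idx <- match(entry$gene_ids, dataset$gene_ids)
  found <- !is.na(idx)
  if (!any(found)) {
    stop(errorCondition(
      sprintf("pathway '%s': none of its %d gene(s) are in the dataset",
              entry$pathway_id, length(entry$gene_ids)),
      class = c("pathweight_empty_pathway", "pathweight_error")))
  }
  structure(
    list(values = dataset$values[, idx[found], drop = FALSE],
         gene_ids = entry$gene_ids[found],
         labels = dataset$labels,
         n_missing = sum(!found),
         pathway_id = entry$pathway_id),
    class = "pathway_matrix")
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("pathway_matrix '%s': %d samples x %d genes (%d pathway gene(s) missing from dataset)\n",
              x$pathway_id, nrow(x$values), ncol(x$values), x$n_missing))
  invisible(x)
}
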