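# Synthetic pathway-data generator.
#
# Simulated pathway expression is multivariate normal with a specified mean
# vector and covariance matrix, so a simulated pathway retains the mean and
# the full correlation structure of whatever real pathway the model was
# estimated from.  Group labels split the samples into a normal and a
# disease half; an optional mean shift on the disease half plants
# differential expression with known ground truth.

#' Construct a pathway simulation model
#'
#' @param mean Length-m mean expression vector.
#' @param covariance m x m symmetric positive semi-definite covariance.
#' @param shift Length-m vector added to the disease-group mean (default 0,
#'   i.e. a null pathway with identically distributed groups).
#' @param gene_ids Optional gene identifiers (default `gene_1..gene_m`).
#' @return A `pathway_model`.
#' @export
pathway_model <- function(mean, covariance, shift = 0, gene_ids = NULL) {
  m <- length(mean)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == m)) stop("covariance must be m x m")
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance)))) {
    stop("covariance must be symmetric")
  }
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop("covariance must be positive semi-definite")
  }
  shift <- rep_len(shift, m)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(m))
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 shift = as.numeric(shift), gene_ids = as.character(gene_ids)),
            class = "pathway_model")
}

#' Estimate a simulation model from observed pathway data
#'
#' Sample mean vector and sample covariance (denominator n - 1) of the
#' matrix.  Tiny negative eigenvalues arising from numerical error are
#' clipped to zero (with a message) so the result is always a usable
#' simulation model; the shift is set to zero.
#'
#' @param X Numeric n x m matrix with n >= 2.
#' @return A `pathway_model` with `shift = 0`.
#' @export
estimate_moments <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need n >= 2 samples to estimate a covariance")
  S <- stats::cov(X)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 0) {
    message(sprintf("clipping %d negative eigenvalue(s) (most negative %.3g) to zero",
                    sum(e$values < 0), min(e$values)))
    e$values[e$values < 0] <- 0
    S <- e$vectors %*% (e$values * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  pathway_model(colMeans(X), S, shift = 0, gene_ids = colnames(X))
}

#' Simulate expression for one pathway
#'
#' Draws `n_samples` multivariate-normal samples from the model: the first
#' half (labels 0, normal) from `MVN(mean, covariance)` and the second half
#' (labels 1, disease) from `MVN(mean + shift, covariance)`.  Even sample
#' sizes give exactly balanced groups; odd sizes differ by one with a
#' warning.
#'
#' @param model A `pathway_model`.
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed, or `NULL`.
#' @return A `pathway_matrix` with simulated `values` and balanced `labels`.
#' @export
simulate_pathway <- function(model, n_samples, seed = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  if (n_samples < 2L) stop("n_samples must be >= 2")
  n0 <- ceiling(n_samples / 2)
  n1 <- n_samples - n0
  if (n0 != n1) {
    warning(sprintf("odd n_samples: groups of %d (normal) and %d (disease)", n0, n1))
  }
  vals <- with_seed(seed, {
    rbind(
      MASS::mvrnorm(n0, mu = model$mean, Sigma = model$covariance),
      MASS::mvrnorm(n1, mu = model$mean + model$shift, Sigma = model$covariance))
  })
  colnames(vals) <- model$gene_ids
  structure(
    list(values = vals,
         gene_ids = model$gene_ids,
         labels = c(rep(0L, n0), rep(1L, n1)),
         n_missing = 0L,
         pathway_id = "simulated"),
    class = "pathway_matrix")
}

#' Generate a full synthetic pathway study
#'
#' Builds a gene universe with i.i.d. standard-normal background expression,
#' a collection of random gene sets (sampled without replacement within a
#' pathway, free to overlap across pathways, as in real collections), and
#' balanced two-group labels.  For each designated informative pathway, half
#' of its member genes (rounded up) receive a mean shift of `shift_size` in
#' the disease group, planting differential expression with known ground
#' truth.
#'
#' Genes shared between an informative and another pathway carry their shift
#' wherever they appear, again mirroring real overlapping collections.
#'
#' @param n_genes Size of the gene universe.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Length-2 integer range of set sizes.
#' @param n_samples Total samples; first half normal, second half disease.
#' @param n_informative_pathways How many pathways carry planted signal.
#' @param shift_size Disease-group mean shift for planted genes, in units of
#'   the unit background standard deviation.
#' @param seed Integer seed, or `NULL`.
#' @return List with `dataset` (an `expression_dataset` with labels),
#'   `pathways` (a `pathway_collection`), and `truth` (a data.frame with one
#'   row per informative pathway: `pathway_id`, `n_genes`,
#'   `n_shifted_genes`, `shifted_gene_ids` comma-separated, `shift_size`).
#' @export
make_synthetic_study <- function(n_genes = 500L, n_pathways = 20L,
                                 pathway_size_range = c(10L, 26L),
                                 n_samples = 50L,
                                 n_informative_pathways = 3L,
                                 shift_size = 2,
                                 seed = NULL) {
  if (n_genes < max(pathway_size_range)) {
    stop("largest pathway size exceeds the gene universe")
  }
  if (n_informative_pathways > n_pathways) {
    stop("more informative pathways than pathways")
  }
  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    n0 <- ceiling(n_samples / 2)
    labels <- c(rep(0L, n0), rep(1L, n_samples - n0))
    values <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
    sizes <- sample(seq(pathway_size_range[1L], pathway_size_range[2L]),
                    n_pathways, replace = TRUE)
    entries <- lapply(seq_len(n_pathways), function(i) {
      list(pathway_id = sprintf("PW%03d", i),
           pathway_name = sprintf("synthetic pathway %d", i),
           gene_ids = sample(gene_ids, sizes[i]))
    })
    informative <- sort(sample(n_pathways, n_informative_pathways))
    truth <- lapply(informative, function(i) {
      members <- entries[[i]]$gene_ids
      shifted <- members[seq_len(ceiling(length(members) / 2))]
      data.frame(pathway_id = entries[[i]]$pathway_id,
                 n_genes = length(members),
                 n_shifted_genes = length(shifted),
                 shifted_gene_ids = paste(shifted, collapse = ","),
                 shift_size = shift_size,
                 stringsAsFactors = FALSE)
    })
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pathway_id = character(), n_genes = integer(),
                 n_shifted_genes = integer(), shifted_gene_ids = character(),
                 shift_size = numeric(), stringsAsFactors = FALSE)
    shifted_genes <- unique(unlist(lapply(truth$shifted_gene_ids, function(s) {
      strsplit(s, ",", fixed = TRUE)[[1L]]
    })))
    if (length(shifted_genes)) {
      cols <- match(shifted_genes, gene_ids)
      values[labels == 1L, cols] <- values[labels == 1L, cols] + shift_size
    }
    dataset <- expression_dataset(values, gene_ids, sample_ids, labels = labels)
    list(dataset = dataset,
         pathways = pathway_collection(entries),
         truth = truth)
  })
}

#' Write a synthetic study as the TSV/GMT/CLS file trio
#'
#' Emits `expression.tsv` (genes in rows), `pathways.gmt`, `labels.cls`, and
#' `truth.tsv` under `dir`, so downstream commands can be exercised
#' file-to-file.
#'
#' @param study Result of [make_synthetic_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    labels = file.path(dir, "labels.cls"),
    truth = file.path(dir, "truth.tsv"))
  write_expression_tsv(study$dataset, paths[["expression"]],
                       orientation = "genes_in_rows")
  write_gmt(study$pathways, paths[["pathways"]])
  write_cls(study$dataset$labels, paths[["labels"]])
  utils::write.table(study$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
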