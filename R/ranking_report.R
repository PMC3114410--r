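# Screening a pathway collection under a (weighting scheme x method)
# combination, and the reporting machinery built on the resulting scores:
# competition ranking with ties, tie-aware top-k selection, significance
# counts, rank-change tables, overlap detection, and the
# iteration-convergence sweep for the random-search schemes.

SCHEMES <- c("uniform", "absT", "Qdiff", "RWV", "RWM")
METHODS <- c("global_test", "random_forest")

#' Screening parameters
#'
#' Bundles every knob a screen needs; the full set is echoed into reports so
#' any output can be reproduced exactly.
#'
#' @param n_perm Permutations per global-test p-value.
#' @param count Random-search iterations for RWV/RWM.
#' @param range_lo,range_hi Random-weight range.
#' @param n_trees Trees per forest.
#' @param k Top-k size for selection reports.
#' @param include_ties Expand top-k through tied ranks.
#' @param alpha Significance threshold for p-value counts.
#' @param seed Base seed; each pathway derives its own sub-seed from it.
#' @param simple_draw Use the one-step candidate draw in searches.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(n_perm = 10000L, count = 25000L,
                          range_lo = 0.1, range_hi = 1.0,
                          n_trees = 1000L, k = 20L, include_ties = FALSE,
                          alpha = 0.05, seed = NULL, simple_draw = FALSE) {
  structure(list(n_perm = as.integer(n_perm), count = as.integer(count),
                 range_lo = range_lo, range_hi = range_hi,
                 n_trees = as.integer(n_trees), k = as.integer(k),
                 include_ties = include_ties, alpha = alpha, seed = seed,
                 simple_draw = simple_draw),
            class = "screen_params")
}

#' Competition ranks ("1224" style) for ascending-better scores
#'
#' Rank of an item is 1 plus the number of strictly smaller scores, so tied
#' items share the smallest applicable rank and the next rank skips the tie
#' block (e.g. scores `c(.26,.29,.29,.31,.31,.31,.34)` rank
#' `1,2,2,4,4,4,7`).
#'
#' @param scores Numeric vector, smaller = better; must be finite.
#' @return Integer ranks.
#' @export
rank_with_ties <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  as.integer(rank(scores, ties.method = "min"))
}

#' Screen every pathway under one scheme and method
#'
#' For each pathway: extract its expression submatrix, derive weights per
#' the scheme (uniform applies none), apply them, and score by the method —
#' the permutation p-value of the global test, or the forest out-of-bag
#' error.  For the search schemes the score is the search's best objective,
#' whose fixed permutation stream per pathway matches the uniform score at
#' the same base seed, so search scores are comparable to uniform scores
#' pathway by pathway.  Pathways with no genes in the dataset are skipped
#' with a warning and listed in `skipped`.
#'
#' Vector-weight schemes (absT, Qdiff, RWV) are rejected under the forest
#' method: per-gene scaling cannot change tree splits, so their OOB scores
#' would be identical to uniform.
#'
#' @param dataset An `expression_dataset` with labels attached.
#' @param pathways A `pathway_collection`.
#' @param scheme One of `"uniform"`, `"absT"`, `"Qdiff"`, `"RWV"`, `"RWM"`.
#' @param method `"global_test"` or `"random_forest"`.
#' @param params A [screen_params()] bundle.
#' @return A `screen_result`: list with `method`, `scheme`, `score_kind`,
#'   `table` (data.frame: `pathway_id`, `m_genes`, `score`, `rank`, in file
#'   order), `skipped`, `params`.
#' @export
run_screen <- function(dataset, pathways, scheme = SCHEMES, method = METHODS,
                       params = screen_params()) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (method == "random_forest" && scheme %in% c("absT", "Qdiff", "RWV")) {
    unsupported_combination(
      scheme, method,
      "per-gene weights apply the same monotone scaling to every sample and cannot change out-of-bag errors")
  }
  Y <- dataset$labels
  if (is.null(Y)) stop("dataset has no labels attached")
  rows <- list()
  skipped <- character()
  for (i in seq_along(pathways$entries)) {
    entry <- pathways$entries[[i]]
    pm <- tryCatch(extract_pathway_matrix(dataset, entry),
                   pathweight_empty_pathway = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(pm)) {
      skipped <- c(skipped, entry$pathway_id)
      next
    }
    sub_seed <- derive_seed(params$seed, i)
    score <- score_pathway(pm$values, Y, scheme, method, params, sub_seed)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = entry$pathway_id, m_genes = ncol(pm$values),
      score = score, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no pathway had any gene in the dataset")
  tab <- do.call(rbind, rows)
  tab$rank <- rank_with_ties(tab$score)
  structure(
    list(method = method, scheme = scheme,
         score_kind = if (method == "global_test") "p_value" else "oob_error",
         table = tab, skipped = skipped, params = params),
    class = "screen_result")
}

# One pathway's score under a scheme/method; sub_seed fixes both the
# permutation stream and any search/forest randomness.
score_pathway <- function(X, Y, scheme, method, params, sub_seed) {
  if (method == "global_test") {
    switch(scheme,
      uniform = ,
      absT = ,
      Qdiff = {
        W <- switch(scheme,
                    uniform = NULL,
                    absT = abs_t_weights(X, Y),
                    Qdiff = qdiff_weights(X, Y))
        wX <- if (is.null(W)) X else apply_weights(X, W)
        # same fixed-stream objective the searches use, so scores share one
        # permutation grid per pathway at a common base seed
        make_gt_objective(Y, params$n_perm, seed = derive_seed(sub_seed, 1L))(wX)$value
      },
      RWV = rwv_search(X, Y, count = params$count,
                       range_lo = params$range_lo, range_hi = params$range_hi,
                       seed = sub_seed, n_perm = params$n_perm,
                       simple_draw = params$simple_draw)$best_objective,
      RWM = rwm_search(X, Y, count = params$count,
                       range_lo = params$range_lo, range_hi = params$range_hi,
                       objective = "global_test_p",
                       seed = sub_seed, n_perm = params$n_perm,
                       simple_draw = params$simple_draw)$best_objective)
  } else {
    switch(scheme,
      uniform = oob_error(X, Y, n_trees = params$n_trees,
                          seed = derive_seed(sub_seed, 1L))$oob_error,
      RWM = rwm_search_oob(X, Y, count = params$count,
                           range_lo = params$range_lo,
                           range_hi = params$range_hi,
                           n_trees = params$n_trees,
                           seed = sub_seed)$best_objective)
  }
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen: scheme %s, method %s; %d pathways scored (%s)%s\n",
              x$scheme, x$method, nrow(x$table), x$score_kind,
              if (length(x$skipped))
                sprintf(", %d skipped", length(x$skipped)) else ""))
  invisible(x)
}

#' Select the top-k pathways of a screen
#'
#' Rows are ordered by rank (ties kept in collection file order).  With
#' `include_ties = FALSE` exactly k rows are returned; with
#' `include_ties = TRUE` the selection extends through every row tied at the
#' rank of the k-th row, so a tie block is never split (the rule behind
#' reporting 33 pathways when the 20th rank sits inside a tie).
#'
#' @param result A `screen_result`.
#' @param k Number of pathways (before tie expansion).
#' @param include_ties Expand through the tie block containing row k.
#' @return Data.frame subset of the screen table, ordered by rank.
#' @export
select_top_k <- function(result, k, include_ties = FALSE) {
  stopifnot(inherits(result, "screen_result"), k >= 1L)
  tab <- result$table
  ord <- tab[order(tab$rank), , drop = FALSE]   # stable: file order inside ties
  if (k >= nrow(ord)) {
    if (k > nrow(ord)) {
      warning(sprintf("k = %d exceeds the %d screened pathways; returning all",
                      k, nrow(ord)))
    }
    return(ord)
  }
  if (include_ties) {
    ord[ord$rank <= ord$rank[k], , drop = FALSE]
  } else {
    ord[seq_len(k), , drop = FALSE]
  }
}

#' Count pathways significant at a threshold
#'
#' Number of screened pathways with p-value strictly below `alpha`.  Raw
#' (uncorrected) p-values are counted; no multiplicity adjustment is
#' applied.
#'
#' @param result A `screen_result` with `score_kind = "p_value"`.
#' @param alpha Threshold (default 0.05).
#' @return Integer count.
#' @export
count_significant <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "screen_result"))
  if (result$score_kind != "p_value") {
    stop("count_significant applies to p-value screens, not OOB screens")
  }
  sum(result$table$score < alpha)
}

#' Pathways whose rank improved between two screens
#'
#' Joins two screens over the same pathway universe and returns the
#' pathways whose rank improved (`rank_a - rank_b`) by at least `threshold`,
#' sorted by decreasing improvement.
#'
#' @param result_a,result_b `screen_result`s over identical pathway sets
#'   (typically uniform vs. a weighting scheme).
#' @param threshold Minimum rank improvement to report (default 1).
#' @return Data.frame: `pathway_id`, `rank_a`, `rank_b`, `score_a`,
#'   `score_b`, `improvement`.
#' @export
rank_changes <- function(result_a, result_b, threshold = 1L) {
  stopifnot(inherits(result_a, "screen_result"),
            inherits(result_b, "screen_result"))
  a <- result_a$table; b <- result_b$table
  if (!setequal(a$pathway_id, b$pathway_id)) {
    stop("the two screens cover different pathway universes")
  }
  idx <- match(a$pathway_id, b$pathway_id)
  out <- data.frame(pathway_id = a$pathway_id,
                    rank_a = a$rank, rank_b = b$rank[idx],
                    score_a = a$score, score_b = b$score[idx],
                    stringsAsFactors = FALSE)
  out$improvement <- out$rank_a - out$rank_b
  out <- out[out$improvement >= threshold, , drop = FALSE]
  out[order(-out$improvement), , drop = FALSE]
}

#' Pathways recurring across several top-k selections
#'
#' @param id_sets List (length >= 2) of pathway-id character vectors, one
#'   per scheme's top-k selection.
#' @param min_schemes Minimum number of sets an id must appear in
#'   (default 3).
#' @return Character vector of recurring pathway ids.
#' @export
find_overlaps <- function(id_sets, min_schemes = 3L) {
  if (length(id_sets) < 2L) stop("need at least two id sets")
  tally <- table(unlist(lapply(id_sets, unique)))
  names(tally)[tally >= min_schemes]
}

#' Convergence of the random search over iteration counts
#'
#' For each pathway, runs one random search to `max(counts)` iterations on a
#' single growing candidate stream and records the best objective at each
#' checkpoint (prefix evaluation, so the curve is non-increasing by
#' construction and costs one search per pathway).  Returns the mean best
#' objective across pathways at each count — the curve used to judge when
#' additional iterations stop paying.
#'
#' @param dataset An `expression_dataset` with labels.
#' @param pathways A `pathway_collection`.
#' @param counts Ascending iteration checkpoints (0 allowed = uniform).
#' @param scheme `"RWV"` or `"RWM"`.
#' @param params A [screen_params()] bundle (its `count` is ignored in favor
#'   of `max(counts)`).
#' @return Data.frame: `count`, `mean_objective`.
#' @export
iteration_sweep <- function(dataset, pathways, counts, scheme = c("RWM", "RWV"),
                            params = screen_params()) {
  scheme <- match.arg(scheme)
  if (is.unsorted(counts)) stop("counts must be ascending")
  Y <- dataset$labels
  if (is.null(Y)) stop("dataset has no labels attached")
  traces <- list()
  for (i in seq_along(pathways$entries)) {
    pm <- tryCatch(extract_pathway_matrix(dataset, pathways$entries[[i]]),
                   pathweight_empty_pathway = function(e) NULL)
    if (is.null(pm)) next
    sub_seed <- derive_seed(params$seed, i)
    fn <- if (scheme == "RWV") rwv_search else rwm_search
    res <- fn(pm$values, Y, count = max(counts),
              range_lo = params$range_lo, range_hi = params$range_hi,
              seed = sub_seed, n_perm = params$n_perm,
              checkpoints = counts)
    traces[[length(traces) + 1L]] <- res$trace$best_objective
  }
  if (!length(traces)) stop("no pathway could be screened")
  data.frame(count = counts,
             mean_objective = rowMeans(do.call(cbind, traces)))
}

#' Write a screen result as TSV
#'
#' The file opens with `#`-prefixed lines echoing every parameter needed to
#' reproduce it, followed by the score table in rank order.
#'
#' @param result A `screen_result`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(result, path) {
  p <- result$params
  hdr <- c(
    sprintf("# scheme=%s method=%s score_kind=%s", result$scheme,
            result$method, result$score_kind),
    sprintf("# n_perm=%d count=%d range=[%g,%g] n_trees=%d seed=%s simple_draw=%s",
            p$n_perm, p$count, p$range_lo, p$range_hi, p$n_trees,
            if (is.null(p$seed)) "NULL" else p$seed, p$simple_draw),
    sprintf("# skipped=%s",
            if (length(result$skipped)) paste(result$skipped, collapse = ",")
            else "none"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  tab <- result$table[order(result$table$rank), , drop = FALSE]
  writeLines("pathway_id\tm_genes\tscore\trank", con)
  writeLines(sprintf("%s\t%d\t%.17g\t%d", tab$pathway_id, tab$m_genes,
                     tab$score, tab$rank), con)
  invisible(path)
}
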