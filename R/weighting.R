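# Gene-weighting schemes.
#
# Two closed-form schemes derive a per-gene weight vector from differential
# expression: absT (normalized |two-sample t|) and Qdiff (normalized
# leave-one-gene-out change in the global test statistic Q).  Two
# random-search schemes draw candidate weights uniformly in a fixed range
# and keep the candidate minimizing an objective: RWV draws one weight per
# gene, RWM one weight per (sample, gene) cell.

#' Construct a weight specification
#'
#' @param kind `"vector"` (one weight per gene) or `"matrix"` (one weight
#'   per sample-gene cell).
#' @param weights Nonnegative numeric vector of length m, or n x m matrix.
#' @return A `weight_spec`.
#' @export
weight_spec <- function(kind = c("vector", "matrix"), weights) {
  kind <- match.arg(kind)
  if (kind == "vector") {
    weights <- as.numeric(weights)
  } else if (!is.matrix(weights)) {
    stop("matrix-kind weight_spec needs a matrix of weights")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(kind = kind, weights = weights), class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  if (x$kind == "vector") {
    cat(sprintf("weight_spec (vector, m = %d)\n", length(x$weights)))
  } else {
    cat(sprintf("weight_spec (matrix, %d x %d)\n",
                nrow(x$weights), ncol(x$weights)))
  }
  invisible(x)
}

#' Apply a weight specification to an expression matrix
#'
#' Vector weights scale columns (the same weight for every sample of a
#' gene); matrix weights multiply elementwise.
#'
#' @param X Numeric n x m matrix.
#' @param W A `weight_spec`.
#' @return The weighted matrix wX.
#' @export
apply_weights <- function(X, W) {
  stopifnot(inherits(W, "weight_spec"))
  if (W$kind == "vector") {
    if (length(W$weights) != ncol(X)) {
      stop(sprintf("weight vector length (%d) does not match gene columns (%d)",
                   length(W$weights), ncol(X)))
    }
    sweep(X, 2L, W$weights, `*`)
  } else {
    if (!all(dim(W$weights) == dim(X))) {
      stop("weight matrix dimensions do not match the expression matrix")
    }
    X * W$weights
  }
}

# Pooled two-sample t statistics, one per column of X.  Welch available for
# callers who prefer unequal-variance t; the default is the classical
# equal-variance form.
two_sample_t <- function(X, Y, flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  g0 <- X[Y == 0, , drop = FALSE]
  g1 <- X[Y == 1, , drop = FALSE]
  n0 <- nrow(g0); n1 <- nrow(g1)
  if (n0 < 2L || n1 < 2L) {
    stop("each class needs >= 2 samples to estimate gene variances")
  }
  m0 <- colMeans(g0); m1 <- colMeans(g1)
  v0 <- apply(g0, 2L, stats::var); v1 <- apply(g1, 2L, stats::var)
  if (flavor == "pooled") {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1))
  } else {
    (m1 - m0) / sqrt(v0 / n0 + v1 / n1)
  }
}

#' absT weights: normalized absolute t statistics
#'
#' Weight of gene j is \eqn{|T_j| / \sum_k |T_k|}, with \eqn{T_j} the
#' two-sample t statistic (pooled-variance form by default) of gene j
#' between the two classes, so the most differentially expressed gene in
#' the pathway receives the largest weight.
#'
#' Degenerate cases: a gene with zero within-class variance but a nonzero
#' mean difference has an infinite t; its |T| is capped at the largest
#' finite |T| in the pathway so the normalization stays defined.  If every
#' |T| is zero the scheme falls back to uniform weights 1/m with a warning.
#'
#' @inheritParams compute_Q
#' @param flavor `"pooled"` (classical equal-variance t) or `"welch"`.
#' @return A vector `weight_spec` whose weights sum to 1.
#' @export
abs_t_weights <- function(X, Y, flavor = c("pooled", "welch")) {
  check_xy(X, Y)
  abs_t <- abs(two_sample_t(X, Y, flavor = match.arg(flavor)))
  abs_t[is.nan(abs_t)] <- 0           # 0/0: no variance, no mean difference
  if (any(is.infinite(abs_t))) {
    finite <- abs_t[is.finite(abs_t)]
    cap <- if (length(finite) && max(finite) > 0) max(finite) else 1
    warning(sprintf("%d gene(s) with zero within-class variance and nonzero mean difference; |T| capped at %.3g",
                    sum(is.infinite(abs_t)), cap))
    abs_t[is.infinite(abs_t)] <- cap
  }
  total <- sum(abs_t)
  if (total == 0) {
    warning("all |T| are zero; falling back to uniform weights")
    return(weight_spec("vector", rep(1 / ncol(X), ncol(X))))
  }
  weight_spec("vector", abs_t / total)
}

#' Qdiff weights: normalized leave-one-gene-out change in Q
#'
#' Weight of gene j is \eqn{|Q - Q_{(-j)}| / \sum_k |Q - Q_{(-k)}|}, where
#' Q is the global test statistic of the full m-gene pathway and
#' \eqn{Q_{(-j)}} drops gene j.  A gene whose removal changes Q most is
#' taken to carry the most association signal.
#'
#' For m = 1 the leave-one-out statistic is undefined and the single gene
#' receives weight 1.  If every difference is zero the scheme falls back to
#' uniform weights with a warning.
#'
#' @inheritParams compute_Q
#' @return A vector `weight_spec` whose weights sum to 1.
#' @export
qdiff_weights <- function(X, Y) {
  check_xy(X, Y)
  m <- ncol(X)
  if (m == 1L) return(weight_spec("vector", 1))
  q_full <- compute_Q(X, Y)
  q_drop <- vapply(seq_len(m), function(j) {
    compute_Q(X[, -j, drop = FALSE], Y)
  }, numeric(1))
  d <- abs(q_full - q_drop)
  if (sum(d) == 0) {
    warning("all leave-one-out differences are zero; falling back to uniform weights")
    return(weight_spec("vector", rep(1 / m, m)))
  }
  weight_spec("vector", d / sum(d))
}

# --- random-search machinery ------------------------------------------------

# Global-test objective with one fixed permutation stream shared by every
# candidate, so candidates are compared on the same Monte-Carlo grid rather
# than through independent permutation noise.
make_gt_objective <- function(Y, n_perm, seed = NULL) {
  mu <- mean(Y)
  mu2 <- mu * (1 - mu)
  # observed labels occupy the first column so exact label ties (a shuffle
  # reproducing Y or its complement) tie Q_obs bitwise
  yc_all <- cbind(Y, perm_label_matrix(Y, n_perm, seed = seed)) - mu
  function(X) {
    q_all <- unname(q_for_labels(X, yc_all, mu2))
    list(value = mean(q_all[-1L] >= q_all[1L]), q = q_all[1L])
  }
}

# OOB objective: every candidate forest reuses the same tree seed so the
# comparison isolates the weights from forest randomness.
make_oob_objective <- function(Y, n_trees, seed = NULL) {
  function(X) {
    list(value = oob_error(X, Y, n_trees = n_trees, seed = seed)$oob_error,
         q = NA_real_)
  }
}

# Core random search shared by RWV and RWM.  Evaluates the uniform candidate
# first, then `count` random candidates from one seeded stream; keeps the
# minimizer.  Exact ties on the objective keep the first-found candidate
# unless the challenger has a strictly larger observed Q (only meaningful
# for the global-test objective, where p-values are granular at finite B).
random_weight_search <- function(X, Y, count, range_lo, range_hi,
                                 kind = c("vector", "matrix"),
                                 objective_fn, objective_kind,
                                 seed = NULL, simple_draw = FALSE,
                                 checkpoints = NULL) {
  kind <- match.arg(kind)
  check_xy(X, Y)
  if (count < 0L) stop("count must be >= 0")
  if (!(range_lo > 0 && range_lo <= range_hi)) {
    stop("weight range must satisfy 0 < range_lo <= range_hi")
  }
  n <- nrow(X); m <- ncol(X)
  uniform_w <- if (kind == "vector") rep(1, m) else matrix(1, n, m)
  init <- objective_fn(X)
  best_value <- init$value
  best_q <- init$q
  best_w <- uniform_w
  n_ties <- 0L
  trace <- if (!is.null(checkpoints)) numeric(length(checkpoints)) else NULL
  with_seed(seed, {
    for (i in seq_len(count)) {
      k <- if (kind == "vector") m else n * m
      vals <- stats::runif(k, range_lo, range_hi)
      # two-step draw: generate k values, then resample k of them with
      # replacement; `simple_draw` collapses this to the single draw
      w <- if (simple_draw) vals else sample(vals, k, replace = TRUE)
      if (kind == "matrix") w <- matrix(w, n, m)
      cand <- objective_fn(if (kind == "vector") sweep(X, 2L, w, `*`) else X * w)
      take <- FALSE
      if (cand$value < best_value) {
        take <- TRUE
      } else if (cand$value == best_value &&
                 !is.na(cand$q) && !is.na(best_q) && cand$q > best_q) {
        take <- TRUE
        n_ties <- n_ties + 1L
      }
      if (take) {
        best_value <- cand$value
        best_q <- cand$q
        best_w <- w
      }
      if (!is.null(trace)) {
        done <- checkpoints == i
        if (any(done)) trace[done] <- best_value
      }
    }
  })
  if (!is.null(trace) && any(checkpoints == 0L)) {
    trace[checkpoints == 0L] <- init$value
  }
  structure(
    list(best_weights = weight_spec(kind, best_w),
         best_objective = best_value,
         initial_objective = init$value,
         best_q = best_q,
         iterations_run = as.integer(count),
         seed = seed,
         objective_kind = objective_kind,
         n_tie_breaks = n_ties,
         trace = if (is.null(trace)) NULL
                 else data.frame(count = checkpoints, best_objective = trace)),
    class = "weight_search_result")
}

#' @export
print.weight_search_result <- function(x, ...) {
  cat(sprintf("weight search (%s, %s): %d iterations, objective %.4g -> %.4g\n",
              x$best_weights$kind, x$objective_kind,
              x$iterations_run, x$initial_objective, x$best_objective))
  invisible(x)
}

#' RWV: random weight-vector search
#'
#' Draws, for each of `count` iterations, m values uniformly in
#' `[range_lo, range_hi]`, resamples m of them with replacement, scales the
#' gene columns by the resulting weight vector, evaluates the global-test
#' permutation p-value of the weighted matrix, and keeps the weights
#' minimizing it.  The uniform (all-ones) candidate is evaluated first, so
#' the best objective never exceeds the uniform one.  All candidates share
#' one fixed permutation stream; the search is deterministic given `seed`.
#'
#' Because the permutation p-value is invariant to uniform rescaling of X,
#' only the relative pattern of a weight vector matters; the search explores
#' shapes, not scales.
#'
#' @inheritParams compute_Q
#' @param count Number of random candidates (default 25000; exploratory runs
#'   and tests use far fewer).
#' @param range_lo,range_hi Weight range (default 0.1 to 1.0).
#' @param objective Objective to minimize.  Only `"global_test_p"` is valid
#'   for vector weights: a per-gene weight is a monotone column scaling,
#'   which cannot change a classification forest's splits, so the OOB
#'   objective is rejected.
#' @param seed Integer seed, or `NULL`.
#' @param n_perm Permutations for the global-test objective (default 2000).
#' @param simple_draw Skip the resample-with-replacement second step and use
#'   the initial uniform draw directly.
#' @param checkpoints Optional ascending iteration counts at which to record
#'   the best objective (used by [iteration_sweep()]).
#' @return A `weight_search_result`.
#' @export
rwv_search <- function(X, Y, count = 25000L, range_lo = 0.1, range_hi = 1.0,
                       objective = c("global_test_p", "oob_error"),
                       seed = NULL, n_perm = 2000L, simple_draw = FALSE,
                       checkpoints = NULL) {
  objective <- match.arg(objective)
  if (objective == "oob_error") {
    unsupported_combination(
      "RWV", "random_forest",
      "a per-gene weight applies the same monotone scaling to every sample, which leaves the out-of-bag error unchanged")
  }
  objective_fn <- make_gt_objective(Y, n_perm, seed = derive_seed(seed, 1L))
  random_weight_search(X, Y, count, range_lo, range_hi, kind = "vector",
                       objective_fn = objective_fn,
                       objective_kind = "global_test_p",
                       seed = derive_seed(seed, 2L),
                       simple_draw = simple_draw, checkpoints = checkpoints)
}

#' RWM: random weight-matrix search
#'
#' Like [rwv_search()] but each candidate is an n x m matrix of weights
#' applied elementwise, so different samples of the same gene can receive
#' different weights.  The larger search space lets RWM reach objective
#' values at least as small as RWV at comparable iteration counts, at higher
#' cost.  Supports both the global-test p-value objective and the
#' random-forest out-of-bag error objective (see [rwm_search_oob()]).
#'
#' @inheritParams rwv_search
#' @param n_trees Trees per candidate forest for the OOB objective.
#' @return A `weight_search_result`.
#' @export
rwm_search <- function(X, Y, count = 25000L, range_lo = 0.1, range_hi = 1.0,
                       objective = c("global_test_p", "oob_error"),
                       seed = NULL, n_perm = 2000L, n_trees = 1000L,
                       simple_draw = FALSE, checkpoints = NULL) {
  objective <- match.arg(objective)
  objective_fn <- switch(objective,
    global_test_p = make_gt_objective(Y, n_perm, seed = derive_seed(seed, 1L)),
    oob_error = make_oob_objective(Y, n_trees, seed = derive_seed(seed, 1L)))
  random_weight_search(X, Y, count, range_lo, range_hi, kind = "matrix",
                       objective_fn = objective_fn,
                       objective_kind = objective,
                       seed = derive_seed(seed, 2L),
                       simple_draw = simple_draw, checkpoints = checkpoints)
}

#' Write a weight specification to TSV
#'
#' Vector weights are written as `gene_id<TAB>weight` rows; matrix weights
#' as a samples x genes table with identifier headers.
#'
#' @param W A `weight_spec`.
#' @param path Output path.
#' @param gene_ids Gene identifiers (column names for matrices).
#' @param sample_ids Sample identifiers (matrix rows only).
#' @export
write_weights_tsv <- function(W, path, gene_ids, sample_ids = NULL) {
  stopifnot(inherits(W, "weight_spec"))
  if (W$kind == "vector") {
    writeLines(c("gene_id\tweight",
                 sprintf("%s\t%.17g", gene_ids, W$weights)), path)
  } else {
    if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(W$weights)))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(c("sample_id", gene_ids), collapse = "\t"), con)
    for (i in seq_len(nrow(W$weights))) {
      writeLines(paste(c(sample_ids[i], sprintf("%.17g", W$weights[i, ])),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
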