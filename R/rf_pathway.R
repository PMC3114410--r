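# Random-forest out-of-bag error as a pathway score and search objective.
#
# Each tree of a bagged classification forest is grown on a bootstrap sample
# that leaves roughly one third of the samples out of bag (OOB); those
# samples act as the tree's test set.  A sample's OOB prediction is the
# majority vote of the trees for which it was out of bag, and the OOB error
# is the fraction of samples whose OOB prediction misses their true class.
# Scores are reported as proportions in [0, 1].

#' Out-of-bag error for one pathway matrix
#'
#' Grows a classification forest (via \pkg{randomForest}) on the pathway's
#' expression submatrix and returns the OOB misclassification proportion.
#' Samples that were never out of bag (possible at very small tree counts)
#' are excluded from the denominator and counted in `n_excluded`.
#'
#' Forest hyperparameters follow the randomForest conventions: `mtry =
#' floor(sqrt(m))`, unlimited depth, bootstrap samples of size n.
#'
#' @inheritParams compute_Q
#' @param n_trees Number of trees (default 1000; large counts such as 50000
#'   reproduce legacy settings but are rarely needed for stable estimates).
#' @param seed Integer seed for the forest's randomness, or `NULL`.
#' @return An `oob_result`: list with `oob_error`, `n_trees`, `seed`,
#'   `n_excluded`.
#' @export
oob_error <- function(X, Y, n_trees = 1000L, seed = NULL) {
  check_xy(X, Y)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))
  yf <- factor(Y, levels = c(0, 1))
  rf <- with_seed(seed, {
    randomForest::randomForest(x = X, y = yf, ntree = n_trees)
  })
  pred <- rf$predicted            # OOB majority-vote predictions; NA if never OOB
  voted <- !is.na(pred)
  if (!any(voted)) stop("no sample received an out-of-bag vote; increase n_trees")
  structure(
    list(oob_error = mean(pred[voted] != yf[voted]),
         n_trees = as.integer(n_trees),
         seed = seed,
         n_excluded = sum(!voted)),
    class = "oob_result")
}

#' @export
print.oob_result <- function(x, ...) {
  cat(sprintf("OOB error: %.4f (%d trees%s)\n", x$oob_error, x$n_trees,
              if (x$n_excluded > 0)
                sprintf(", %d sample(s) never out of bag", x$n_excluded)
              else ""))
  invisible(x)
}

#' RWM search minimizing the out-of-bag error
#'
#' Convenience wrapper around [rwm_search()] with the OOB objective:
#' candidate weight matrices are scored by the OOB error of a forest grown
#' on the weighted matrix, every candidate forest reusing the same tree
#' seed so that differences reflect the weights alone.
#'
#' Only the matrix scheme is meaningful here: vector schemes (absT, Qdiff,
#' RWV) scale each gene column by one constant, a strictly monotone
#' per-column transformation that preserves every attainable tree split and
#' hence the OOB error; requesting them under the forest objective raises an
#' unsupported-combination error.
#'
#' @inheritParams rwm_search
#' @return A `weight_search_result` with `objective_kind = "oob_error"`.
#' @export
rwm_search_oob <- function(X, Y, count = 25000L, range_lo = 0.1,
                           range_hi = 1.0, n_trees = 1000L, seed = NULL,
                           checkpoints = NULL) {
  rwm_search(X, Y, count = count, range_lo = range_lo, range_hi = range_hi,
             objective = "oob_error", seed = seed, n_trees = n_trees,
             checkpoints = checkpoints)
}
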