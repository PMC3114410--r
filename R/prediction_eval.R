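# Leave-one-out cross-validated prediction rates for selected pathways.
#
# Four standard classifiers: LDA (pooled-covariance linear discriminant),
# linear- and polynomial-kernel SVMs, and k-nearest neighbours.  Each
# pathway's expression submatrix is evaluated by LOOCV, and a report
# averages the per-pathway rates per classifier.
#
# Scale caveat: schemes that assign one weight per gene rescale columns,
# which leaves scale-invariant classifiers (LDA) untouched but can shift
# scale-sensitive ones (KNN, SVM).  Rates are computed faithfully on the
# weighted data either way; only a matrix weighting (different weights
# across samples) can change every classifier.

CLASSIFIERS <- c("LDA", "SVM_linear", "SVM_poly", "KNN")

#' Leave-one-out cross-validated prediction rate
#'
#' Holds out each sample once, trains the classifier on the rest, and
#' returns the fraction of held-out samples predicted correctly.
#'
#' Degenerate folds fall back to the training fold's majority class (ties
#' broken toward class 0), with a warning: this covers training folds with
#' a single class and classifier failures on constant features.
#'
#' @inheritParams compute_Q
#' @param classifier `"LDA"`, `"SVM_linear"`, `"SVM_poly"`, or `"KNN"`.
#' @param params Optional hyperparameters: `k` (KNN neighbours, default 3),
#'   `degree` (polynomial kernel, default 3), `cost` (SVM regularization,
#'   default 1), `standardize` (center/scale features on the training fold,
#'   default FALSE).
#' @return Scalar rate in \[0, 1\].
#' @export
loocv_rate <- function(X, Y, classifier = CLASSIFIERS, params = list()) {
  classifier <- match.arg(classifier)
  check_xy(X, Y)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs n >= 3")
  k <- params$k %||% 3L
  degree <- params$degree %||% 3L
  cost <- params$cost %||% 1
  standardize <- isTRUE(params$standardize)
  n_fallback <- 0L
  correct <- logical(n)
  for (i in seq_len(n)) {
    x_tr <- X[-i, , drop = FALSE]
    y_tr <- Y[-i]
    x_te <- X[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(x_tr)
      sd <- apply(x_tr, 2L, stats::sd)
      sd[sd == 0] <- 1
      x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sd, `/`)
      x_te <- sweep(sweep(x_te, 2L, mu), 2L, sd, `/`)
    }
    pred <- if (length(unique(y_tr)) < 2L) NULL else {
      tryCatch(predict_one(x_tr, y_tr, x_te, classifier, k, degree, cost),
               error = function(e) NULL)
    }
    if (is.null(pred)) {
      n_fallback <- n_fallback + 1L
      pred <- if (sum(y_tr == 1) > sum(y_tr == 0)) 1L else 0L
    }
    correct[i] <- pred == Y[i]
  }
  if (n_fallback > 0L) {
    warning(sprintf("%d of %d folds fell back to the training-majority class",
                    n_fallback, n))
  }
  mean(correct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predict_one <- function(x_tr, y_tr, x_te, classifier, k, degree, cost) {
  yf <- factor(y_tr, levels = c(0, 1))
  switch(classifier,
    LDA = {
      fit <- MASS::lda(x_tr, grouping = yf)
      as.integer(as.character(stats::predict(fit, x_te)$class))
    },
    SVM_linear = {
      fit <- e1071::svm(x_tr, yf, kernel = "linear", cost = cost,
                        scale = FALSE)
      as.integer(as.character(stats::predict(fit, x_te)))
    },
    SVM_poly = {
      fit <- e1071::svm(x_tr, yf, kernel = "polynomial", degree = degree,
                        cost = cost, scale = FALSE)
      as.integer(as.character(stats::predict(fit, x_te)))
    },
    KNN = {
      as.integer(as.character(class::knn(x_tr, x_te, cl = yf, k = k)))
    })
}

#' LOOCV prediction report for a top-k selection
#'
#' Evaluates every selected pathway with every requested classifier and
#' averages the per-pathway rates within each classifier, giving the
#' classifier x scheme grid one cell at a time.  When a matrix
#' `weight_spec` is supplied for a pathway (the RWM case — the only scheme
#' whose weights can alter single-gene classifiers sample by sample), it is
#' applied to the expression before classification; vector weights may also
#' be supplied and are applied as column scalings.
#'
#' @param dataset An `expression_dataset` with labels attached.
#' @param pathways A `pathway_collection`.
#' @param top Data.frame from [select_top_k()] (needs a `pathway_id`
#'   column), or a character vector of pathway ids.
#' @param scheme Label recorded in the report rows.
#' @param weight_specs Optional named list of `weight_spec`s keyed by
#'   pathway id.
#' @param classifiers Classifiers to run (default all four).
#' @param params Passed to [loocv_rate()].
#' @return A `prediction_report`: list with `summary` (data.frame:
#'   `classifier`, `scheme`, `mean_rate`) and `per_pathway` (data.frame:
#'   `pathway_id`, `classifier`, `rate`).
#' @export
evaluate_topk <- function(dataset, pathways, top, scheme = "uniform",
                          weight_specs = NULL,
                          classifiers = CLASSIFIERS, params = list()) {
  ids <- if (is.data.frame(top)) top$pathway_id else as.character(top)
  if (!length(ids)) stop("empty top-k selection")
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  all_ids <- vapply(pathways$entries, `[[`, character(1), "pathway_id")
  rows <- list()
  for (pid in ids) {
    idx <- match(pid, all_ids)
    if (is.na(idx)) stop("pathway not in collection: ", pid)
    entry <- pathways$entries[[idx]]
    pm <- extract_pathway_matrix(dataset, entry)
    X <- pm$values
    if (!is.null(weight_specs[[pid]])) {
      X <- apply_weights(X, weight_specs[[pid]])
    }
    for (cl in classifiers) {
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid, classifier = cl,
        rate = loocv_rate(X, dataset$labels, classifier = cl, params = params),
        stringsAsFactors = FALSE)
    }
  }
  per_pathway <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(classifiers, function(cl) {
    data.frame(classifier = cl, scheme = scheme,
               mean_rate = mean(per_pathway$rate[per_pathway$classifier == cl]),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, per_pathway = per_pathway),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("LOOCV prediction report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
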