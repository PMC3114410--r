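# The global test: a gene-set association statistic for binary outcomes.
#
# For a pathway matrix X (n samples x m genes) and labels Y, the statistic is
#
#   Q = (1/mu2) * (Y - mu)' R (Y - mu),   R = (1/m) X X',
#
# with mu = mean(Y) the null expectation of Y and mu2 = mu (1 - mu) its null
# variance.  Q grows when the between-sample covariance of expression aligns
# with the covariance of the outcomes, i.e. when samples with similar
# profiles share labels.  Significance comes from permuting Y.
#
# Note on the 1/mu2 scale factor: the statistic is sometimes printed in a
# form readable as either 1/mu^2 or 1/mu_2 (the second central moment).  We
# use mu2 = mu(1-mu), the binary null variance, following the original
# global-test formulation.  Because mu2 is constant for a fixed Y, the
# permutation p-value is identical under either reading; only the absolute
# scale of Q differs.

#' Global test statistic Q for one pathway
#'
#' Computes \eqn{Q = (Y-\mu)' R (Y-\mu) / \mu_2} with
#' \eqn{R = (1/m) X X'}, \eqn{\mu = \bar Y} and \eqn{\mu_2 = \mu(1-\mu)}.
#' Implemented as \eqn{\|X'(Y-\mu)\|^2 / (m \mu_2)}, which is algebraically
#' identical to the explicit double sum over sample pairs.
#'
#' @param X Numeric matrix, n samples x m genes.  No centering or scaling is
#'   applied; the data are assumed pre-normalized.
#' @param Y Binary vector of length n (1 = disease, 0 = normal); both classes
#'   must be present.
#' @return Nonnegative scalar Q.
#' @examples
#' X <- matrix(rnorm(18), 6, 3)
#' Y <- c(1, 1, 1, 0, 0, 0)
#' compute_Q(X, Y)
#' @export
compute_Q <- function(X, Y) {
  check_xy(X, Y)
  mu <- mean(Y)
  mu2 <- mu * (1 - mu)
  yc <- Y - mu
  sum(crossprod(X, yc)^2) / (ncol(X) * mu2)
}

# Columns of permuted labels sharing one stream: first column is the observed
# Y, the rest are uniform random shuffles.  Centering and scaling by mu/mu2
# are left to the caller (both are permutation-invariant).
perm_label_matrix <- function(Y, n_perm, seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sample(Y), numeric(length(Y)))
  })
}

# Q for every column of a centered label matrix at once (one BLAS call).
q_for_labels <- function(X, yc_mat, mu2) {
  colSums(crossprod(X, yc_mat)^2) / (ncol(X) * mu2)
}

#' Permutation p-value for the global test
#'
#' Approximates the null distribution of Q by uniform random shuffles of the
#' label vector (which preserve class sizes by construction) and reports
#' \eqn{p = \#\{b : Q_b \ge Q_{obs}\} / B}.  This is the plain frequency
#' estimator, so p = 0 is attainable; when it occurs the result is best read
#' as "p < 1/B".
#'
#' @inheritParams compute_Q
#' @param n_perm Number of permutations B (default 10000).
#' @param seed Integer seed fixing the permutation stream, or `NULL`.
#' @return A `global_test_result`: list with `q_observed`, `p_value`,
#'   `n_permutations`, `mu`, `mu2`, `seed`.
#' @examples
#' X <- matrix(rnorm(18), 6, 3)
#' Y <- c(1, 1, 1, 0, 0, 0)
#' permutation_p_value(X, Y, n_perm = 1000, seed = 1)
#' @export
permutation_p_value <- function(X, Y, n_perm = 10000L, seed = NULL) {
  check_xy(X, Y)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  mu <- mean(Y)
  mu2 <- mu * (1 - mu)
  perms <- perm_label_matrix(Y, n_perm, seed = seed)
  # observed labels ride along as the first column so that a permutation
  # reproducing Y (or its complement) ties Q_obs bitwise, not merely to
  # floating-point tolerance
  q_all <- unname(q_for_labels(X, cbind(Y, perms) - mu, mu2))
  q_obs <- q_all[1L]
  q_perm <- q_all[-1L]
  structure(
    list(q_observed = q_obs,
         p_value = mean(q_perm >= q_obs),
         n_permutations = as.integer(n_perm),
         mu = mu, mu2 = mu2, seed = seed),
    class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  extra <- if (x$p_value == 0) sprintf(" (< %.3g)", 1 / x$n_permutations) else ""
  cat(sprintf("global test: Q = %.4g, p = %.4g%s (%d permutations)\n",
              x$q_observed, x$p_value, extra, x$n_permutations))
  invisible(x)
}

#' Exact permutation p-value by full enumeration
#'
#' Enumerates all \eqn{C(n, n_1)} distinct arrangements of the label vector
#' and returns the proportion with \eqn{Q \ge Q_{obs}}.  The observed
#' arrangement is always among them, so \eqn{p \ge 1/C(n, n_1)}.  Used as
#' the exact reference for the Monte-Carlo estimator at small n.
#'
#' @inheritParams compute_Q
#' @param max_n Refuse enumeration beyond this sample size (default 10).
#' @return Scalar p-value on the grid \eqn{k/C(n, n_1)}.
#' @export
exact_permutation_p_value <- function(X, Y, max_n = 10L) {
  check_xy(X, Y)
  n <- length(Y)
  if (n > max_n) {
    stop(sprintf("n = %d too large for full enumeration (max_n = %d)", n, max_n))
  }
  n1 <- sum(Y == 1)
  pos <- utils::combn(n, n1)
  labels <- matrix(0, nrow = n, ncol = ncol(pos))
  labels[cbind(as.vector(pos),
               rep(seq_len(ncol(pos)), each = n1))] <- 1
  mu <- mean(Y)
  mu2 <- mu * (1 - mu)
  # observed labels share the enumeration's matrix call so arrangements
  # identical (or complementary) to Y tie Q_obs bitwise
  q_all <- unname(q_for_labels(X, cbind(Y, labels) - mu, mu2))
  mean(q_all[-1L] >= q_all[1L])
}
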