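# Shared fixtures: small random instances and studies, built in code.

# A random Gaussian instance with balanced labels.
rand_instance <- function(n = 6L, m = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- n %/% 2L
  list(X = matrix(rnorm(n * m), n, m),
       Y = c(rep(1L, n1), rep(0L, n - n1)))
}

# Independently coded Eq-style double-loop Q, the brute-force oracle.
q_double_sum <- function(X, Y) {
  n <- nrow(X); m <- ncol(X)
  mu <- mean(Y); mu2 <- mu * (1 - mu)
  R <- (X %*% t(X)) / m
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + R[i, j] * (Y[i] - mu) * (Y[j] - mu)
    }
  }
  total / mu2
}

# Independent pooled-t oracle via stats::t.test, one statistic per gene.
two_sample_t_oracle <- function(X, Y) {
  apply(X, 2, function(g) {
    unname(stats::t.test(g[Y == 1], g[Y == 0], var.equal = TRUE)$statistic)
  })
}

# A small synthetic study fast enough for module tests.
tiny_study <- function(seed = 42L, n_pathways = 5L, n_informative = 1L,
                       n_samples = 20L) {
  make_synthetic_study(n_genes = 60L, n_pathways = n_pathways,
                       pathway_size_range = c(4L, 8L),
                       n_samples = n_samples,
                       n_informative_pathways = n_informative,
                       shift_size = 2, seed = seed)
}

# Write a tiny expression/GMT/label trio for reader tests; returns paths.
write_toy_files <- function(dir) {
  expr <- file.path(dir, "expr.tsv")
  writeLines(c("id\tS1\tS2\tS3\tS4",
               "G1\t1\t2\t3\t4",
               "G2\t0\t0\t1\t1",
               "G3\t-1\t0.5\t2\t0"), expr)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tfirst set\tG1\tG2",
               "P2\tsecond set\tG3\tG1\tG9"), gmt)
  cls <- file.path(dir, "labels.cls")
  writeLines(c("4 2 1", "# norm dis", "norm norm dis dis"), cls)
  list(expr = expr, gmt = gmt, cls = cls)
}
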