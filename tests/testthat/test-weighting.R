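test_that("absT weights match the pooled-t hand computation and contracts", {
  # gene1: class0 = (0,2), class1 = (4,6): pooled t = 2.828
  # gene2: class0 = (0,2), class1 = (2,4): pooled t = 1.414 -> weights 2/3, 1/3
  X <- cbind(c(0, 2, 4, 6), c(0, 2, 2, 4))
  Y <- c(0, 0, 1, 1)
  w <- abs_t_weights(X, Y)
  expect_equal(w$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(w$weights), 1)

  # identical gene columns share the weight equally
  Xdup <- cbind(c(0, 2, 4, 6), c(0, 2, 4, 6))
  expect_equal(abs_t_weights(Xdup, Y)$weights, c(0.5, 0.5))

  # single gene gets all the weight
  expect_equal(abs_t_weights(X[, 1, drop = FALSE], Y)$weights, 1)

  # order of weights matches order of |T|
  inst <- rand_instance(12, 5, seed = 31)
  wt <- abs_t_weights(inst$X, inst$Y)$weights
  tt <- abs(apply(inst$X, 2, function(g) {
    stats::t.test(g[inst$Y == 1], g[inst$Y == 0], var.equal = TRUE)$statistic
  }))
  expect_equal(order(wt), order(tt))
  expect_equal(wt, unname(tt / sum(tt)), tolerance = 1e-12)
})

test_that("absT handles degenerate variance patterns", {
  Y <- c(0, 0, 1, 1)
  # zero within-class variance with nonzero mean difference: capped, not Inf
  X <- cbind(c(0, 0, 1, 1), c(0, 2, 4, 6))
  expect_warning(w <- abs_t_weights(X, Y), "capped")
  expect_true(all(is.finite(w$weights)))
  expect_equal(sum(w$weights), 1)
  expect_equal(w$weights[1], w$weights[2])   # capped at the largest finite |T|

  # all-flat data falls back to uniform
  expect_warning(wu <- abs_t_weights(matrix(1, 4, 3), Y), "uniform")
  expect_equal(wu$weights, rep(1 / 3, 3))
})

test_that("Qdiff weights agree with a from-scratch leave-one-out oracle", {
  inst <- rand_instance(6, 3, seed = 17)
  w <- qdiff_weights(inst$X, inst$Y)
  q_full <- q_double_sum(inst$X, inst$Y)
  d <- vapply(1:3, function(j) {
    abs(q_full - q_double_sum(inst$X[, -j, drop = FALSE], inst$Y))
  }, numeric(1))
  expect_equal(w$weights, d / sum(d), tolerance = 1e-10)

  # m = 1 fallback and duplicated-column symmetry
  expect_equal(qdiff_weights(inst$X[, 1, drop = FALSE], inst$Y)$weights, 1)
  Xdup <- inst$X[, c(1, 1, 2)]
  wd <- qdiff_weights(Xdup, inst$Y)$weights
  expect_equal(wd[1], wd[2], tolerance = 1e-12)
})

test_that("closed-form weights are equivariant to gene permutation", {
  inst <- rand_instance(10, 4, seed = 23)
  perm <- c(3, 1, 4, 2)
  expect_equal(abs_t_weights(inst$X[, perm], inst$Y)$weights,
               abs_t_weights(inst$X, inst$Y)$weights[perm])
  expect_equal(qdiff_weights(inst$X[, perm], inst$Y)$weights,
               qdiff_weights(inst$X, inst$Y)$weights[perm],
               tolerance = 1e-12)
})

test_that("apply_weights covers vector, matrix and error cases", {
  X <- matrix(1:6, 2, 3)
  expect_equal(apply_weights(X, weight_spec("vector", rep(1, 3))), X)
  zeroed <- apply_weights(X, weight_spec("vector", c(1, 0, 1)))
  expect_equal(zeroed[, 2], c(0, 0))
  expect_equal(apply_weights(X, weight_spec("matrix", matrix(1, 2, 3))), X)
  expect_error(apply_weights(X, weight_spec("vector", c(1, 2))), "length")
  expect_error(weight_spec("vector", c(-1, 1)), "nonnegative")
})

test_that("random searches satisfy their optimization contracts", {
  inst <- rand_instance(10, 4, seed = 41)

  # count = 0 returns the uniform candidate
  s0 <- rwv_search(inst$X, inst$Y, count = 0, seed = 1, n_perm = 200)
  expect_equal(s0$best_objective, s0$initial_objective)
  expect_equal(s0$best_weights$weights, rep(1, 4))

  # best <= initial always; deterministic per seed
  s1 <- rwv_search(inst$X, inst$Y, count = 60, seed = 5, n_perm = 200)
  s2 <- rwv_search(inst$X, inst$Y, count = 60, seed = 5, n_perm = 200)
  expect_lte(s1$best_objective, s1$initial_objective)
  expect_identical(s1$best_weights$weights, s2$best_weights$weights)
  expect_identical(s1$best_objective, s2$best_objective)
  expect_equal(s1$iterations_run, 60L)

  # prefix property: best objective non-increasing in count on one stream
  tr <- rwv_search(inst$X, inst$Y, count = 80, seed = 5, n_perm = 200,
                   checkpoints = c(0L, 20L, 40L, 80L))$trace
  expect_true(all(diff(tr$best_objective) <= 0))
  expect_equal(tr$best_objective[1], s1$initial_objective)

  # matrix search: same contracts, weights within range
  sm <- rwm_search(inst$X, inst$Y, count = 40, seed = 9, n_perm = 200)
  expect_lte(sm$best_objective, sm$initial_objective)
  if (sm$best_objective < sm$initial_objective) {
    expect_true(all(sm$best_weights$weights >= 0.1 &
                    sm$best_weights$weights <= 1.0))
  }
  expect_error(rwv_search(inst$X, inst$Y, count = 5, range_lo = 0), "range")
})

test_that("an all-ones-proportional candidate scores exactly the uniform objective", {
  # the fixed-stream global-test objective is invariant to uniform rescaling,
  # so only the relative pattern of an RWV weight vector matters
  inst <- rand_instance(8, 3, seed = 51)
  obj <- pathweight:::make_gt_objective(inst$Y, 300, seed = 4)
  expect_identical(obj(inst$X)$value, obj(0.25 * inst$X)$value)
})

test_that("search rejects the OOB objective for vector weights", {
  inst <- rand_instance(8, 3, seed = 61)
  expect_error(rwv_search(inst$X, inst$Y, count = 5, objective = "oob_error"),
               class = "pathweight_unsupported_combination")
})
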