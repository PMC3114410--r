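test_that("competition ranking reproduces the 1224 tie pattern", {
  expect_equal(rank_with_ties(c(.26, .29, .29, .31, .31, .31, .34)),
               c(1L, 2L, 2L, 4L, 4L, 4L, 7L))
  expect_equal(rank_with_ties(c(3, 1, 2)), c(3L, 1L, 2L))
  expect_equal(rank_with_ties(rep(0.5, 4)), rep(1L, 4))
  expect_error(rank_with_ties(c(1, NA)), "finite")
})

make_screen <- function(scores, score_kind = "p_value") {
  structure(list(
    method = if (score_kind == "p_value") "global_test" else "random_forest",
    scheme = "uniform", score_kind = score_kind,
    table = data.frame(pathway_id = sprintf("P%02d", seq_along(scores)),
                       m_genes = 5L, score = scores,
                       rank = rank_with_ties(scores),
                       stringsAsFactors = FALSE),
    skipped = character(), params = screen_params()),
    class = "screen_result")
}

test_that("top-k selection respects and never splits tie blocks", {
  s <- make_screen(c(.26, .29, .29, .31, .31, .31, .34, .4))
  expect_equal(nrow(select_top_k(s, 5, include_ties = FALSE)), 5L)
  # k = 5 lands inside the rank-4 block of three: expands to 6 rows
  expect_equal(nrow(select_top_k(s, 5, include_ties = TRUE)), 6L)
  expect_warning(all_rows <- select_top_k(s, 99), "exceeds")
  expect_equal(nrow(all_rows), 8L)

  # a 20 -> 33 expansion: 19 leaders, then a 14-way tie spanning ranks 20-33
  scores <- c(seq(0.001, 0.019, by = 0.001), rep(0.5, 14), seq(0.6, 0.9, 0.1))
  s2 <- make_screen(scores)
  top <- select_top_k(s2, 20, include_ties = TRUE)
  expect_equal(nrow(top), 33L)
  expect_equal(max(top$rank), 20L)

  # selection is ordered by rank and never drops part of an included block
  ranks_present <- table(top$rank)
  full_ranks <- table(s2$table$rank[s2$table$rank <= 20])
  expect_equal(ranks_present, full_ranks)
})

test_that("significance counting is strict and monotone in alpha", {
  s <- make_screen(c(.01, .049, .05, .2))
  expect_equal(count_significant(s, 0.05), 2L)
  expect_equal(count_significant(make_screen(rep(0.05, 3)), 0.05), 0L)
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  counts <- vapply(alphas, function(a) count_significant(s, a), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_significant(make_screen(c(.1, .2), "oob_error")), "OOB")
})

test_that("rank-change tables equal a brute-force join", {
  a <- make_screen(c(.5, .1, .9, .3))
  b <- make_screen(c(.05, .5, .2, .4))
  expect_equal(nrow(rank_changes(a, a, threshold = 1)), 0L)

  ch <- rank_changes(a, b, threshold = 1)
  merged <- merge(a$table, b$table, by = "pathway_id",
                  suffixes = c("_a", "_b"))
  merged$improvement <- merged$rank_a - merged$rank_b
  expected <- merged[merged$improvement >= 1, "pathway_id"]
  expect_setequal(ch$pathway_id, expected)
  expect_true(all(diff(ch$improvement) <= 0))

  mismatched <- make_screen(c(.1, .2, .3))
  expect_error(rank_changes(a, mismatched), "universe")
})

test_that("overlap detection equals a brute-force membership tally", {
  sets <- list(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"), c("C", "B"))
  expect_setequal(find_overlaps(sets, min_schemes = 3), c("B", "C"))
  expect_setequal(find_overlaps(sets, min_schemes = 4), "C")
  expect_equal(length(find_overlaps(list(c("A"), c("B")), 2)), 0L)
  expect_error(find_overlaps(list(c("A"))), "two")

  tally <- table(unlist(lapply(sets, unique)))
  expect_setequal(find_overlaps(sets, 2), names(tally)[tally >= 2])
})

test_that("screens score, rank and skip pathways correctly", {
  study <- tiny_study(seed = 8)
  params <- screen_params(n_perm = 200, seed = 3)
  res <- run_screen(study$dataset, study$pathways, scheme = "uniform",
                    method = "global_test", params = params)
  expect_equal(nrow(res$table), 5L)
  expect_setequal(res$table$rank, rank_with_ties(res$table$score))
  expect_identical(res$score_kind, "p_value")

  # a pathway disjoint from the dataset is skipped with a warning, not ranked
  extra <- study$pathways
  extra$entries[[6]] <- list(pathway_id = "PWX", pathway_name = "missing",
                             gene_ids = c("NOPE1", "NOPE2"))
  coll <- pathway_collection(extra$entries)
  expect_warning(res2 <- run_screen(study$dataset, coll, scheme = "uniform",
                                    method = "global_test", params = params),
                 "none of its")
  expect_equal(res2$skipped, "PWX")
  expect_equal(nrow(res2$table), 5L)
})

test_that("search schemes never score worse than uniform at matched seeds", {
  study <- tiny_study(seed = 12, n_pathways = 3)
  params <- screen_params(n_perm = 150, count = 25, seed = 5)
  uni <- run_screen(study$dataset, study$pathways, "uniform", "global_test",
                    params)
  for (scheme in c("RWV", "RWM")) {
    res <- run_screen(study$dataset, study$pathways, scheme, "global_test",
                      params)
    expect_true(all(res$table$score <= uni$table$score),
                info = scheme)
  }
})

test_that("iteration sweep is a non-increasing prefix curve", {
  study <- tiny_study(seed = 14, n_pathways = 3)
  params <- screen_params(n_perm = 150, seed = 2)
  curve <- iteration_sweep(study$dataset, study$pathways,
                           counts = c(0L, 10L, 20L, 40L),
                           scheme = "RWM", params = params)
  expect_equal(curve$count, c(0L, 10L, 20L, 40L))
  expect_true(all(diff(curve$mean_objective) <= 0))

  # counts = 0 alone returns the uniform mean
  c0 <- iteration_sweep(study$dataset, study$pathways, counts = 0L,
                        scheme = "RWM", params = params)
  uni <- run_screen(study$dataset, study$pathways, "uniform", "global_test",
                    params)
  expect_equal(c0$mean_objective, mean(uni$table$score))
})
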