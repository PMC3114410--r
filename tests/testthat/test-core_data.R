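test_that("expression TSV reading honors orientation and round-trips", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)

  d <- read_expression_tsv(paths$expr, orientation = "genes_in_rows")
  expect_equal(dim(d$values), c(4L, 3L))
  expect_equal(d$gene_ids, c("G1", "G2", "G3"))
  expect_equal(d$sample_ids, c("S1", "S2", "S3", "S4"))
  expect_equal(unname(d$values[, "G1"]), c(1, 2, 3, 4))

  # round trip in both orientations reproduces values exactly
  for (orient in c("genes_in_rows", "samples_in_rows")) {
    set.seed(9)
    orig <- expression_dataset(matrix(rnorm(12) * 1e3, 4, 3),
                               gene_ids = c("A", "B", "C"),
                               sample_ids = sprintf("S%d", 1:4))
    out <- file.path(dir, paste0("rt_", orient, ".tsv"))
    write_expression_tsv(orig, out, orientation = orient)
    back <- read_expression_tsv(out, orientation = orient)
    expect_identical(back$values, orig$values)
  }
})

test_that("malformed expression files fail with informative errors", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("id\tS1\tS2", "G1\t1\t2", "G1\t3\t4"), dup)
  expect_error(read_expression_tsv(dup, "genes_in_rows"), "G1")

  ragged <- file.path(dir, "ragged.tsv")
  writeLines(c("id\tS1\tS2", "G1\t1\t2", "G2\t3"), ragged)
  expect_error(read_expression_tsv(ragged, "genes_in_rows"), "ragged")

  alpha <- file.path(dir, "alpha.tsv")
  writeLines(c("id\tS1\tS2", "G1\t1\tx"), alpha)
  expect_error(read_expression_tsv(alpha, "genes_in_rows"), "non-numeric")
})

test_that("GMT parsing keeps file order and de-duplicates genes per line", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tdesc\tG1\tG2",
               "P2\tdesc\tG3\tG3\tG1"), gmt)
  coll <- read_gmt(gmt)
  expect_equal(length(coll), 2L)
  expect_equal(coll$entries[[1L]]$gene_ids, c("G1", "G2"))
  expect_equal(coll$entries[[2L]]$gene_ids, c("G3", "G1"))

  # many-line synthetic file keeps count and order
  big <- file.path(dir, "big.gmt")
  writeLines(sprintf("PW%03d\tset %d\tGA\tGB", 1:278, 1:278), big)
  coll_big <- read_gmt(big)
  expect_equal(length(coll_big), 278L)
  expect_equal(coll_big$entries[[278L]]$pathway_id, "PW278")

  short <- file.path(dir, "short.gmt")
  writeLines(c("P1\tdesc\tG1", "P2\tonlydesc"), short)
  expect_error(read_gmt(short), "line 2")
})

test_that("CLS parsing maps the first-listed class to 0 and validates shape", {
  dir <- withr::local_tempdir()
  cls <- file.path(dir, "ok.cls")
  writeLines(c("4 2 1", "# norm dis", "norm norm dis dis"), cls)
  expect_equal(read_cls(cls), c(0L, 0L, 1L, 1L))

  three <- file.path(dir, "three.cls")
  writeLines(c("4 3 1", "# a b c", "a b c a"), three)
  expect_error(read_cls(three), "exactly 2")

  short <- file.path(dir, "short.cls")
  writeLines(c("4 2 1", "# a b", "a b a"), short)
  expect_error(read_cls(short), "declares 4")

  rt <- file.path(dir, "rt.cls")
  write_cls(c(0L, 1L, 1L, 0L), rt)
  expect_equal(read_cls(rt), c(0L, 1L, 1L, 0L))
})

test_that("labels attach by name when named and positionally when bare", {
  d <- expression_dataset(matrix(0, 3, 2), c("G1", "G2"),
                          c("S1", "S2", "S3"))
  named <- c(S3 = 1L, S1 = 0L, S2 = 1L)
  expect_equal(attach_labels(d, named)$labels, c(0L, 1L, 1L))
  expect_warning(d2 <- attach_labels(d, c(1L, 0L, 1L)), "positionally")
  expect_equal(d2$labels, c(1L, 0L, 1L))
  expect_error(attach_labels(d, c(S1 = 0L, S2 = 1L)), "S3")
})

test_that("pathway extraction preserves set order and flags missing genes", {
  d <- expression_dataset(matrix(seq_len(8), 4, 2),
                          gene_ids = c("G1", "G2"),
                          sample_ids = sprintf("S%d", 1:4),
                          labels = c(0L, 0L, 1L, 1L))
  entry <- list(pathway_id = "P", pathway_name = "p",
                gene_ids = c("G2", "G9", "G1"))
  pm <- extract_pathway_matrix(d, entry)
  expect_equal(pm$gene_ids, c("G2", "G1"))   # pathway order, G9 dropped
  expect_equal(pm$n_missing, 1L)
  expect_equal(ncol(pm$values), 2L)

  full <- extract_pathway_matrix(
    d, list(pathway_id = "P2", pathway_name = "p", gene_ids = c("G1", "G2")))
  expect_equal(full$n_missing, 0L)

  expect_error(
    extract_pathway_matrix(
      d, list(pathway_id = "P3", pathway_name = "p", gene_ids = "G7")),
    class = "pathweight_empty_pathway")
  expect_error(extract_pathway_matrix(
    expression_dataset(matrix(0, 2, 1), "G1", c("a", "b")),
    entry), "labels")
})
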