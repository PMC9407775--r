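test_that("expression tables round-trip through read/write with validation", {
  dir <- withr::local_tempdir()
  expr_path <- file.path(dir, "expr.tsv")
  lab_path <- file.path(dir, "labels.tsv")
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   S1 = c(1, 4, 7), S2 = c(2, 5, 8),
                   S3 = c(3, 6, 9), S4 = c(0, 1, 2))
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = paste0("S", 1:4),
                         label = c("CTL", "CTL", "AD", "AD")),
              lab_path, sep = "\t", quote = FALSE, row.names = FALSE)

  em <- read_expression_table(expr_path, lab_path)
  expect_s3_class(em, "expression_set")
  expect_equal(dim(em), c(3L, 4L))
  expect_identical(rownames(em$values), c("g1", "g2", "g3"))
  expect_identical(colnames(em$values), paste0("S", 1:4))
  expect_equal(as.character(em$labels), c("CTL", "CTL", "AD", "AD"))
  expect_false(em$normalized)

  # write back and re-read: identical content
  out_expr <- file.path(dir, "out.tsv")
  out_lab <- file.path(dir, "out_labels.tsv")
  write_expression_table(em, out_expr, out_lab)
  em2 <- read_expression_table(out_expr, out_lab)
  expect_equal(em2$values, em$values)
  expect_equal(em2$labels, em$labels)

  # samples-in-rows input with transpose flag
  tmat <- t(as.matrix(df[, -1]))
  tdf <- data.frame(sample_id = rownames(tmat), tmat, check.names = FALSE)
  colnames(tdf) <- c("sample_id", df$gene_id)
  tpath <- file.path(dir, "transposed.tsv")
  write.table(tdf, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  em3 <- read_expression_table(tpath, lab_path, transpose = TRUE)
  expect_equal(em3$values, em$values)
})

test_that("malformed inputs raise identifier / label-mismatch / parse errors", {
  dir <- withr::local_tempdir()
  lab_path <- file.path(dir, "labels.tsv")
  write.table(data.frame(sample_id = paste0("S", 1:4),
                         label = c("CTL", "CTL", "AD", "AD")),
              lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tab <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  # sample missing from the label file
  short_lab <- write_tab(data.frame(sample_id = paste0("S", 1:3),
                                    label = c("CTL", "CTL", "AD")),
                         "short_labels.tsv")
  good <- write_tab(data.frame(gene_id = c("g1", "g2"), S1 = 1:2, S2 = 3:4,
                               S3 = 5:6, S4 = 7:8), "good.tsv")
  expect_error(read_expression_table(good, short_lab), "label-mismatch")

  # duplicated gene id
  dup <- write_tab(data.frame(gene_id = c("g1", "g1"), S1 = 1:2, S2 = 3:4,
                              S3 = 5:6, S4 = 7:8), "dup.tsv")
  expect_error(read_expression_table(dup, lab_path), "identifier error")

  # non-numeric cell names its row and column
  bad <- write_tab(data.frame(gene_id = c("g1", "g2"), S1 = c("1", "oops"),
                              S2 = 3:4, S3 = 5:6, S4 = 7:8), "bad.tsv")
  expect_error(read_expression_table(bad, lab_path), "g2.*S1")
})

test_that("min-max normalization rescales each gene to [0, 1]", {
  v <- rbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5), g3 = c(0.1, 0.9, 0.5))
  colnames(v) <- c("a", "b", "c")
  em <- expression_set(v, c(a = "x", b = "x", c = "y"))
  nm <- minmax_normalize(em)
  expect_true(nm$normalized)
  expect_equal(unname(nm$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(nm$values["g2", ]), c(0, 0, 0))   # constant row rule

  # idempotence
  expect_equal(minmax_normalize(nm)$values, nm$values)

  # per-gene min 0 / max 1 for non-constant genes, to 1e-12
  set.seed(1)
  big <- expression_set(
    matrix(rnorm(50 * 8), 50, 8,
           dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:8))),
    stats::setNames(rep(c("A", "B"), 4), sprintf("s%d", 1:8)))
  bn <- minmax_normalize(big)
  expect_true(all(abs(apply(bn$values, 1, min)) < 1e-12))
  expect_true(all(abs(apply(bn$values, 1, max) - 1) < 1e-12))
})

test_that("intersect_and_merge keeps shared genes and re-normalizes", {
  mk <- function(genes, samples, seed) {
    set.seed(seed)
    v <- matrix(runif(length(genes) * length(samples)), length(genes),
                dimnames = list(genes, samples))
    minmax_normalize(expression_set(
      v, stats::setNames(rep(c("A", "B"), length.out = length(samples)),
                         samples)))
  }
  a <- mk(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4"), 1)
  b <- mk(c("g2", "g3", "g4"), c("t1", "t2", "t3"), 2)

  m <- intersect_and_merge(list(a, b))
  expect_identical(rownames(m$values), c("g2", "g3"))  # first dataset's order
  expect_equal(ncol(m$values), 7L)                     # sample conservation
  expect_true(m$normalized)
  expect_true(all(abs(apply(m$values, 1, min)) < 1e-12))

  # single dataset: identity gene set, re-normalized
  one <- intersect_and_merge(list(a))
  expect_identical(rownames(one$values), rownames(a$values))

  # disjoint gene sets
  c_ <- mk(c("h1", "h2"), c("u1", "u2"), 3)
  expect_error(intersect_and_merge(list(a, c_)), "empty-intersection")

  # duplicate sample ids across datasets
  d <- mk(c("g1", "g2", "g3"), c("s1", "x2"), 4)
  expect_error(intersect_and_merge(list(a, d)), "identifier error")
})

test_that("stratified split is deterministic, exhaustive and per-class sized", {
  sim <- simulate_expression(synthetic_spec(
    n_genes = 10L, n_informative = 0L,
    samples_per_class = c(CTL = 100L, AD = 100L), seed = 5L))
  parts <- split_train_test(sim$em, test_fraction = 0.2, seed = 9L)
  expect_equal(ncol(parts$train$values), 160L)
  expect_equal(ncol(parts$test$values), 40L)
  expect_equal(unname(table(parts$test$labels)), c(20L, 20L),
               ignore_attr = TRUE)

  # partition: disjoint and exhaustive
  tr_ids <- colnames(parts$train$values)
  te_ids <- colnames(parts$test$values)
  expect_length(intersect(tr_ids, te_ids), 0L)
  expect_setequal(c(tr_ids, te_ids), colnames(sim$em$values))

  # determinism
  parts2 <- split_train_test(sim$em, test_fraction = 0.2, seed = 9L)
  expect_identical(colnames(parts2$test$values), te_ids)

  # a different seed gives a different draw
  parts3 <- split_train_test(sim$em, test_fraction = 0.2, seed = 10L)
  expect_false(identical(colnames(parts3$test$values), te_ids))

  # class with < 2 samples
  v <- matrix(runif(8), 2, 4,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  em1 <- expression_set(v, c(s1 = "A", s2 = "A", s3 = "A", s4 = "B"))
  expect_error(split_train_test(em1, 0.2, 1L), "insufficient-class")
})
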