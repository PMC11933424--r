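test_that("largest_remainder allocates exactly and breaks ties to earlier splits", {
  expect_equal(largest_remainder(10, c(0.6, 0.2, 0.2)), c(6L, 2L, 2L))
  # quotas 4.2/1.4/1.4 -> floors 4/1/1, one seat to the first tied remainder
  expect_equal(largest_remainder(7, c(0.6, 0.2, 0.2)), c(4L, 2L, 1L))
  set.seed(40)
  for (i in 1:100) {
    fr <- stats::runif(3); fr <- fr / sum(fr)
    n <- sample(1:500, 1)
    alloc <- largest_remainder(n, fr)
    expect_equal(sum(alloc), n)
    expect_true(all(abs(alloc - n * fr) < 1))
  }
})

test_that("stratified_split preserves class counts and is deterministic", {
  cfg <- generator_config(n_per_class = c(10, 10, 10), seed = 41)
  corpus <- generate_corpus(cfg)
  sp <- stratified_split(corpus, seed = 41)
  expected_per_class <- c(6L, 2L, 2L)
  for (s in seq_along(sp)) {
    counts <- table(factor(corpus_labels(sp[[s]]), levels = PK_LABELS))
    expect_equal(as.integer(counts), rep(expected_per_class[s], 3))
  }
  # disjoint and exhaustive
  ids <- unlist(lapply(sp, function(s)
    vapply(s$records, `[[`, character(1), "table_id")))
  expect_setequal(ids, vapply(corpus$records, `[[`, character(1),
                              "table_id"))
  expect_equal(anyDuplicated(ids), 0L)
  # per-class totals preserved under any proportions
  cfg2 <- generator_config(n_per_class = c(13, 7, 22), seed = 42)
  corpus2 <- generate_corpus(cfg2)
  sp2 <- stratified_split(corpus2, seed = 42)
  totals <- Reduce(`+`, lapply(sp2, function(s)
    table(factor(corpus_labels(s), levels = PK_LABELS))))
  expect_equal(as.integer(totals), c(13L, 7L, 22L))
  # determinism
  sp3 <- stratified_split(corpus2, seed = 42)
  expect_identical(lapply(sp3, corpus_labels), lapply(sp2, corpus_labels))
  # infeasible class
  tiny <- pk_corpus(list(tiny_pk_table("a", "PK"), tiny_pk_table("b", "PK"),
                         tiny_pk_table("c", "DEMOGRAPHICS"),
                         tiny_pk_table("d", "DEMOGRAPHICS"),
                         tiny_pk_table("e", "DEMOGRAPHICS"),
                         tiny_pk_table("f", "OTHER"),
                         tiny_pk_table("g", "OTHER"),
                         tiny_pk_table("h", "OTHER")))
  expect_error(stratified_split(tiny, seed = 1), "cannot split")
})

test_that("score matches the hand-computed worked example", {
  y_true <- c("PK", "PK", "OTHER")
  y_pred <- c("PK", "OTHER", "OTHER")
  m <- score(y_true, y_pred)
  expect_equal(m$micro$F1, 2 / 3)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "PK"], 1)
  expect_equal(pc$recall[pc$class == "PK"], 0.5)
  expect_equal(pc$f1[pc$class == "PK"], 2 / 3)
  expect_equal(pc$precision[pc$class == "OTHER"], 0.5)
  expect_equal(pc$recall[pc$class == "OTHER"], 1)
  expect_equal(pc$f1[pc$class == "OTHER"], 2 / 3)
  expect_equal(pc$support[pc$class == "DEMOGRAPHICS"], 0L)
  # zero-support class excluded from the macro mean
  expect_equal(m$macro$F1, 2 / 3)
  # perfect predictions
  p <- score(y_true, y_true)
  expect_equal(p$macro$F1, 1)
  expect_equal(p$micro$F1, 1)
  expect_error(score(c("PK", "PK"), "PK"), "length mismatch")
})

test_that("score equals the brute-force confusion-matrix oracle", {
  set.seed(43)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    y_true <- sample(PK_LABELS, n, replace = TRUE)
    y_pred <- sample(PK_LABELS, n, replace = TRUE)
    m <- score(y_true, y_pred)
    o <- oracle_metrics(y_true, y_pred)
    expect_equal(unname(m$confusion), unname(o$confusion))
    expect_equal(m$per_class$precision, o$precision)
    expect_equal(m$per_class$recall, o$recall)
    expect_equal(m$per_class$f1, o$f1)
    expect_equal(m$macro$F1, o$macro_f1)
    expect_equal(m$micro$F1, o$micro_f1)
    # micro P = R = F1 = accuracy in single-label multiclass
    expect_equal(m$micro$P, mean(y_true == y_pred))
    expect_equal(m$micro$R, m$micro$P)
    # confusion row sums = supports
    expect_equal(unname(rowSums(m$confusion)),
                 as.numeric(m$per_class$support))
  }
})

test_that("cohens_kappa matches hand arithmetic and its invariants", {
  # perfect agreement with >= 2 distinct labels
  a <- c("PK", "OTHER", "PK", "DEMOGRAPHICS")
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  # chance-level: construct observed agreement equal to chance agreement
  a2 <- c("PK", "PK", "OTHER", "OTHER")
  b2 <- c("PK", "OTHER", "PK", "OTHER")
  k2 <- cohens_kappa(a2, b2)
  expect_equal(k2$p_o, 0.5)
  expect_equal(k2$p_e, 0.5)
  expect_equal(k2$kappa, 0)

  # worked example: n = 100, 80 agreements, marginals (.4,.3,.3)/(.5,.25,.25)
  # contingency table (rows annotator A, cols annotator B):
  #   PK   40  0  0
  #   DEMO  1 22  7
  #   OTHER 9  3 18
  counts <- matrix(c(40, 0, 0, 1, 22, 7, 9, 3, 18), 3, 3, byrow = TRUE)
  a3 <- rep(PK_LABELS, rowSums(counts))
  b3 <- unlist(lapply(1:3, function(r) rep(PK_LABELS, counts[r, ])))
  expect_equal(mean(a3 == b3), 0.8)
  k3 <- cohens_kappa(a3, b3)
  expect_equal(k3$p_e, 0.35, tolerance = 1e-12)
  expect_equal(k3$kappa, (0.8 - 0.35) / 0.65, tolerance = 1e-12)

  # symmetry and relabeling invariance
  set.seed(44)
  for (i in 1:50) {
    x <- sample(PK_LABELS, 30, replace = TRUE)
    y <- sample(PK_LABELS, 30, replace = TRUE)
    expect_equal(cohens_kappa(x, y)$kappa, cohens_kappa(y, x)$kappa)
    perm <- setNames(sample(PK_LABELS), PK_LABELS)
    expect_equal(cohens_kappa(perm[x], perm[y])$kappa,
                 cohens_kappa(x, y)$kappa)
  }

  # degenerate single-category case
  expect_equal(cohens_kappa(rep("PK", 5), rep("PK", 5))$kappa, 1)
})

test_that("write_metrics emits a JSON report", {
  m <- score(c("PK", "OTHER"), c("PK", "OTHER"))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, path, kappa = cohens_kappa(c("PK", "OTHER"),
                                              c("PK", "OTHER")))
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$macro$F1, 1)
  expect_equal(rep$kappa$kappa, 1)
})
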