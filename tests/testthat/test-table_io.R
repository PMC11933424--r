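test_that("parse_article_tables extracts all four fields from a table-wrap", {
  xml <- paste0(
    '<article><body><table-wrap id="tw1">',
    "<caption><p>PK parameters</p></caption>",
    "<table><thead><tr><th>Parameter</th><th>Value</th></tr></thead>",
    "<tbody><tr><td>CL</td><td>5.1</td></tr>",
    "<tr><td>AUC</td><td>9.2</td></tr></tbody></table>",
    "<table-wrap-foot><p>CL, clearance</p></table-wrap-foot>",
    "</table-wrap></body></article>")
  tables <- parse_article_tables(xml)
  expect_length(tables, 1)
  t1 <- tables[[1]]
  expect_equal(t1$table_id, "tw1")
  expect_equal(t1$caption, "PK parameters")
  expect_equal(t1$header_rows, list(c("Parameter", "Value")))
  expect_equal(t1$body, list(c("CL", "5.1"), c("AUC", "9.2")))
  expect_equal(t1$footer, "CL, clearance")
})

test_that("image-only table-wraps are excluded; no table-wraps gives empty list", {
  img <- paste0(
    '<article xmlns:xlink="http://www.w3.org/1999/xlink"><body>',
    '<table-wrap><caption><p>figure table</p></caption>',
    '<graphic xlink:href="t1.jpg"/></table-wrap></body></article>')
  expect_length(parse_article_tables(img), 0)
  expect_length(parse_article_tables("<article><body/></article>"), 0)
})

test_that("cell text is flattened: inline markup collapsed to single-space text", {
  xml <- paste0(
    "<article><body><table-wrap><table><tbody>",
    "<tr><td>C<sub>max</sub>  \n (ng/mL)</td></tr>",
    "</tbody></table></table-wrap></body></article>")
  tables <- parse_article_tables(xml)
  expect_equal(tables[[1]]$body, list("Cmax (ng/mL)"))
})

test_that("table-wrap with rows but no cells is skipped with a warning", {
  xml <- paste0("<article><body><table-wrap><table><tbody><tr/></tbody>",
                "</table></table-wrap></body></article>")
  expect_warning(tables <- parse_article_tables(xml), "no cells")
  expect_length(tables, 0)
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_article_tables("<article><body>"), "malformed XML")
})

test_that("normalize_grid expands spans and pads ragged rows", {
  # colspan replication
  expect_equal(
    normalize_grid(list(list(list(text = "A", colspan = 2),
                             list(text = "B")))),
    list(c("A", "A", "B")))
  # ragged rows right-padded
  expect_equal(
    normalize_grid(list(list(list(text = "a"), list(text = "b"),
                             list(text = "c")),
                        list(list(text = "x"), list(text = "y")))),
    list(c("a", "b", "c"), c("x", "y", "")))
  # rowspan: hand-expanded 2x2 oracle, column 0 becomes [A, A]
  g <- normalize_grid(list(list(list(text = "A", rowspan = 2),
                                list(text = "x")),
                           list(list(text = "y"))))
  expect_equal(g, list(c("A", "x"), c("A", "y")))
})

test_that("overlapping spans raise an error naming the position", {
  raw <- list(
    list(list(text = "A", rowspan = 2), list(text = "B")),
    list(list(text = "C", colspan = 2)))  # C wants columns 2-3 via skip; ok
  expect_silent(normalize_grid(raw))
  bad <- list(
    list(list(text = "A"), list(text = "B", rowspan = 2)),
    list(list(text = "C", colspan = 2)))  # C covers column 2, held by B
  expect_error(normalize_grid(bad), "overlapping spans at row 2, column 2")
})

test_that("randomized colspan fixtures match the hand-expansion oracle", {
  set.seed(42)
  for (trial in 1:50) {
    rows <- lapply(seq_len(sample(1:4, 1)), function(i) {
      lapply(seq_len(sample(1:4, 1)), function(j) {
        list(text = random_text(1), colspan = sample(1:3, 1), rowspan = 1)
      })
    })
    # oracle: replicate texts colspan times, then right-pad
    expanded <- lapply(rows, function(row) {
      unlist(lapply(row, function(c) rep(c$text, c$colspan)))
    })
    width <- max(vapply(expanded, length, integer(1)))
    expected <- lapply(expanded, function(r) c(r, rep("", width - length(r))))
    expect_equal(normalize_grid(rows), expected)
  }
})

test_that("every parsed body grid is rectangular", {
  set.seed(11)
  corpus <- generate_corpus(generator_config(total = 12, seed = 11))
  xml <- generate_jats(corpus$records)
  for (t in parse_article_tables(xml)) {
    widths <- vapply(t$body, length, integer(1))
    expect_length(unique(widths), 1)
  }
})

test_that("corpus JSONL round-trips identically and validates labels", {
  set.seed(5)
  records <- lapply(1:20, function(i) random_table(sprintf("id-%03d", i)))
  corpus <- pk_corpus(records)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  expect_identical(read_corpus(path)$records, corpus$records)

  # lowercase labels are normalized
  line <- paste0('{"table_id":"a","article_id":"","caption":"c",',
                 '"header_rows":[],"body":[["x"]],"footer":"","label":"pk"}')
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(line, p2)
  expect_equal(read_corpus(p2)$records[[1]]$label, "PK")

  # unknown label lists the allowed set
  writeLines(sub('"pk"', '"misc"', line), p2)
  expect_error(read_corpus(p2), "PK, DEMOGRAPHICS, OTHER")

  # missing body names the field
  writeLines(paste0('{"table_id":"a","article_id":"","caption":"c",',
                    '"header_rows":[],"footer":""}'), p2)
  expect_error(read_corpus(p2), "body")

  # duplicate ids rejected
  writeLines(c(line, line), p2)
  expect_error(read_corpus(p2), "duplicate table_id")
})

test_that("Zenodo adapter maps alternative key spellings", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0(
    '{"tab_id":"z1","pmid":"123","title":"Baseline data",',
    '"header":["a","b"],"rows":[["1","2"]],"foot":"note","class":"other"}'),
    path)
  corpus <- read_pktc_zenodo(path)
  t1 <- corpus$records[[1]]
  expect_equal(t1$table_id, "z1")
  expect_equal(t1$caption, "Baseline data")
  expect_equal(t1$header_rows, list(c("a", "b")))
  expect_equal(t1$label, "OTHER")
  writeLines('{"something":"else"}', path)
  expect_error(read_pktc_zenodo(path), "cannot map record 1")
})
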