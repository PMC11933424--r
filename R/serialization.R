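#' Table field variants used as classifier input
#'
#' Seven text views of a table, trading signal against noise: the caption
#' alone, the first header row, the concatenated first column, the first few
#' rows, the whole table in markdown, the footer, and the concatenation of
#' caption and whole table (the best-performing combination).
#'
#' @format Character vector of the seven field kinds.
#' @export
FIELD_KINDS <- c("CAPTION", "HEADER_ROW", "FIRST_COLUMN", "FIRST_FEW_ROWS",
                 "TABLE", "FOOTER", "CAPTION_PLUS_TABLE")

escape_md <- function(cells, escape_pipes = TRUE) {
  if (escape_pipes) gsub("|", "\\|", cells, fixed = TRUE) else cells
}

md_row <- function(cells, escape_pipes = TRUE) {
  paste0("| ", paste(escape_md(cells, escape_pipes), collapse = " | "), " |")
}

#' Serialize a table to pipe-delimited markdown
#'
#' Emits the first header row, a `| --- |` separator row, then the body rows
#' in order, one line each. Literal pipes inside cells are escaped as `\|`.
#' A table with no header rows yields its body rows only, with no separator;
#' an entirely empty table yields `""`.
#'
#' @param table a [pk_table].
#' @param escape_pipes escape literal `|` inside cells (default `TRUE`).
#' @return single markdown string, rows joined by `"\n"`.
#' @export
to_markdown <- function(table, escape_pipes = TRUE) {
  lines <- character(0)
  if (length(table$header_rows) > 0L) {
    hdr <- table$header_rows[[1L]]
    lines <- c(md_row(hdr, escape_pipes),
               md_row(rep("---", length(hdr)), escape_pipes = FALSE))
  }
  lines <- c(lines, vapply(table$body, md_row, character(1),
                           escape_pipes = escape_pipes))
  paste(lines, collapse = "\n")
}

#' Extract one field variant of a table as text
#'
#' @param table a [pk_table].
#' @param kind one of [FIELD_KINDS].
#' @param first_few_rows_k number of body rows used by `FIRST_FEW_ROWS`
#'   (default 3).
#' @param escape_pipes passed to [to_markdown()].
#' @return single character string (possibly `""`).
#' @details
#' * `CAPTION` — the caption text.
#' * `HEADER_ROW` — the first header row as one markdown row.
#' * `FIRST_COLUMN` — column-0 cells of the first header row and every body
#'   row, joined by single spaces (empty cells dropped).
#' * `FIRST_FEW_ROWS` — first header row, separator, and the first
#'   `first_few_rows_k` body rows in markdown.
#' * `TABLE` — the full markdown serialization.
#' * `FOOTER` — the footer text.
#' * `CAPTION_PLUS_TABLE` — caption, newline, full markdown; the `TABLE`
#'   serialization is always a suffix of this variant.
#' @export
select_field <- function(table, kind, first_few_rows_k = 3L,
                         escape_pipes = TRUE) {
  kind <- match.arg(kind, FIELD_KINDS)
  switch(kind,
    CAPTION = table$caption,
    HEADER_ROW = if (length(table$header_rows) > 0L)
      md_row(table$header_rows[[1L]], escape_pipes) else "",
    FIRST_COLUMN = {
      cells <- character(0)
      if (length(table$header_rows) > 0L) {
        cells <- table$header_rows[[1L]][1L]
      }
      cells <- c(cells, vapply(table$body, `[`, character(1), 1L))
      paste(cells[nzchar(cells)], collapse = " ")
    },
    FIRST_FEW_ROWS = {
      k <- min(as.integer(first_few_rows_k), length(table$body))
      trunc <- table
      trunc$body <- if (k > 0L) table$body[seq_len(k)] else list()
      to_markdown(trunc, escape_pipes)
    },
    TABLE = to_markdown(table, escape_pipes),
    FOOTER = table$footer,
    CAPTION_PLUS_TABLE = paste0(table$caption, "\n",
                                to_markdown(table, escape_pipes)))
}
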