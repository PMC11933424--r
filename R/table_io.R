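#' Structured table record
#'
#' The unit record of the pipeline: one table lifted out of a full-text
#' article, with its caption, header rows, rectangular body grid and footer.
#' Cell text is plain text (inline markup already flattened); the body grid
#' is rectangular by construction — every row has the same number of columns.
#'
#' @param table_id unique identifier within a corpus file.
#' @param article_id PMC/PMID of the source article; may be `""` for
#'   synthetic fixtures.
#' @param caption caption text (`""` if absent, never `NULL`).
#' @param header_rows list of character vectors, one per header row.
#' @param body list of character vectors, one per body row; must be
#'   rectangular.
#' @param footer footer text (`""` if absent).
#' @param label optional gold label in [PK_LABELS] (case-insensitive).
#' @return object of class `pk_table`.
#' @export
pk_table <- function(table_id, article_id = "", caption = "",
                     header_rows = list(), body = list(), footer = "",
                     label = NULL) {
  stopifnot(is.character(table_id), length(table_id) == 1L)
  header_rows <- lapply(header_rows, as.character)
  body <- lapply(body, as.character)
  widths <- vapply(body, length, integer(1))
  if (length(widths) > 0L && length(unique(widths)) != 1L) {
    stop("body grid is not rectangular: row widths ",
         paste(widths, collapse = ", "), call. = FALSE)
  }
  if (!is.null(label)) label <- normalize_label(label)
  structure(
    list(table_id = table_id,
         article_id = as.character(article_id),
         caption = as.character(caption),
         header_rows = header_rows,
         body = body,
         footer = as.character(footer),
         label = label),
    class = "pk_table")
}

#' @export
print.pk_table <- function(x, ...) {
  cat(sprintf("<pk_table %s> %d header row(s), %d x %d body%s\n",
              x$table_id, length(x$header_rows), length(x$body),
              if (length(x$body)) length(x$body[[1]]) else 0L,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  if (nzchar(x$caption)) cat("  caption: ", x$caption, "\n", sep = "")
  invisible(x)
}

#' Table corpus
#'
#' A list of [pk_table] records; labeled corpora carry gold labels drawn
#' exclusively from [PK_LABELS].
#'
#' @param records list of `pk_table` objects with unique `table_id`s.
#' @return object of class `pk_corpus`.
#' @export
pk_corpus <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "pk_table")))
  ids <- vapply(records, `[[`, character(1), "table_id")
  if (anyDuplicated(ids)) {
    stop("duplicate table_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(records = records), class = "pk_corpus")
}

#' @export
length.pk_corpus <- function(x) length(x$records)

#' @export
print.pk_corpus <- function(x, ...) {
  labs <- corpus_labels(x)
  cat(sprintf("<pk_corpus> %d tables", length(x$records)))
  if (!any(is.na(labs))) {
    tab <- table(factor(labs, levels = PK_LABELS))
    cat(" (", paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Gold labels of a corpus
#'
#' @param corpus a [pk_corpus].
#' @return character vector (NA for unlabeled records).
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$records,
         function(r) if (is.null(r$label)) NA_character_ else r$label,
         character(1))
}

# ---- grid normalization -----------------------------------------------------

#' Expand row/column spans into a rectangular grid
#'
#' JATS table rows carry `rowspan`/`colspan` attributes; downstream markdown
#' serialization presupposes a rectangle. Spanned cells are replicated into
#' every covered grid position, and ragged rows are right-padded with empty
#' strings.
#'
#' @param raw_rows list of rows; each row is a list of cells, each cell a
#'   list with elements `text`, `rowspan`, `colspan` (spans default to 1).
#' @return list of character vectors, all the same length.
#' @export
normalize_grid <- function(raw_rows) {
  n_rows <- length(raw_rows)
  if (n_rows == 0L) return(list())
  grid <- list()        # row -> character vector (grown on demand)
  taken <- list()       # row -> logical occupancy
  put <- function(r, c, text) {
    while (length(grid) < r) {
      grid[[length(grid) + 1L]] <<- character(0)
      taken[[length(taken) + 1L]] <<- logical(0)
    }
    if (length(grid[[r]]) < c) {
      grid[[r]][(length(grid[[r]]) + 1L):c] <<- ""
      taken[[r]][(length(taken[[r]]) + 1L):c] <<- FALSE
    }
    if (taken[[r]][c]) {
      stop(sprintf("overlapping spans at row %d, column %d", r, c),
           call. = FALSE)
    }
    grid[[r]][c] <<- text
    taken[[r]][c] <<- TRUE
  }
  occupied <- function(r, c) {
    r <= length(taken) && c <= length(taken[[r]]) && taken[[r]][c]
  }
  for (i in seq_len(n_rows)) {
    col <- 1L
    for (cell in raw_rows[[i]]) {
      text <- as.character(cell$text %||% "")
      rs <- as.integer(cell$rowspan %||% 1L)
      cs <- as.integer(cell$colspan %||% 1L)
      stopifnot(rs >= 1L, cs >= 1L)
      while (occupied(i, col)) col <- col + 1L
      for (dr in seq_len(rs) - 1L) {
        for (dc in seq_len(cs) - 1L) put(i + dr, col + dc, text)
      }
      col <- col + cs
    }
  }
  width <- max(vapply(grid, length, integer(1)))
  lapply(grid, function(row) {
    if (length(row) < width) row[(length(row) + 1L):width] <- ""
    row
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- JATS parsing -----------------------------------------------------------

collapse_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

cell_text <- function(node) collapse_ws(xml2::xml_text(node))

# All rows under a node, as raw cells with span attributes.
raw_rows_of <- function(node) {
  trs <- xml2::xml_find_all(node, ".//*[local-name()='tr']")
  lapply(trs, function(tr) {
    cells <- xml2::xml_find_all(
      tr, "./*[local-name()='td' or local-name()='th']")
    span <- function(cell, which) {
      v <- suppressWarnings(as.integer(xml2::xml_attr(cell, which)))
      if (is.na(v)) 1L else v
    }
    lapply(cells, function(cell) {
      list(text = cell_text(cell),
           rowspan = span(cell, "rowspan"),
           colspan = span(cell, "colspan"))
    })
  })
}

#' Parse JATS article XML into structured tables
#'
#' Targets `table-wrap` containers as distributed by the PMC Open Access
#' subset: label/caption, a `table` with `thead`/`tbody` rows, and a
#' `table-wrap-foot`. Table-wraps whose only content is a graphic/image
#' reference (tables published as images) are skipped, as are wraps with
#' rows but no cells (a warning is raised for the latter). Row/column spans
#' are expanded so every returned body grid is rectangular.
#'
#' @param jats_document JATS XML, as a string or an `xml_document`.
#' @return list of [pk_table] records, in document order.
#' @export
parse_article_tables <- function(jats_document) {
  doc <- if (inherits(jats_document, "xml_document")) jats_document else {
    tryCatch(xml2::read_xml(jats_document),
             error = function(e) stop("malformed XML: ", conditionMessage(e),
                                      call. = FALSE))
  }
  art_id <- xml2::xml_find_first(
    doc, ".//*[local-name()='article-id']")
  article_id <- if (inherits(art_id, "xml_missing")) "" else cell_text(art_id)

  wraps <- xml2::xml_find_all(doc, ".//*[local-name()='table-wrap']")
  out <- list()
  for (i in seq_along(wraps)) {
    wrap <- wraps[[i]]
    tbl_node <- xml2::xml_find_first(wrap, ".//*[local-name()='table']")
    has_graphic <- !inherits(
      xml2::xml_find_first(wrap, ".//*[local-name()='graphic']"),
      "xml_missing")
    if (inherits(tbl_node, "xml_missing")) {
      # image-only (or empty) table-wrap: excluded silently
      next
    }
    n_cells <- length(xml2::xml_find_all(
      tbl_node, ".//*[local-name()='td' or local-name()='th']"))
    if (n_cells == 0L) {
      if (length(xml2::xml_find_all(
            tbl_node, ".//*[local-name()='tr']")) > 0L) {
        warning(sprintf("table-wrap %d has rows but no cells; skipped", i),
                call. = FALSE)
      }
      next
    }

    cap_node <- xml2::xml_find_first(wrap, "./*[local-name()='caption']")
    caption <- if (inherits(cap_node, "xml_missing")) "" else
      cell_text(cap_node)
    foot_node <- xml2::xml_find_first(
      wrap, "./*[local-name()='table-wrap-foot']")
    footer <- if (inherits(foot_node, "xml_missing")) "" else
      cell_text(foot_node)

    head_node <- xml2::xml_find_first(tbl_node, ".//*[local-name()='thead']")
    body_node <- xml2::xml_find_first(tbl_node, ".//*[local-name()='tbody']")
    head_raw <- if (inherits(head_node, "xml_missing")) list() else
      raw_rows_of(head_node)
    body_raw <- if (inherits(body_node, "xml_missing")) {
      # tables without an explicit tbody: all rows outside thead are body
      if (inherits(head_node, "xml_missing")) raw_rows_of(tbl_node) else list()
    } else raw_rows_of(body_node)

    # normalize head and body jointly so their column counts agree
    grid <- normalize_grid(c(head_raw, body_raw))
    n_head <- length(head_raw)
    header_rows <- if (n_head > 0L) grid[seq_len(n_head)] else list()
    body <- if (length(grid) > n_head) grid[(n_head + 1L):length(grid)] else
      list()

    id <- xml2::xml_attr(wrap, "id")
    if (is.na(id) || !nzchar(id)) id <- sprintf("table-%d", i)
    out[[length(out) + 1L]] <- pk_table(
      table_id = id, article_id = article_id, caption = caption,
      header_rows = header_rows, body = body, footer = footer)
  }
  out
}

# ---- JSONL corpus I/O -------------------------------------------------------

required_fields <- c("table_id", "article_id", "caption", "header_rows",
                     "body", "footer")

record_to_json <- function(r) {
  obj <- list(
    table_id = r$table_id,
    article_id = r$article_id,
    caption = r$caption,
    header_rows = lapply(r$header_rows, function(row) I(as.list(row))),
    body = lapply(r$body, function(row) I(as.list(row))),
    footer = r$footer)
  if (!is.null(r$label)) obj$label <- r$label
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

json_to_record <- function(line, lineno) {
  obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  missing <- setdiff(required_fields, names(obj))
  if (length(missing)) {
    stop(sprintf("corpus record %d is missing field(s): %s", lineno,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- function(x) lapply(x, function(row) unlist(lapply(row, as.character),
                                                    use.names = FALSE) %||%
                               character(0))
  pk_table(table_id = obj$table_id,
           article_id = obj$article_id,
           caption = obj$caption,
           header_rows = rows(obj$header_rows),
           body = rows(obj$body),
           footer = obj$footer,
           label = obj$label)
}

#' Read a JSONL table corpus
#'
#' One JSON object per line with keys `table_id`, `article_id`, `caption`,
#' `header_rows`, `body`, `footer` and optionally `label`. Labels are
#' normalized case-insensitively to [PK_LABELS]; unknown labels and
#' duplicate `table_id`s are errors.
#'
#' @param path path to a JSONL file.
#' @return a [pk_corpus].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(seq_along(lines),
                    function(i) json_to_record(lines[[i]], i))
  pk_corpus(records)
}

#' Write a JSONL table corpus
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` field-for-field.
#'
#' @param corpus a [pk_corpus].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "pk_corpus"))
  lines <- vapply(corpus$records, record_to_json, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a PKTC-style Zenodo release file (adapter)
#'
#' Best-effort adapter mapping an external labeled-table release onto the
#' package's corpus schema. The release schema is not fixed by this package;
#' the adapter accepts JSONL records and maps common key spellings
#' (`tab_id`/`id` for `table_id`, `pmid`/`pmcid` for `article_id`,
#' `foot`/`footnote` for `footer`). Records it cannot map raise an error
#' naming the record and the keys found, so the mapping can be extended
#' against the actual files.
#'
#' @param path path to a JSONL file from the external release.
#' @return a [pk_corpus].
#' @export
read_pktc_zenodo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  alias <- list(table_id = c("table_id", "tab_id", "id"),
                article_id = c("article_id", "pmid", "pmcid", "pmc"),
                caption = c("caption", "title"),
                header_rows = c("header_rows", "header", "headers"),
                body = c("body", "rows", "table"),
                footer = c("footer", "foot", "footnote"),
                label = c("label", "class", "category"))
  pick <- function(obj, keys) {
    hit <- intersect(keys, names(obj))
    if (length(hit)) obj[[hit[[1L]]]] else NULL
  }
  records <- lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    got <- lapply(alias, pick, obj = obj)
    if (is.null(got$table_id)) got$table_id <- sprintf("zenodo-%d", i)
    if (is.null(got$body)) {
      stop(sprintf(
        "cannot map record %d onto the corpus schema; keys found: %s", i,
        paste(names(obj), collapse = ", ")), call. = FALSE)
    }
    rows <- function(x) {
      if (is.null(x)) return(list())
      lapply(x, function(row) unlist(lapply(row, as.character),
                                     use.names = FALSE) %||% character(0))
    }
    hdr <- got$header_rows
    if (!is.null(hdr) && length(hdr) && !is.list(hdr[[1L]])) hdr <- list(hdr)
    pk_table(table_id = as.character(got$table_id),
             article_id = as.character(got$article_id %||% ""),
             caption = as.character(got$caption %||% ""),
             header_rows = rows(hdr),
             body = rows(got$body),
             footer = as.character(got$footer %||% ""),
             label = got$label)
  })
  pk_corpus(records)
}
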