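# Synthetic corpus generator. Emulates the decision-relevant features of
# tables in PK literature: PK-parameter tables (parameter names, value +/- SD
# cells, units), demographics tables (age/weight/sex/BMI), and "other" tables
# including the hard negative of concentration-time measurements that carry
# concentration units but no derived parameter names.

pk_lexicon <- function() {
  list(
    params = c("CL", "Vd", "AUC", "Cmax", "Tmax", "t1/2", "ka", "MRT",
               "AUC0-t", "Vss"),
    units = c("mL/min", "L", "ng.h/mL", "ng/mL", "h", "1/h", "L/kg"),
    caption_words = c("Pharmacokinetic", "parameters", "estimates",
                      "noncompartmental", "oral", "intravenous", "dose"),
    footer_words = c("CL, clearance;", "AUC, area under the curve;",
                     "Cmax, peak concentration;", "t1/2, half-life."))
}

demo_lexicon <- function() {
  list(
    rows = c("Age", "Weight", "Height", "BMI", "Sex", "Ethnicity",
             "Creatinine", "Albumin"),
    units = c("years", "kg", "cm", "kg/m2", "male/female", "g/dL"),
    caption_words = c("Baseline", "characteristics", "demographics",
                      "study", "population", "subjects", "patients"),
    footer_words = c("Values are mean (range).", "BMI, body mass index."))
}

other_lexicons <- function() {
  list(
    adverse = list(
      rows = c("Headache", "Nausea", "Dizziness", "Rash", "Fatigue",
               "Vomiting", "Diarrhea"),
      units = c("n (%)", "events", "grade"),
      caption_words = c("Adverse", "events", "treatment", "emergent",
                        "safety", "placebo"),
      footer_words = c("Events coded by MedDRA preferred term.")),
    invitro = list(
      rows = c("Inhibition", "Viability", "Binding", "Permeability",
               "Solubility", "Stability"),
      units = c("percent", "ratio", "score"),
      caption_words = c("In", "vitro", "assay", "results", "cell",
                        "culture"),
      footer_words = c("Assays performed in triplicate.")),
    conc = list(
      # hard negative: concentration units, no parameter-name tokens
      rows = c("0.5", "1", "2", "4", "8", "12", "24"),
      units = c("ng/mL", "ug/mL"),
      caption_words = c("Plasma", "concentration", "time", "profiles",
                        "individual", "measurements"),
      footer_words = c("Samples below the limit of quantification omitted.")))
}

all_class_tokens <- function() {
  list(PK = unique(unlist(pk_lexicon()[c("params", "caption_words")])),
       DEMOGRAPHICS = unique(unlist(demo_lexicon()[c("rows",
                                                     "caption_words")])),
       OTHER = unique(unlist(lapply(other_lexicons(), function(l)
         c(l$rows, l$caption_words)))))
}

maybe_noise <- function(tokens, label, noise) {
  if (noise <= 0) return(tokens)
  pools <- all_class_tokens()
  cross <- unlist(pools[setdiff(names(pools), label)], use.names = FALSE)
  hit <- stats::runif(length(tokens)) < noise
  if (any(hit)) {
    tokens[hit] <- sample(cross, sum(hit), replace = TRUE)
  }
  tokens
}

value_sd_cell <- function() {
  sprintf("%.2f +/- %.2f", stats::runif(1, 0.1, 120), stats::runif(1, 0.01, 15))
}

#' Generator configuration for the synthetic corpus
#'
#' Defaults state the emulated world: class proportions follow the training
#' split of the motivating corpus (532 PK : 233 demographics : 819 other),
#' lexical noise is off, and no table exceeds the 512-token chunking limit
#' unless `long_rate` says so.
#'
#' @param total total number of tables (used with `proportions`).
#' @param proportions relative class sizes in [PK_LABELS] order.
#' @param n_per_class optional explicit per-class counts (overrides
#'   `total`/`proportions`).
#' @param noise probability that a class-typical token is replaced by a
#'   token from another class's lexicon (0 = lexically disjoint classes).
#' @param long_rate fraction of tables padded past 512 whitespace tokens.
#' @param seed integer seed; generation is a pure function of this config.
#' @return object of class `pk_generator_config`.
#' @export
generator_config <- function(total = 600L, proportions = c(532, 233, 819),
                             n_per_class = NULL, noise = 0, long_rate = 0,
                             seed = 1L) {
  stopifnot(noise >= 0, noise <= 1, long_rate >= 0, long_rate <= 1)
  structure(list(total = as.integer(total),
                 proportions = proportions,
                 n_per_class = n_per_class,
                 noise = noise, long_rate = long_rate,
                 seed = as.integer(seed)),
            class = "pk_generator_config")
}

#' Generate one labeled synthetic table
#'
#' Draws from the current RNG state (seed it, or use [generate_corpus()]
#' which seeds from its config). `PK` tables carry parameter-name rows with
#' value +/- SD cells and units; `DEMOGRAPHICS` tables carry
#' age/weight/sex/BMI rows; `OTHER` tables use one of three templates —
#' adverse events, in vitro assay, or concentration-time measurements
#' without derived parameters (the hard negative sharing units with PK
#' tables but no parameter names).
#'
#' @param label one of [PK_LABELS].
#' @param config a [generator_config()].
#' @param table_id identifier for the record.
#' @param long force long-table padding (default: off).
#' @return a labeled [pk_table].
#' @export
generate_table <- function(label, config = generator_config(),
                           table_id = "tbl-1", long = FALSE) {
  label <- normalize_label(label)
  noise <- config$noise
  n_rows <- sample(3:8, 1L)
  if (label == "PK") {
    lex <- pk_lexicon()
    cap <- c(sample(lex$caption_words, 3L),
             sample(lex$params, 2L))
    header <- c("Parameter", "Unit", "Estimate")
    rows <- lapply(seq_len(n_rows), function(i) {
      c(maybe_noise(sample(lex$params, 1L), label, noise),
        sample(lex$units, 1L),
        value_sd_cell())
    })
    footer <- paste(sample(lex$footer_words, 2L), collapse = " ")
  } else if (label == "DEMOGRAPHICS") {
    lex <- demo_lexicon()
    cap <- sample(lex$caption_words, 4L)
    header <- c("Characteristic", "Unit", "Value")
    rows <- lapply(seq_len(n_rows), function(i) {
      c(maybe_noise(sample(lex$rows, 1L), label, noise),
        sample(lex$units, 1L),
        value_sd_cell())
    })
    footer <- sample(lex$footer_words, 1L)
  } else {
    tmpl <- sample(names(other_lexicons()), 1L)
    lex <- other_lexicons()[[tmpl]]
    cap <- sample(lex$caption_words, 4L)
    header <- if (tmpl == "conc") c("Time", "Concentration", "Unit") else
      c("Item", "Measure", "Unit")
    rows <- lapply(seq_len(n_rows), function(i) {
      if (tmpl == "conc") {
        c(sample(lex$rows, 1L), sprintf("%.2f", stats::runif(1, 0.1, 500)),
          sample(lex$units, 1L))
      } else {
        c(maybe_noise(sample(lex$rows, 1L), label, noise),
          value_sd_cell(), sample(lex$units, 1L))
      }
    })
    footer <- sample(lex$footer_words, 1L)
  }
  caption <- paste(maybe_noise(cap, label, noise), collapse = " ")
  tbl <- pk_table(table_id = table_id, article_id = "",
                  caption = caption,
                  header_rows = list(header), body = rows, footer = footer,
                  label = label)
  if (long) tbl <- pad_long(tbl)
  tbl
}

# Pad with subject rows until the full markdown exceeds 512 whitespace tokens.
pad_long <- function(tbl) {
  n_tokens <- function(t) {
    toks <- strsplit(select_field(t, "TABLE"), "[[:space:]]+")[[1L]]
    length(toks[nzchar(toks)])
  }
  width <- length(tbl$body[[1L]])
  i <- 0L
  while (n_tokens(tbl) <= 512L) {
    i <- i + 1L
    row <- c(sprintf("Subject %d", i),
             vapply(seq_len(width - 1L),
                    function(j) sprintf("%.2f", stats::runif(1, 0.1, 99)),
                    character(1)))
    tbl$body[[length(tbl$body) + 1L]] <- row
  }
  tbl
}

#' Generate a labeled synthetic corpus
#'
#' Class counts follow `n_per_class` if given, otherwise largest-remainder
#' allocation of `total` over `proportions`. Tables are generated and
#' shuffled deterministically from `config$seed`; `long_rate` marks a
#' deterministic fraction of tables for padding past 512 tokens.
#'
#' @param config a [generator_config()].
#' @return a labeled [pk_corpus].
#' @export
generate_corpus <- function(config = generator_config()) {
  counts <- if (!is.null(config$n_per_class)) {
    as.integer(config$n_per_class)
  } else {
    largest_remainder(config$total,
                      config$proportions / sum(config$proportions))
  }
  names(counts) <- PK_LABELS
  set.seed(config$seed)
  labels <- rep(PK_LABELS, counts)
  n <- length(labels)
  n_long <- round(config$long_rate * n)
  long_flags <- rep(FALSE, n)
  if (n_long > 0L) long_flags[sample(n, n_long)] <- TRUE
  records <- lapply(seq_len(n), function(i) {
    generate_table(labels[i], config,
                   table_id = sprintf("tbl-%04d", i),
                   long = long_flags[i])
  })
  pk_corpus(records[sample(n)])
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render tables as a JATS article document
#'
#' Wraps each table in a `table-wrap` (label, caption, `thead`/`tbody`,
#' `table-wrap-foot`), optionally appending graphic-only table-wraps that a
#' parser must exclude. Round-trips through [parse_article_tables()] to
#' exactly the non-image tables with byte-equal captions and footers.
#'
#' @param tables list of [pk_table] records.
#' @param include_image_only number of image-only table-wraps to add.
#' @param article_id article identifier written into the front matter.
#' @return JATS XML as a single string.
#' @export
generate_jats <- function(tables, include_image_only = 0L,
                          article_id = "PMC0000001") {
  wrap_one <- function(tbl, i) {
    rows_xml <- function(rows, cell_tag) {
      paste(vapply(rows, function(row) {
        paste0("<tr>",
               paste0("<", cell_tag, ">", xml_escape(row),
                      "</", cell_tag, ">", collapse = ""),
               "</tr>")
      }, character(1)), collapse = "")
    }
    head_xml <- if (length(tbl$header_rows))
      paste0("<thead>", rows_xml(tbl$header_rows, "th"), "</thead>") else ""
    body_xml <- if (length(tbl$body))
      paste0("<tbody>", rows_xml(tbl$body, "td"), "</tbody>") else ""
    foot_xml <- if (nzchar(tbl$footer))
      paste0("<table-wrap-foot><p>", xml_escape(tbl$footer),
             "</p></table-wrap-foot>") else ""
    paste0('<table-wrap id="', xml_escape(tbl$table_id), '">',
           "<label>Table ", i, "</label>",
           "<caption><p>", xml_escape(tbl$caption), "</p></caption>",
           "<table>", head_xml, body_xml, "</table>",
           foot_xml,
           "</table-wrap>")
  }
  image_wrap <- function(i) {
    paste0('<table-wrap id="img-', i, '">',
           "<label>Table ", i, "</label>",
           "<caption><p>Table available as image only</p></caption>",
           '<graphic xlink:href="table', i, '.jpg"/>',
           "</table-wrap>")
  }
  wraps <- c(
    vapply(seq_along(tables), function(i) wrap_one(tables[[i]], i),
           character(1)),
    vapply(seq_len(include_image_only),
           function(i) image_wrap(length(tables) + i), character(1)))
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<article xmlns:xlink="http://www.w3.org/1999/xlink">',
         "<front><article-meta>",
         '<article-id pub-id-type="pmc">', xml_escape(article_id),
         "</article-id>",
         "</article-meta></front><body>",
         paste(wraps, collapse = ""),
         "</body></article>")
}
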