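# Zero-shot chain-of-thought classification behind an abstract LLM backend.
# The prompt wording is configuration (an editable asset file with named
# slots), not code; tests use deterministic mock backends only.

#' Load the zero-shot prompt template
#'
#' The template is a plain-text asset with slots `{caption}`,
#' `{table_markdown}` and `{footer}`. It must mention all three class labels
#' and the final-answer directive `ANSWER:` so responses are parseable.
#'
#' @param path optional path to a custom template; default is the asset
#'   shipped with the package.
#' @return single string of class `pk_prompt_template`.
#' @export
load_prompt_template <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("templates", "zero_shot_prompt.txt",
                        package = "pktables", mustWork = TRUE)
  }
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  for (slot in c("{caption}", "{table_markdown}", "{footer}")) {
    if (!grepl(slot, text, fixed = TRUE)) {
      stop("prompt template is missing slot ", slot, call. = FALSE)
    }
  }
  if (!all(vapply(PK_LABELS, grepl, logical(1), x = text, fixed = TRUE)) ||
      !grepl("ANSWER:", text, fixed = TRUE)) {
    stop("prompt template must name all three labels and the ANSWER: directive",
         call. = FALSE)
  }
  structure(text, class = "pk_prompt_template")
}

#' Render the classification prompt for one table
#'
#' Deterministic slot filling: the rendered prompt contains the caption, the
#' markdown-serialized table, the footer, the three label names and the
#' final-answer directive.
#'
#' @param template a [load_prompt_template()] result.
#' @param table a [pk_table].
#' @return prompt text.
#' @export
build_prompt <- function(template, table) {
  stopifnot(inherits(template, "pk_prompt_template"))
  text <- sub("{caption}", table$caption, template, fixed = TRUE)
  text <- sub("{table_markdown}", to_markdown(table), text, fixed = TRUE)
  sub("{footer}", table$footer, text, fixed = TRUE)
}

#' Parse a model response into a label
#'
#' Extracts the last case-insensitive `ANSWER: <label>` directive. A missing
#' directive or an unknown label yields [UNPARSEABLE]; this function never
#' throws.
#'
#' @param response raw model output text.
#' @return one of [PK_LABELS] or [UNPARSEABLE].
#' @export
parse_response <- function(response) {
  if (!is.character(response) || length(response) != 1L || is.na(response)) {
    return(UNPARSEABLE)
  }
  m <- regmatches(response,
                  gregexpr("(?i)ANSWER:\\s*<?([A-Za-z]+)>?", response,
                           perl = TRUE))[[1L]]
  if (length(m) == 0L) return(UNPARSEABLE)
  last <- toupper(sub("(?i)ANSWER:\\s*<?([A-Za-z]+)>?", "\\1",
                      m[length(m)], perl = TRUE))
  if (last %in% PK_LABELS) last else UNPARSEABLE
}

#' LLM backend contract and deterministic mocks
#'
#' A backend is a list with a `name` and a
#' `complete(prompt, table_id = NULL)` function returning response text.
#' Live hosted backends are optional plugins; all tests use mocks:
#' `mock_backend_scripted()` replays fixed responses keyed by table id,
#' `mock_backend_oracle()` answers with the gold label of a labeled corpus,
#' and `mock_backend_constant()` always returns the same text (useful for
#' malformed-output paths).
#'
#' @param name backend name (for logs).
#' @param complete function `(prompt, table_id)` returning text.
#' @return object of class `pk_llm_backend`.
#' @export
llm_backend <- function(name, complete) {
  stopifnot(is.function(complete))
  structure(list(name = name, complete = complete), class = "pk_llm_backend")
}

#' @rdname llm_backend
#' @param responses named character vector, table id -> response text.
#' @param default response for ids not in `responses`.
#' @export
mock_backend_scripted <- function(responses, default = "") {
  llm_backend("mock-scripted", function(prompt, table_id = NULL) {
    if (!is.null(table_id) && table_id %in% names(responses)) {
      responses[[table_id]]
    } else default
  })
}

#' @rdname llm_backend
#' @param corpus a labeled [pk_corpus] whose gold labels the mock replays.
#' @export
mock_backend_oracle <- function(corpus) {
  labels <- stats::setNames(corpus_labels(corpus),
                            vapply(corpus$records, `[[`, character(1),
                                   "table_id"))
  llm_backend("mock-oracle", function(prompt, table_id = NULL) {
    if (is.null(table_id) || !table_id %in% names(labels)) return("")
    paste0("Step-by-step review of the table.\nANSWER: ", labels[[table_id]])
  })
}

#' @rdname llm_backend
#' @param text fixed response text.
#' @export
mock_backend_constant <- function(text) {
  llm_backend("mock-constant", function(prompt, table_id = NULL) text)
}

pk_log <- function(...) {
  if (isTRUE(getOption("pktables.verbose", FALSE))) message(sprintf(...))
}

#' Classify one table zero-shot through a backend
#'
#' Builds the chain-of-thought prompt (the whole table, unchunked — the
#' target models have six-figure context windows), sends it to the backend
#' with a small retry budget, and parses the response. Backend failures
#' after retries degrade to [UNPARSEABLE]; this function never throws on
#' malformed model output. Each call logs the table id, prompt length and
#' outcome when `options(pktables.verbose = TRUE)`.
#'
#' @param backend a `pk_llm_backend`.
#' @param template a [load_prompt_template()] result.
#' @param table a [pk_table].
#' @param retries extra attempts after a backend error (default 2).
#' @return one of [PK_LABELS] or [UNPARSEABLE].
#' @export
classify_zero_shot <- function(backend, template, table, retries = 2L) {
  stopifnot(inherits(backend, "pk_llm_backend"))
  prompt <- build_prompt(template, table)
  response <- NULL
  for (attempt in seq_len(retries + 1L)) {
    response <- tryCatch(backend$complete(prompt, table$table_id),
                         error = function(e) {
                           pk_log("backend %s failed on %s (attempt %d): %s",
                                  backend$name, table$table_id, attempt,
                                  conditionMessage(e))
                           NULL
                         })
    if (!is.null(response)) break
  }
  label <- if (is.null(response)) UNPARSEABLE else parse_response(response)
  pk_log("zero-shot %s: prompt %d chars -> %s", table$table_id,
         nchar(prompt), label)
  label
}
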