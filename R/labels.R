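#' Class labels used throughout the package
#'
#' The pipeline is a fixed three-class problem: tables reporting in vivo
#' pharmacokinetic parameter estimates (`PK`), tables of study population
#' characteristics (`DEMOGRAPHICS`), and everything else (`OTHER`, e.g.
#' adverse events, in vitro assays, raw concentration measurements without
#' derived parameters). The order of this vector is the canonical class
#' order: probability vectors, confusion matrices and argmax tie-breaks all
#' use it.
#'
#' @format Character vector of length 3.
#' @export
PK_LABELS <- c("PK", "DEMOGRAPHICS", "OTHER")

#' Sentinel returned when a fallback response carries no usable label
#' @export
UNPARSEABLE <- "UNPARSEABLE"

#' Normalize a label string to the canonical three-class set
#'
#' Labels are matched case-insensitively ("pk", "Pk" and "PK" are all `PK`).
#'
#' @param x character vector of raw label strings.
#' @return character vector of canonical labels.
#' @export
normalize_label <- function(x) {
  up <- toupper(trimws(x))
  bad <- !(up %in% PK_LABELS)
  if (any(bad)) {
    stop("unknown label(s) ", paste(unique(x[bad]), collapse = ", "),
         "; allowed labels are ", paste(PK_LABELS, collapse = ", "),
         call. = FALSE)
  }
  up
}
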