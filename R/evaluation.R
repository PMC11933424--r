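#' Largest-remainder allocation of n items over fractions
#'
#' Floors the quotas, then hands remaining seats to the largest fractional
#' remainders; ties go to the earlier split. Internal helper, exported for
#' transparency of the split arithmetic.
#'
#' @param n number of items.
#' @param fractions numeric vector summing to 1.
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    # order by remainder descending, earlier split wins ties
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# Core splitter on a label vector: returns split assignment 1..length(fractions)
stratified_split_assign <- function(labels, fractions, seed) {
  assign <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    members <- which(labels == cls)
    if (length(members) < length(fractions)) {
      stop(sprintf("class %s has only %d member(s); cannot split into %d parts",
                   cls, length(members), length(fractions)), call. = FALSE)
    }
    counts <- largest_remainder(length(members), fractions)
    shuffled <- sample(members)
    assign[shuffled] <- rep(seq_along(fractions), counts)
  }
  assign
}

#' Stratified train/validation/test split
#'
#' Within each class, counts are allocated to the splits by
#' largest-remainder rounding of the fractions (ties to the earlier split),
#' and membership is randomized by `seed`. Splits are disjoint, exhaustive,
#' and preserve per-class totals.
#'
#' @param corpus a labeled [pk_corpus].
#' @param fractions split fractions summing to 1 (default 0.6/0.2/0.2).
#' @param seed integer seed.
#' @return list of [pk_corpus] objects, one per fraction.
#' @export
stratified_split <- function(corpus, fractions = c(0.6, 0.2, 0.2),
                             seed = 1L) {
  stopifnot(inherits(corpus, "pk_corpus"))
  labels <- corpus_labels(corpus)
  if (any(is.na(labels))) {
    stop("stratified_split needs a fully labeled corpus", call. = FALSE)
  }
  assign <- stratified_split_assign(labels, fractions, seed)
  lapply(seq_along(fractions), function(s) {
    pk_corpus(corpus$records[assign == s])
  })
}

#' Per-class precision/recall/F1 with macro and micro averages
#'
#' Computes the 3x3 confusion matrix in canonical class order and derives
#' per-class precision, recall and F1 (`F1 = 2PR/(P+R)`, 0 when `P+R = 0`).
#' Macro averages are unweighted means over classes with non-zero support;
#' micro averages come from pooled counts, so micro-P = micro-R = micro-F1 =
#' accuracy for single-label multiclass.
#'
#' @param y_true,y_pred equal-length character vectors of labels in
#'   [PK_LABELS].
#' @return object of class `pk_metrics`: list with `per_class` (data.frame
#'   P/R/F1/support), `macro`, `micro` (named lists P/R/F1), `confusion`
#'   (matrix, rows = true).
#' @export
score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(y_true), length(y_pred)), call. = FALSE)
  }
  y_true <- factor(normalize_label(y_true), levels = PK_LABELS)
  y_pred <- factor(normalize_label(y_pred), levels = PK_LABELS)
  cm <- table(true = y_true, predicted = y_pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted_n <- colSums(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, predicted_n)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = PK_LABELS, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.integer(support))
  present <- support > 0
  macro <- list(P = mean(precision[present]), R = mean(recall[present]),
                F1 = mean(f1[present]))
  acc <- sum(tp) / sum(cm)
  micro <- list(P = acc, R = acc, F1 = acc)
  structure(list(per_class = per_class, macro = macro, micro = micro,
                 confusion = unclass(cm)),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat("<pk_metrics>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("macro P/R/F1: %.4f / %.4f / %.4f   micro F1: %.4f\n",
              x$macro$P, x$macro$R, x$macro$F1, x$micro$F1))
  invisible(x)
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `K = (p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement fraction and `p_e` the chance agreement from the two
#' annotators' marginal label distributions. The degenerate case where both
#' annotators use a single identical category (`p_e = 1`, `p_o = 1`) is
#' defined as `K = 1`.
#'
#' @param labels_a,labels_b equal-length label vectors (any label set).
#' @return list with `p_o`, `p_e`, `kappa`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 1L)
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  classes <- union(labels_a, labels_b)
  marg_a <- vapply(classes, function(c) mean(labels_a == c), numeric(1))
  marg_b <- vapply(classes, function(c) mean(labels_b == c), numeric(1))
  p_e <- sum(marg_a * marg_b)
  kappa <- if (abs(1 - p_e) < 1e-15) {
    if (p_o >= 1 - 1e-15) 1 else NaN
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}

#' Serialize a metrics report to JSON
#'
#' @param metrics a `pk_metrics` object.
#' @param path output path.
#' @param kappa optional [cohens_kappa()] result to embed.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, kappa = NULL) {
  obj <- list(per_class = metrics$per_class,
              macro = metrics$macro, micro = metrics$micro,
              confusion = as.data.frame.matrix(metrics$confusion))
  if (!is.null(kappa)) obj$kappa <- kappa
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
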