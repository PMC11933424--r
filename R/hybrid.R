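# Confidence-gated routing: the boosted classifier answers by default, and
# only predictions whose confidence (max class probability) falls strictly
# below a threshold T are double-checked by the zero-shot fallback.

#' Should a prediction be routed to the fallback?
#'
#' Strict inequality: a prediction with confidence exactly `T` stays with
#' the supervised classifier.
#'
#' @param confidence max class probability of the supervised prediction
#'   (or a one-row prediction data.frame with a `confidence` column).
#' @param threshold routing threshold `T` in `(0, 1]`.
#' @return logical vector.
#' @export
route <- function(confidence, threshold) {
  if (is.data.frame(confidence)) confidence <- confidence$confidence
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  confidence < threshold
}

#' Choose the routing threshold on a validation set
#'
#' For each candidate `T` the trade-off table records the routed fraction
#' (share of predictions with confidence below `T`) and the number of
#' supervised errors captured below `T` — the errors the fallback gets a
#' chance to fix. The chosen `T` maximizes captured errors subject to the
#' routed fraction staying within `max_routed_frac`; if no candidate
#' satisfies the cap, the one with the smallest routed fraction wins.
#' Tied candidates capturing at least one error resolve to the smaller
#' threshold (the cheaper double-check achieving the same correction);
#' when no errors are capturable at all the trade-off data is
#' uninformative and the largest candidate is kept as the conservative
#' default.
#'
#' @param predictions data.frame from [predict.pk_boosted_model()] (needs
#'   `label` and `confidence` columns).
#' @param gold character vector of gold labels, same length.
#' @param candidates candidate thresholds (default 0.85, 0.9, 0.95).
#' @param max_routed_frac cap on the routed fraction (default 0.10).
#' @return list with `threshold` and `tradeoff` (data.frame with columns
#'   `threshold`, `routed_fraction`, `captured_errors`).
#' @export
select_threshold <- function(predictions, gold,
                             candidates = c(0.85, 0.9, 0.95),
                             max_routed_frac = 0.10) {
  stopifnot(length(candidates) >= 1L)
  if (nrow(predictions) == 0L) {
    stop("empty validation set", call. = FALSE)
  }
  stopifnot(nrow(predictions) == length(gold))
  gold <- normalize_label(gold)
  wrong <- predictions$label != gold
  conf <- predictions$confidence
  tradeoff <- data.frame(
    threshold = candidates,
    routed_fraction = vapply(candidates, function(t) mean(conf < t),
                             numeric(1)),
    captured_errors = vapply(candidates, function(t) sum(wrong & conf < t),
                             numeric(1)))
  ok <- tradeoff$routed_fraction <= max_routed_frac
  pool <- if (any(ok)) tradeoff[ok, ] else
    tradeoff[tradeoff$routed_fraction == min(tradeoff$routed_fraction), ]
  best <- pool$threshold[pool$captured_errors == max(pool$captured_errors)]
  chosen <- if (max(pool$captured_errors) > 0) min(best) else max(best)
  list(threshold = chosen, tradeoff = tradeoff)
}

#' Hybrid supervised + zero-shot classification
#'
#' Runs the supervised pipeline on every table, routes low-confidence cases
#' (confidence strictly below `threshold`) to the zero-shot backend, and
#' takes the fallback label when it parses; an [UNPARSEABLE] fallback (or a
#' failing backend) degrades to the supervised label, so the hybrid is
#' total.
#'
#' @param pipeline a trained [train_pipeline()] object (or a bare
#'   `pk_boosted_model` plus pre-featurized tables — see `features`).
#' @param backend a [llm_backend()].
#' @param template a [load_prompt_template()] result.
#' @param tables list of [pk_table] records or a [pk_corpus].
#' @param threshold routing threshold in `(0, 1]`.
#' @return data.frame of routing decisions: `table_id`, supervised
#'   `label`/`confidence`, `routed`, `fallback` (NA when not routed),
#'   `final`, `threshold`.
#' @export
hybrid_classify <- function(pipeline, backend, template, tables, threshold) {
  if (inherits(tables, "pk_corpus")) tables <- tables$records
  preds <- predict_pipeline(pipeline, tables)
  routed <- route(preds$confidence, threshold)
  fallback <- rep(NA_character_, length(tables))
  final <- preds$label
  for (i in which(routed)) {
    fb <- classify_zero_shot(backend, template, tables[[i]])
    fallback[i] <- fb
    if (fb != UNPARSEABLE) final[i] <- fb
  }
  pk_log("hybrid: routed %d/%d tables (%.1f%%) at T=%.2f", sum(routed),
         length(tables), 100 * mean(routed), threshold)
  data.frame(table_id = preds$table_id,
             label = preds$label,
             confidence = preds$confidence,
             routed = routed,
             fallback = fallback,
             final = final,
             threshold = threshold,
             stringsAsFactors = FALSE)
}
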