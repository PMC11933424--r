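# End-to-end pipeline object: a prediction is meaningless without its
# featurization, so the trained artifact bundles the boosted ensemble with
# the vocabulary, the field-selection config and the class order, and is
# persisted as a single versioned JSON file.

PIPELINE_FORMAT_VERSION <- 1L

#' Train the full table-classification pipeline on a labeled corpus
#'
#' Serializes each table with [select_field()] (default: caption + full
#' markdown table, the best-performing variant), fits a bag-of-words
#' vocabulary on the training texts, and trains the class-weighted boosted
#' classifier with early stopping.
#'
#' @param corpus a labeled [pk_corpus].
#' @param field one of [FIELD_KINDS] (default `CAPTION_PLUS_TABLE`).
#' @param hp a [hyperparameters()] object.
#' @param first_few_rows_k body rows used by the `FIRST_FEW_ROWS` field.
#' @param min_df vocabulary minimum document frequency.
#' @param eval_fraction early-stopping holdout fraction.
#' @param seed integer seed.
#' @return object of class `pk_pipeline`.
#' @export
train_pipeline <- function(corpus, field = "CAPTION_PLUS_TABLE",
                           hp = hyperparameters(), first_few_rows_k = 3L,
                           min_df = 1L, eval_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(corpus, "pk_corpus"))
  field <- match.arg(field, FIELD_KINDS)
  labels <- corpus_labels(corpus)
  if (any(is.na(labels))) stop("corpus must be fully labeled", call. = FALSE)
  texts <- vapply(corpus$records, select_field, character(1), kind = field,
                  first_few_rows_k = first_few_rows_k)
  vocab <- fit_vocabulary(texts, min_df = min_df)
  features <- bow_encode_matrix(texts, vocab)
  model <- train_boosted(features, labels, hp = hp,
                         eval_fraction = eval_fraction, seed = seed)
  structure(list(model = model, vocab = vocab, field = field,
                 first_few_rows_k = as.integer(first_few_rows_k),
                 representation = "bow",
                 format_version = PIPELINE_FORMAT_VERSION),
            class = "pk_pipeline")
}

#' @export
print.pk_pipeline <- function(x, ...) {
  cat(sprintf("<pk_pipeline> field %s, %s features (%d terms), %s\n",
              x$field, x$representation, length(x$vocab),
              format(x$model)))
  invisible(x)
}

#' @export
format.pk_boosted_model <- function(x, ...) {
  sprintf("boosted model (best iteration %d)", x$best_iter)
}

pipeline_features <- function(pipeline, tables) {
  texts <- vapply(tables, select_field, character(1), kind = pipeline$field,
                  first_few_rows_k = pipeline$first_few_rows_k)
  bow_encode_matrix(texts, pipeline$vocab)
}

#' Predict labels for tables with a trained pipeline
#'
#' @param pipeline a [train_pipeline()] result.
#' @param tables list of [pk_table] records or a [pk_corpus].
#' @return data.frame: `table_id`, per-class probabilities, `label`,
#'   `confidence`.
#' @export
predict_pipeline <- function(pipeline, tables) {
  stopifnot(inherits(pipeline, "pk_pipeline"))
  if (inherits(tables, "pk_corpus")) tables <- tables$records
  out <- predict(pipeline$model, pipeline_features(pipeline, tables))
  cbind(data.frame(table_id = vapply(tables, `[[`, character(1), "table_id"),
                   stringsAsFactors = FALSE),
        out)
}

#' Persist / restore a trained pipeline
#'
#' Single-file JSON artifact bundling the ensemble (all trees), the
#' vocabulary, the serialization config and the class order, with a format
#' version for forward compatibility. Numeric values are written at full
#' precision, so save/load round-trips predictions exactly.
#'
#' @param pipeline a `pk_pipeline`.
#' @param path output path.
#' @return `path` invisibly (`write_pipeline`); a `pk_pipeline`
#'   (`read_pipeline`).
#' @export
write_pipeline <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "pk_pipeline"))
  m <- pipeline$model
  obj <- list(
    format_version = PIPELINE_FORMAT_VERSION,
    field = pipeline$field,
    first_few_rows_k = pipeline$first_few_rows_k,
    representation = pipeline$representation,
    vocab_terms = names(pipeline$vocab),
    vocab_lowercase = attr(pipeline$vocab, "lowercase"),
    vocab_min_df = attr(pipeline$vocab, "min_df"),
    class_order = m$class_order,
    best_iter = m$best_iter,
    rounds_used = m$rounds_used,
    n_features = m$n_features,
    hp = unclass(m$hp),
    trees = m$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (obj$format_version != PIPELINE_FORMAT_VERSION) {
    stop("unsupported pipeline format version ", obj$format_version,
         call. = FALSE)
  }
  vocab <- structure(stats::setNames(seq_along(obj$vocab_terms) - 1L,
                                     obj$vocab_terms),
                     class = "pk_vocabulary",
                     lowercase = obj$vocab_lowercase,
                     min_df = obj$vocab_min_df)
  trees <- lapply(obj$trees, function(round) {
    lapply(round, function(tree) {
      list(feature = as.integer(tree$feature),
           threshold = as.numeric(tree$threshold),
           left = as.integer(tree$left),
           right = as.integer(tree$right),
           value = as.numeric(tree$value))
    })
  })
  hp <- do.call(hyperparameters, obj$hp)
  model <- structure(list(trees = trees,
                          best_iter = as.integer(obj$best_iter),
                          rounds_used = as.integer(obj$rounds_used),
                          class_order = obj$class_order,
                          hp = hp,
                          n_features = as.integer(obj$n_features),
                          feature_names = obj$vocab_terms,
                          best_eval_auc = NA_real_,
                          seed = NA_integer_),
                     class = "pk_boosted_model")
  structure(list(model = model, vocab = vocab, field = obj$field,
                 first_few_rows_k = as.integer(obj$first_few_rows_k),
                 representation = obj$representation,
                 format_version = PIPELINE_FORMAT_VERSION),
            class = "pk_pipeline")
}

#' Write predictions or routing decisions as JSONL
#'
#' @param df a data.frame (one JSON object per row).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}
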