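#' Tokenizer used for bag-of-words features
#'
#' Lowercases (optionally) and splits on any run of non-alphanumeric
#' characters, keeping tokens of length >= 1. Digits are kept: PK tables are
#' number-dense and numeric tokens carry signal.
#'
#' @param text character vector.
#' @param lowercase lowercase before splitting (default `TRUE`).
#' @return list of character vectors, one per input element.
#' @export
bow_tokenize <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  pattern <- if (lowercase) "[^a-z0-9]+" else "[^A-Za-z0-9]+"
  lapply(strsplit(text, pattern), function(t) t[nzchar(t)])
}

#' Fit a bag-of-words vocabulary
#'
#' Collects every token meeting the minimum document frequency and assigns
#' indices 0..V-1 in lexicographic (C-locale) order, so fitting is fully
#' deterministic.
#'
#' @param texts character vector of documents (non-empty).
#' @param lowercase fold case before tokenizing (default `TRUE`).
#' @param min_df minimum number of documents a term must appear in
#'   (default 1).
#' @return object of class `pk_vocabulary`: a named integer vector mapping
#'   term to 0-based index, with the config stored as attributes.
#' @export
fit_vocabulary <- function(texts, lowercase = TRUE, min_df = 1L) {
  stopifnot(length(texts) > 0L)
  toks <- bow_tokenize(texts, lowercase)
  if (all(vapply(toks, length, integer(1)) == 0L)) {
    stop("cannot fit a vocabulary: all texts are empty after tokenization",
         call. = FALSE)
  }
  df <- table(unlist(lapply(toks, unique)))
  terms <- sort(names(df)[df >= min_df], method = "radix")
  vocab <- stats::setNames(seq_along(terms) - 1L, terms)
  structure(vocab, class = "pk_vocabulary",
            lowercase = lowercase, min_df = as.integer(min_df))
}

#' @export
print.pk_vocabulary <- function(x, ...) {
  cat(sprintf("<pk_vocabulary> %d terms (lowercase=%s, min_df=%d)\n",
              length(x), attr(x, "lowercase"), attr(x, "min_df")))
  invisible(x)
}

new_feature_vector <- function(values, tag) {
  structure(list(values = as.numeric(values),
                 dimension = length(values),
                 tag = tag),
            class = "pk_feature_vector")
}

#' @export
print.pk_feature_vector <- function(x, ...) {
  cat(sprintf("<pk_feature_vector %s> dim %d\n", x$tag, x$dimension))
  invisible(x)
}

#' Encode one document as term counts over a fitted vocabulary
#'
#' `values[i]` is the count of term `i` in the tokenized text;
#' out-of-vocabulary tokens are ignored. Empty text yields the zero vector.
#'
#' @param text a single document.
#' @param vocab a [fit_vocabulary()] result.
#' @return a `pk_feature_vector` with tag `"bow"`; `$values` are
#'   non-negative integers of length `|V|`.
#' @export
bow_encode <- function(text, vocab) {
  stopifnot(inherits(vocab, "pk_vocabulary"))
  toks <- bow_tokenize(text, attr(vocab, "lowercase"))[[1L]]
  counts <- numeric(length(vocab))
  idx <- vocab[toks]
  idx <- idx[!is.na(idx)]
  if (length(idx)) {
    tab <- tabulate(idx + 1L, nbins = length(vocab))
    counts <- as.numeric(tab)
  }
  new_feature_vector(counts, "bow")
}

#' Encode many documents as a dense count matrix
#'
#' Convenience wrapper over [bow_encode()] used by the training pipeline.
#'
#' @param texts character vector.
#' @param vocab a fitted vocabulary.
#' @return numeric matrix, one row per document, columns named by term.
#' @export
bow_encode_matrix <- function(texts, vocab) {
  m <- t(vapply(texts, function(tx) bow_encode(tx, vocab)$values,
                numeric(length(vocab))))
  dimnames(m) <- list(NULL, names(vocab))
  m
}

#' Split a token sequence into fixed-size chunks
#'
#' Consecutive, non-overlapping chunks of `max_len` tokens (the last chunk
#' may be shorter); concatenating the chunks reproduces the input exactly.
#' An empty input yields a single empty chunk so every text has at least one
#' chunk to encode.
#'
#' @param tokens character (or any) vector of tokens.
#' @param max_len maximum chunk length (default 512, the input limit of the
#'   transformer encoders this mirrors).
#' @return list of token vectors.
#' @export
chunk_tokens <- function(tokens, max_len = 512L) {
  stopifnot(max_len >= 1L)
  n <- length(tokens)
  if (n == 0L) return(list(tokens[0L]))
  starts <- seq.int(1L, n, by = max_len)
  lapply(starts, function(s) tokens[s:min(s + max_len - 1L, n)])
}

#' Pool per-chunk vectors into one vector
#'
#' @param chunk_vectors non-empty list of equal-length numeric vectors.
#' @param mode `"MEAN"` (elementwise arithmetic mean) or `"MAX"`
#'   (elementwise maximum).
#' @return numeric vector of the common dimension.
#' @export
pool_chunks <- function(chunk_vectors, mode = c("MEAN", "MAX")) {
  mode <- match.arg(mode)
  stopifnot(length(chunk_vectors) > 0L)
  dims <- vapply(chunk_vectors, length, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("chunk vectors have mismatched dimensions: ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  }
  m <- do.call(cbind, chunk_vectors)
  if (mode == "MEAN") rowMeans(m) else apply(m, 1L, max)
}

#' Encoder backend contract
#'
#' A pluggable text encoder is a list with fields `name`, `dimension`,
#' `max_len`, `tokenize(text) -> tokens`, and `encode(tokens) -> numeric
#' vector` of length `dimension`. Published biomedical encoders can be
#' wrapped to this contract; tests use [hash_encoder()], a deterministic
#' stub with no model weights.
#'
#' @param name encoder name used in feature tags.
#' @param dimension output dimension.
#' @param max_len maximum tokens per chunk.
#' @param tokenize function mapping one string to a token vector.
#' @param encode function mapping a token chunk to a numeric vector.
#' @return object of class `pk_encoder`.
#' @export
encoder_backend <- function(name, dimension, max_len, tokenize, encode) {
  stopifnot(is.function(tokenize), is.function(encode), dimension >= 1L,
            max_len >= 1L)
  structure(list(name = name, dimension = as.integer(dimension),
                 max_len = as.integer(max_len), tokenize = tokenize,
                 encode = encode),
            class = "pk_encoder")
}

#' Deterministic hash-based stub encoder
#'
#' Maps each token to a bucket by a polynomial rolling hash and accumulates
#' a value derived from the same hash, then normalizes by token count. Pure
#' arithmetic, no randomness: identical text always yields identical
#' vectors. Useful for exercising the chunk/pool machinery without model
#' weights.
#'
#' @param dimension output dimension (default 8).
#' @param max_len chunk size (default 512).
#' @return a `pk_encoder`.
#' @export
hash_encoder <- function(dimension = 8L, max_len = 512L) {
  dimension <- as.integer(dimension)
  hash1 <- function(token) {
    h <- 0
    for (cp in utf8ToInt(token)) h <- (h * 31 + cp) %% 1000003
    h
  }
  encoder_backend(
    name = sprintf("hash%d", dimension),
    dimension = dimension,
    max_len = max_len,
    tokenize = function(text) {
      toks <- strsplit(text, "[[:space:]]+")[[1L]]
      toks[nzchar(toks)]
    },
    encode = function(tokens) {
      v <- numeric(dimension)
      if (length(tokens) == 0L) return(v)
      for (tok in tokens) {
        h <- hash1(tok)
        b <- (h %% dimension) + 1L
        v[b] <- v[b] + (h %% 1000) / 1000
      }
      v / length(tokens)
    })
}

#' Encode arbitrarily long text by chunking and pooling
#'
#' Tokenizes with the encoder's own tokenizer, splits into `max_len`-token
#' chunks, encodes each chunk separately and pools the chunk vectors
#' elementwise. Text shorter than `max_len` reduces to a single direct
#' encoder call.
#'
#' @param text a single document.
#' @param encoder a `pk_encoder` backend.
#' @param mode pooling mode, `"MEAN"` or `"MAX"`.
#' @return a `pk_feature_vector` tagged `"<encoder>+<mode>"`.
#' @export
encode_long_text <- function(text, encoder, mode = c("MEAN", "MAX")) {
  mode <- match.arg(mode)
  stopifnot(inherits(encoder, "pk_encoder"))
  tokens <- encoder$tokenize(text)
  chunks <- chunk_tokens(tokens, encoder$max_len)
  vecs <- lapply(seq_along(chunks), function(i) {
    v <- tryCatch(encoder$encode(chunks[[i]]), error = function(e) {
      stop(sprintf("encoder '%s' failed on chunk %d: %s", encoder$name, i,
                   conditionMessage(e)), call. = FALSE)
    })
    if (length(v) != encoder$dimension) {
      stop(sprintf("encoder '%s' returned dimension %d on chunk %d, expected %d",
                   encoder$name, length(v), i, encoder$dimension),
           call. = FALSE)
    }
    v
  })
  new_feature_vector(pool_chunks(vecs, mode),
                     paste0(encoder$name, "+", tolower(mode)))
}
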