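# Shared builders and independent oracles for the test suite.

# A tiny hand-built PK table used across modules.
tiny_pk_table <- function(id = "t1", label = NULL) {
  pk_table(table_id = id, article_id = "PMC1",
           caption = "PK parameters",
           header_rows = list(c("P", "V")),
           body = list(c("CL", "5"), c("AUC", "9")),
           footer = "CL, clearance",
           label = label)
}

# Random printable cell text (includes pipes and punctuation on purpose).
random_text <- function(n_words = 3) {
  alphabet <- c(letters, LETTERS, 0:9, "|", "-", "/", "+", ".", "(", ")")
  paste(vapply(seq_len(n_words), function(i) {
    paste(sample(alphabet, sample(1:8, 1), replace = TRUE), collapse = "")
  }, character(1)), collapse = " ")
}

random_table <- function(id) {
  n_col <- sample(1:4, 1)
  n_hdr <- sample(0:2, 1)
  n_body <- sample(0:5, 1)
  pk_table(
    table_id = id,
    article_id = sample(c("", "PMC123", "998877"), 1),
    caption = if (stats::runif(1) < 0.8) random_text(5) else "",
    header_rows = lapply(seq_len(n_hdr), function(i)
      vapply(seq_len(n_col), function(j) random_text(2), character(1))),
    body = lapply(seq_len(n_body), function(i)
      vapply(seq_len(n_col), function(j) random_text(2), character(1))),
    footer = if (stats::runif(1) < 0.5) random_text(4) else "",
    label = if (stats::runif(1) < 0.7) sample(PK_LABELS, 1) else NULL)
}

# Brute-force confusion-matrix metrics, independent of score().
oracle_metrics <- function(y_true, y_pred) {
  cm <- matrix(0, 3, 3, dimnames = list(PK_LABELS, PK_LABELS))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  }
  prec <- rec <- f1 <- numeric(3)
  for (k in 1:3) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec[k] <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  present <- rowSums(cm) > 0
  list(confusion = cm,
       precision = prec, recall = rec, f1 = f1,
       macro_f1 = mean(f1[present]),
       micro_f1 = sum(diag(cm)) / sum(cm))
}

# Brute-force per-term counter, independent of bow_encode().
oracle_bow <- function(text, vocab) {
  toks <- tolower(text)
  toks <- strsplit(toks, "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  vapply(names(vocab), function(term) sum(toks == term), numeric(1),
         USE.NAMES = FALSE)
}

# Small linearly separable 3-class feature set for classifier tests.
separable_data <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  X <- matrix(stats::runif(n * 6), n, 6)
  labels <- rep(PK_LABELS, each = n_per_class)
  for (k in 1:3) {
    rows <- ((k - 1) * n_per_class + 1):(k * n_per_class)
    X[rows, k] <- X[rows, k] + 3  # class k loads on feature k
  }
  list(X = X, labels = labels)
}
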