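#' @useDynLib pktables, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Inverse-frequency class weights
#'
#' Balanced sample weights: `w_c = N / (K * n_c)` with `N` the total count
#' and `K` the number of classes, so the weighted sample mass
#' `sum_c n_c * w_c` equals `N` exactly and the mean sample weight is 1.
#'
#' @param label_counts named numeric vector of per-class counts; all classes
#'   in [PK_LABELS] must be present with count >= 1.
#' @return named numeric vector of per-class weights, in [PK_LABELS] order.
#' @export
compute_class_weights <- function(label_counts) {
  missing <- setdiff(PK_LABELS, names(label_counts))
  if (length(missing)) {
    stop("missing class(es) in label_counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- as.numeric(label_counts[PK_LABELS])
  if (any(counts < 1)) {
    stop("every class needs count >= 1; got ",
         paste(PK_LABELS[counts < 1], collapse = ", "), call. = FALSE)
  }
  n <- sum(counts)
  k <- length(counts)
  stats::setNames(n / (k * counts), PK_LABELS)
}

#' Per-sample weights from labels
#'
#' @param labels character vector of labels.
#' @param class_weights optional precomputed [compute_class_weights()]
#'   output; derived from `labels` when `NULL`.
#' @return numeric vector, one weight per sample.
#' @export
sample_weights <- function(labels, class_weights = NULL) {
  labels <- normalize_label(labels)
  if (is.null(class_weights)) {
    counts <- table(factor(labels, levels = PK_LABELS))
    class_weights <- compute_class_weights(counts)
  }
  unname(class_weights[labels])
}

#' Hyperparameters of the boosted classifier
#'
#' The learning rate is fixed at 0.1; boosting is capped at 1000 rounds with
#' early stopping after 10 rounds without AUC-ROC improvement on the
#' evaluation split.
#'
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum hessian mass in a child node.
#' @param gamma minimum loss reduction required to make a split.
#' @param subsample fraction of training rows used to grow each tree.
#' @param colsample_bytree fraction of features available to each tree.
#' @param learning_rate shrinkage applied to each tree (fixed 0.1).
#' @param max_rounds cap on boosting rounds.
#' @param early_stopping_rounds patience of the AUC-based stopping rule.
#' @return object of class `pk_hyperparameters`.
#' @export
hyperparameters <- function(max_depth = 6L, min_child_weight = 1,
                            gamma = 0, subsample = 1, colsample_bytree = 1,
                            learning_rate = 0.1, max_rounds = 1000L,
                            early_stopping_rounds = 10L) {
  stopifnot(max_depth >= 1L, gamma >= 0,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1)
  structure(list(max_depth = as.integer(max_depth),
                 min_child_weight = as.numeric(min_child_weight),
                 gamma = as.numeric(gamma),
                 subsample = as.numeric(subsample),
                 colsample_bytree = as.numeric(colsample_bytree),
                 learning_rate = as.numeric(learning_rate),
                 max_rounds = as.integer(max_rounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds)),
            class = "pk_hyperparameters")
}

#' The default tuning grid
#'
#' Ranges (with step sizes): max depth 2-10 (2), min child weight 1-6 (2),
#' gamma 0.1-0.5 (0.1), subsample 0.5-1.0 (0.1), colsample bytree 0.3-1.0
#' (0.1) — 3600 candidates in total.
#'
#' @return named list of `(lo, hi, step)` triples.
#' @export
default_grid_spec <- function() {
  list(max_depth = c(2, 10, 2),
       min_child_weight = c(1, 6, 2),
       gamma = c(0.1, 0.5, 0.1),
       subsample = c(0.5, 1.0, 0.1),
       colsample_bytree = c(0.3, 1.0, 0.1))
}

grid_dim_values <- function(triple) {
  lo <- triple[[1]]; hi <- triple[[2]]; step <- triple[[3]]
  if (step <= 0) stop("grid step must be > 0", call. = FALSE)
  # integer index scaling: avoids float accumulation so e.g. 0.3..1.0 by 0.1
  # yields exactly 8 values
  n <- floor((hi - lo) / step + 1e-6)
  round(lo + (0:n) * step, 10)
}

#' Enumerate hyperparameter grid candidates
#'
#' Cartesian product of the per-dimension ranges in deterministic row-major
#' order (the last dimension varies fastest), so candidate 1 is the vector
#' of range lower bounds.
#'
#' @param spec named list of `(lo, hi, step)` triples in the order
#'   `max_depth`, `min_child_weight`, `gamma`, `subsample`,
#'   `colsample_bytree`; defaults to [default_grid_spec()].
#' @return data.frame with one row per candidate.
#' @export
grid_candidates <- function(spec = default_grid_spec()) {
  values <- lapply(spec, grid_dim_values)
  # expand.grid varies the FIRST factor fastest; reverse for row-major order
  g <- do.call(expand.grid, c(rev(values), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_along(values)), drop = FALSE]
  names(g) <- names(spec)
  rownames(g) <- NULL
  g
}

# ---- AUC-ROC ----------------------------------------------------------------

# Rank-statistic AUC for one binary problem (ties get average ranks).
binary_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro one-vs-rest AUC-ROC
#'
#' Mean of the per-class one-vs-rest AUCs, skipping classes absent from (or
#' filling) the whole evaluation set. Used as the early-stopping metric.
#'
#' @param prob matrix of class probabilities (columns in [PK_LABELS] order).
#' @param labels character vector of true labels.
#' @return scalar in \[0, 1\].
#' @export
macro_ovr_auc <- function(prob, labels) {
  aucs <- vapply(seq_along(PK_LABELS), function(k) {
    binary_auc(prob[, k], labels == PK_LABELS[k])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# ---- boosting driver --------------------------------------------------------

softmax_rows <- function(margin) {
  m <- margin - apply(margin, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

forest_margin <- function(trees, X, learning_rate, n_rounds) {
  margin <- matrix(0, nrow(X), length(PK_LABELS))
  for (m in seq_len(n_rounds)) {
    for (k in seq_along(PK_LABELS)) {
      margin[, k] <- margin[, k] +
        learning_rate * .predict_tree_cpp(trees[[m]][[k]], X)
    }
  }
  margin
}

# Stratified index split: returns indices of the held-out part.
stratified_holdout <- function(labels, fraction, seed) {
  idx <- integer(0)
  set.seed(seed)
  for (cls in unique(labels)) {
    members <- which(labels == cls)
    n_hold <- max(1L, round(length(members) * fraction))
    if (n_hold >= length(members)) n_hold <- length(members) - 1L
    if (n_hold > 0L) {
      idx <- c(idx, sample(members, n_hold))
    }
  }
  sort(idx)
}

#' Train the class-weighted boosted table classifier
#'
#' Multiclass gradient boosting with a softmax objective minimizing
#' weighted cross-entropy. Each round fits one regression tree per class on
#' the current gradients/hessians; rows are subsampled per round and
#' features per tree according to the hyperparameters. A stratified
#' evaluation split (`eval_fraction`, carved from the input) drives early
#' stopping on macro one-vs-rest AUC-ROC: boosting halts after
#' `early_stopping_rounds` rounds without improvement, and predictions use
#' the best iteration. Training is deterministic given `seed`.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels character vector of gold labels.
#' @param weights per-sample weights (default: inverse class frequency via
#'   [sample_weights()]).
#' @param hp a [hyperparameters()] object.
#' @param eval_fraction fraction held out for early stopping (default 0.1;
#'   0 disables early stopping and runs `max_rounds` rounds).
#' @param seed integer seed controlling the eval split and subsampling.
#' @return object of class `pk_boosted_model`.
#' @export
train_boosted <- function(features, labels, weights = NULL,
                          hp = hyperparameters(), eval_fraction = 0.1,
                          seed = 1L) {
  features <- as.matrix(features)
  labels <- normalize_label(labels)
  if (nrow(features) != length(labels)) {
    stop(sprintf("feature/label length mismatch: %d rows vs %d labels",
                 nrow(features), length(labels)), call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 classes in labels", call. = FALSE)
  }
  if (is.null(weights)) weights <- sample_weights(labels)
  stopifnot(length(weights) == length(labels))

  n <- nrow(features)
  p <- ncol(features)
  k_cls <- length(PK_LABELS)
  y <- matrix(0, n, k_cls)
  y[cbind(seq_len(n), match(labels, PK_LABELS))] <- 1

  use_es <- eval_fraction > 0 && hp$early_stopping_rounds > 0L
  if (use_es) {
    eval_idx <- stratified_holdout(labels, eval_fraction, seed)
    train_idx <- setdiff(seq_len(n), eval_idx)
  } else {
    eval_idx <- integer(0)
    train_idx <- seq_len(n)
  }

  Xt <- features[train_idx, , drop = FALSE]
  yt <- y[train_idx, , drop = FALSE]
  wt <- weights[train_idx]
  nt <- length(train_idx)
  Xe <- features[eval_idx, , drop = FALSE]
  labels_e <- labels[eval_idx]

  margin_t <- matrix(0, nt, k_cls)
  margin_e <- matrix(0, length(eval_idx), k_cls)
  trees <- vector("list", hp$max_rounds)
  best_auc <- -Inf
  best_iter <- 0L
  rounds_used <- 0L
  set.seed(seed + 1L)
  n_sub <- max(1L, round(hp$subsample * nt))
  n_col <- max(1L, round(hp$colsample_bytree * p))

  for (m in seq_len(hp$max_rounds)) {
    prob_t <- softmax_rows(margin_t)
    rows <- if (n_sub < nt) sort(sample(nt, n_sub)) else seq_len(nt)
    round_trees <- vector("list", k_cls)
    for (k in seq_len(k_cls)) {
      grad <- wt * (prob_t[, k] - yt[, k])
      hess <- pmax(wt * prob_t[, k] * (1 - prob_t[, k]), 1e-16)
      cols <- if (n_col < p) sort(sample(p, n_col)) else seq_len(p)
      tree <- .fit_tree_cpp(Xt, grad, hess, rows - 1L, cols - 1L,
                            hp$max_depth, hp$min_child_weight, hp$gamma, 1.0)
      round_trees[[k]] <- tree
      margin_t[, k] <- margin_t[, k] +
        hp$learning_rate * .predict_tree_cpp(tree, Xt)
      if (length(eval_idx)) {
        margin_e[, k] <- margin_e[, k] +
          hp$learning_rate * .predict_tree_cpp(tree, Xe)
      }
    }
    trees[[m]] <- round_trees
    rounds_used <- m
    if (use_es) {
      auc <- macro_ovr_auc(softmax_rows(margin_e), labels_e)
      if (is.finite(auc) && auc > best_auc + 1e-12) {
        best_auc <- auc
        best_iter <- m
      } else if (m - best_iter >= hp$early_stopping_rounds) {
        break
      }
    } else {
      best_iter <- m
    }
  }
  if (best_iter == 0L) best_iter <- rounds_used

  structure(list(trees = trees[seq_len(rounds_used)],
                 best_iter = best_iter,
                 rounds_used = rounds_used,
                 class_order = PK_LABELS,
                 hp = hp,
                 n_features = p,
                 feature_names = colnames(features),
                 best_eval_auc = if (use_es) best_auc else NA_real_,
                 seed = as.integer(seed)),
            class = "pk_boosted_model")
}

#' @export
print.pk_boosted_model <- function(x, ...) {
  cat(sprintf(
    "<pk_boosted_model> %d features, best iteration %d of %d (depth %d)\n",
    x$n_features, x$best_iter, x$rounds_used, x$hp$max_depth))
  invisible(x)
}

#' Predict class probabilities, labels and confidence
#'
#' Applies the ensemble up to its best (early-stopped) iteration and maps
#' margins through a softmax. The confidence of a prediction is the maximum
#' class probability; argmax ties are broken by the canonical class order
#' `PK, DEMOGRAPHICS, OTHER`.
#'
#' @param object a `pk_boosted_model`.
#' @param features numeric matrix (or single vector) with the training
#'   dimensionality.
#' @param ... unused.
#' @return data.frame with columns `prob_PK`, `prob_DEMOGRAPHICS`,
#'   `prob_OTHER`, `label`, `confidence`; one row per input row.
#' @export
predict.pk_boosted_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != object$n_features) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$n_features, ncol(features)), call. = FALSE)
  }
  margin <- forest_margin(object$trees, features, object$hp$learning_rate,
                          object$best_iter)
  prob <- softmax_rows(margin)
  colnames(prob) <- object$class_order
  label <- object$class_order[apply(prob, 1L, which.max)]
  out <- as.data.frame(prob)
  names(out) <- paste0("prob_", object$class_order)
  out$label <- label
  out$confidence <- apply(prob, 1L, max)
  out
}

# ---- cross-validated grid search --------------------------------------------

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one per class.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    members <- sample(which(labels == cls))
    if (length(members) < folds) {
      stop(sprintf(
        "class %s has %d members, fewer than %d folds; use fewer folds",
        cls, length(members), folds), call. = FALSE)
    }
    assign[members] <- rep_len(seq_len(folds), length(members))
  }
  assign
}

#' Grid-search hyperparameters by stratified k-fold cross-validation
#'
#' The data is shuffled once with `seed` into `folds` stratified folds. For
#' every grid candidate the model is trained on each set of k-1 folds (with
#' an internal stratified 10% early-stopping split) and scored by macro-F1
#' on the held-out fold. The winning candidate has the highest mean
#' macro-F1; ties go to the earlier candidate in grid order.
#'
#' @param features numeric matrix.
#' @param labels character vector of gold labels.
#' @param grid data.frame of candidates from [grid_candidates()].
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for shuffling and early-stopping splits.
#' @param eval_fraction internal early-stopping fraction (default 0.1).
#' @return list with `best` (a [hyperparameters()] object), `best_index`,
#'   and `report` — a data.frame with per-candidate mean and (n-1) s.d. of
#'   macro-F1 plus the per-fold scores as a matrix attribute `"fold_scores"`.
#' @export
tune_boosted <- function(features, labels, grid = grid_candidates(),
                         folds = 10L, seed = 1L, eval_fraction = 0.1) {
  features <- as.matrix(features)
  labels <- normalize_label(labels)
  fold_of <- stratified_folds(labels, folds, seed)
  n_cand <- nrow(grid)
  fold_scores <- matrix(NA_real_, n_cand, folds)
  for (ci in seq_len(n_cand)) {
    hp <- hyperparameters(max_depth = grid$max_depth[ci],
                          min_child_weight = grid$min_child_weight[ci],
                          gamma = grid$gamma[ci],
                          subsample = grid$subsample[ci],
                          colsample_bytree = grid$colsample_bytree[ci])
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      model <- train_boosted(features[tr, , drop = FALSE], labels[tr],
                             hp = hp, eval_fraction = eval_fraction,
                             seed = seed + f)
      pred <- predict(model, features[!tr, , drop = FALSE])
      fold_scores[ci, f] <- score(labels[!tr], pred$label)$macro$F1
    }
  }
  means <- rowMeans(fold_scores)
  sds <- apply(fold_scores, 1L, stats::sd)
  best_index <- which.max(means)  # ties -> first in grid order
  report <- cbind(grid,
                  mean_macro_f1 = means,
                  sd_macro_f1 = sds)
  attr(report, "fold_scores") <- fold_scores
  best <- hyperparameters(max_depth = grid$max_depth[best_index],
                          min_child_weight = grid$min_child_weight[best_index],
                          gamma = grid$gamma[best_index],
                          subsample = grid$subsample[best_index],
                          colsample_bytree = grid$colsample_bytree[best_index])
  list(best = best, best_index = best_index, report = report)
}
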