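#' Select tail proteins by product annotation
#'
#' Keeps records whose product annotation contains the substring "tail",
#' case-insensitive, preserving input order. Tail proteins carry the
#' morphological signal that separates phage families.
#'
#' @param records protein record table.
#' @return subset of `records`; warns (does not fail) when empty.
#' @export
select_tail_proteins <- function(records) {
  keep <- grepl("tail", records$product, ignore.case = TRUE)
  if (!any(keep)) warning("no tail-annotated proteins found")
  records[keep, , drop = FALSE]
}

#' Assemble a labeled feature dataset for family classification
#'
#' Featurizes each record and attaches the family label of its source
#' genome. Records whose genome has no entry in `label_map` are dropped
#' with a logged count; fewer than two families is untrainable.
#'
#' @param records protein record table (typically tail proteins).
#' @param label_map named character vector: genome_id -> family.
#' @return list with `features` (n x 431 matrix), `labels` (factor),
#'   `protein_ids`, `genome_ids`.
#' @export
assemble_dataset <- function(records, label_map) {
  labeled <- records$genome_id %in% names(label_map)
  if (any(!labeled)) {
    warning(sprintf("dropped %d record(s) from unlabeled genomes", sum(!labeled)))
    records <- records[labeled, , drop = FALSE]
  }
  mat <- featurize_records(records)
  records <- records[records$id %in% rownames(mat), , drop = FALSE]
  labels <- unname(label_map[records$genome_id])
  if (length(unique(labels)) < 2) stop("untrainable: fewer than 2 families")
  list(features = mat,
       labels = factor(labels),
       protein_ids = records$id,
       genome_ids = records$genome_id)
}

#' Train the random-forest family classifier
#'
#' A 1000-tree random forest over the 431 physicochemical descriptors.
#' No feature scaling is applied: trees are scale-invariant. Reproducible
#' under a fixed seed.
#'
#' @param ds dataset from [assemble_dataset()].
#' @param n_estimators number of trees (default 1000).
#' @param seed integer RNG seed (default 37).
#' @return object of class `randomForest` with the feature-name list
#'   attached as attribute `feature_names`.
#' @export
train_forest <- function(ds, n_estimators = 1000, seed = 37) {
  counts <- table(ds$labels)
  if (any(counts < 2)) {
    warning("class with a single sample: stratification impossible downstream")
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = ds$features, y = ds$labels,
                                    ntree = n_estimators)
  attr(fit, "feature_names") <- colnames(ds$features)
  fit
}

# deterministic stratified fold assignment: within each class, shuffle
# (seeded) and deal members round-robin so fold class counts differ by
# at most one sample
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the family classifier
#'
#' Folds preserve class proportions to within one sample. Every sample
#' appears in exactly one test fold (no leakage). When the smallest
#' class has fewer than `k` members, `k` is reduced to that size with a
#' warning.
#'
#' @param ds dataset from [assemble_dataset()].
#' @param k number of folds (default 10).
#' @param n_estimators trees per fold model (default 1000).
#' @param seed integer RNG seed (default 37).
#' @return list of class `cv_report`: `fold_accuracies`,
#'   `overall_accuracy`, `confusion_matrix` (true x predicted counts),
#'   `per_class_recall`, `k`, `seed`.
#' @export
stratified_cv <- function(ds, k = 10, n_estimators = 1000, seed = 37) {
  if (k < 2) stop("k must be >= 2")
  min_class <- min(table(ds$labels))
  if (min_class < k) {
    warning(sprintf("smallest class has %d members; reducing k from %d",
                    min_class, k))
    k <- min_class
  }
  fold <- stratified_folds(ds$labels, k, seed)
  pred <- factor(rep(NA_character_, length(ds$labels)),
                 levels = levels(ds$labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    set.seed(seed + f)
    fit <- randomForest::randomForest(x = ds$features[!test, , drop = FALSE],
                                      y = ds$labels[!test],
                                      ntree = n_estimators)
    p <- stats::predict(fit, ds$features[test, , drop = FALSE])
    pred[test] <- p
    fold_acc[f] <- mean(p == ds$labels[test])
  }
  cm <- table(true = ds$labels, predicted = pred)
  structure(list(
    fold_accuracies = fold_acc,
    overall_accuracy = sum(diag(cm)) / sum(cm),
    confusion_matrix = cm,
    per_class_recall = diag(cm) / rowSums(cm),
    k = k,
    seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV (seed %d)\n", x$k, x$seed))
  cat(sprintf("  overall accuracy: %.3f\n", x$overall_accuracy))
  cat(sprintf("  fold accuracies:  %s\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = " ")))
  cat("  per-class recall:\n")
  for (cl in names(x$per_class_recall)) {
    cat(sprintf("    %-20s %.3f\n", cl, x$per_class_recall[cl]))
  }
  invisible(x)
}

#' Genome-level family call from per-protein predictions
#'
#' Predicts a family for each tail protein of one genome and aggregates
#' by majority vote. Ties are broken by the highest mean predicted class
#' probability, then lexicographically (deterministic).
#'
#' @param model fitted classifier from [train_forest()].
#' @param records protein record table: the tail proteins of one genome.
#' @return list: `family` (character), `vote_fractions` (named numeric),
#'   `n_proteins`.
#' @export
predict_genome_family <- function(model, records) {
  if (nrow(records) == 0) stop("unclassifiable: no tail proteins")
  mat <- featurize_records(records)
  if (is.null(mat) || nrow(mat) == 0) stop("unclassifiable: no tail proteins")
  fn <- attr(model, "feature_names")
  if (!is.null(fn) && !identical(colnames(mat), fn)) {
    stop("feature-name mismatch between model and input matrix")
  }
  votes <- stats::predict(model, mat)
  prob <- stats::predict(model, mat, type = "prob")
  vf <- table(votes) / length(votes)
  top <- max(vf)
  winners <- sort(names(vf)[vf == top])
  if (length(winners) > 1) {
    mean_p <- colMeans(prob[, winners, drop = FALSE])
    winners <- winners[order(-mean_p, winners)]
  }
  list(family = winners[1],
       vote_fractions = as.numeric(vf) |> stats::setNames(names(vf)),
       n_proteins = length(votes))
}
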