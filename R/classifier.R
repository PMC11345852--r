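#' Class-stratified train/test split
#'
#' Per class, `round(frac * n_class)` members are drawn (seeded, without
#' replacement) into the training set; the rest form the test set, so class
#' proportions are preserved to within one member per class.
#'
#' @param labels factor/character class labels.
#' @param frac training fraction (default 0.6).
#' @param seed integer seed.
#' @return character vector (`"train"`/`"test"`) aligned with `labels`.
#' @export
stratified_split <- function(labels, frac = 0.6, seed = 1) {
  if (frac < 0 || frac > 1) stop("frac must lie in [0, 1]")
  labels <- as.character(labels)
  local_rng(seed)
  out <- rep("test", length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < 2) stop("class '", cl, "' too small to split")
    n_train <- round(frac * length(ix))
    out[sample(ix, n_train)] <- "train"
  }
  out
}

#' Random-forest variant effect classifier
#'
#' Fits a random forest (library-backed) on the training rows and scores
#' the remaining rows; the score of a variant is the fraction of trees
#' voting for the positive (functional) class and the predicted label is
#' functional iff the score exceeds `threshold`. Test-set performance is
#' summarised with [roc_pr()] (the package's single AUC implementation).
#'
#' @param features numeric matrix/data.frame, variants x features.
#' @param labels factor with the positive class as last level (e.g.
#'   `WT-like` < `functional`); `NA` allowed for unlabeled rows.
#' @param split character vector from [stratified_split()] (`"train"` /
#'   `"test"`); rows with `NA` labels are scored but never trained on.
#' @param n_trees forest size (default 1000).
#' @param max_feats features tried per split: `"sqrt"` (default) for
#'   `floor(sqrt(p))`, or an integer.
#' @param threshold score cutoff for the functional label (default 0.5,
#'   strict `>`).
#' @param seed integer seed.
#' @return object of class `classifier_report`: list with `scores` (named,
#'   all non-training rows), `predicted` (labels at the threshold),
#'   `auroc`, `aupr`, `confusion` (test rows), `split`, `threshold`.
#' @export
fit_predict <- function(features, labels, split, n_trees = 1000,
                        max_feats = "sqrt", threshold = 0.5, seed = 1) {
  x <- as.matrix(features)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  pos <- levels(labels)[2]
  train <- which(split == "train" & !is.na(labels))
  if (length(train) == 0) stop("empty training set")
  if (length(unique(labels[train])) < 2) {
    stop("training set contains a single class")
  }
  mtry <- if (identical(max_feats, "sqrt")) max(1, floor(sqrt(ncol(x))))
          else as.integer(max_feats)
  local_rng(seed)
  rf <- randomForest::randomForest(x[train, , drop = FALSE],
                                   y = droplevels(labels[train]),
                                   ntree = n_trees, mtry = mtry)
  score_rows <- setdiff(seq_len(nrow(x)), train)
  scores <- stats::predict(rf, x[score_rows, , drop = FALSE],
                           type = "prob")[, pos]
  names(scores) <- rownames(x)[score_rows]
  predicted <- ifelse(scores > threshold, pos, levels(labels)[1])

  test <- intersect(which(split == "test" & !is.na(labels)), score_rows)
  auroc <- aupr <- NA_real_
  confusion <- NULL
  if (length(test) > 0 && length(unique(labels[test])) == 2) {
    key <- rownames(x)[test]
    ev <- roc_pr(scores[key], labels[test] == pos)
    auroc <- ev$auroc
    aupr <- ev$aupr
    confusion <- table(truth = labels[test], predicted = predicted[key])
  }
  out <- list(scores = scores, predicted = predicted, auroc = auroc,
              aupr = aupr, confusion = confusion, split = split,
              threshold = threshold)
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: %d scored rows, threshold %.2f\n",
              length(x$scores), x$threshold))
  if (!is.na(x$auroc)) {
    cat(sprintf("test AUROC = %.3f, AUPR = %.3f\n", x$auroc, x$aupr))
    print(x$confusion)
  }
  invisible(x)
}
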