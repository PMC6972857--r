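#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), accuracy = (TP+TN)/(TP+TN+FP+FN).  A metric whose denominator
#' is zero is NA and listed in \code{undefined}, never reported as 0.
#'
#' @param tp,fn,fp,tn Non-negative integer counts, at least one positive.
#' @return List of class \code{confusion_metrics} with the four counts, the
#'   four metrics, and \code{undefined}.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("confusion matrix is all zero", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(TP = tp, FN = fn, FP = fp, TN = tn,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              precision = ratio(tp, tp + fp),
              accuracy = (tp + tn) / sum(counts))
  out$undefined <- names(out)[5:8][vapply(out[5:8], is.na, TRUE)]
  structure(out, class = "confusion_metrics")
}

#' Extract the three-feature table of an FFL
#'
#' Per sample (common to both matrices) the expression of the FFL's TF, miRNA
#' and gene; samples with any missing value among the three are dropped with
#' a message.
#'
#' @param ffl One FFL: a one-row data.frame or list with \code{tf_id},
#'   \code{mirna_id}, \code{gene_id}.
#' @param mrna,mirna \code{\link{expression_matrix}} objects holding the
#'   members.
#' @return Data.frame with columns \code{sample_id}, \code{tf},
#'   \code{mirna}, \code{gene}; attribute \code{dropped} lists removed
#'   samples.
#' @export
ffl_features <- function(ffl, mrna, mirna) {
  ids <- c(tf = ffl$tf_id[1L], mirna = ffl$mirna_id[1L],
           gene = ffl$gene_id[1L])
  if (!ids[["tf"]] %in% feature_ids(mrna))
    stop("FFL member '", ids[["tf"]], "' absent from the mRNA matrix",
         call. = FALSE)
  if (!ids[["gene"]] %in% feature_ids(mrna))
    stop("FFL member '", ids[["gene"]], "' absent from the mRNA matrix",
         call. = FALSE)
  if (!ids[["mirna"]] %in% feature_ids(mirna))
    stop("FFL member '", ids[["mirna"]], "' absent from the miRNA matrix",
         call. = FALSE)
  samples <- intersect(sample_ids(mrna), sample_ids(mirna))
  out <- data.frame(sample_id = samples,
                    tf = mrna$values[ids[["tf"]], samples],
                    mirna = mirna$values[ids[["mirna"]], samples],
                    gene = mrna$values[ids[["gene"]], samples],
                    stringsAsFactors = FALSE, row.names = NULL)
  complete <- !is.na(out$tf) & !is.na(out$mirna) & !is.na(out$gene)
  dropped <- out$sample_id[!complete]
  if (length(dropped))
    message("dropped ", length(dropped),
            " sample(s) with missing values: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# Deterministic stratified fold assignment: within each class, samples are
# shuffled and dealt round-robin over the folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Evaluate an FFL as a two-class classifier
#'
#' Repeated stratified k-fold cross-validation of a random forest on the
#' FFL's three expression features.  Per fold the confusion counts against
#' the positive class (the lexicographically first group label) give
#' sensitivity, specificity, precision and accuracy; the fold AUC is the area
#' under the ROC of the forest's predicted class probabilities.  The report
#' is the mean of each metric over all folds of all repeats.  Each repeat
#' uses a distinct derived seed, so the same \code{seed} gives an identical
#' report.
#'
#' @param features Feature table from \code{\link{ffl_features}}, or any
#'   data.frame whose numeric columns are the features.
#' @param labels Two-class vector aligned with the rows of \code{features}.
#' @param n_folds Folds per repeat (default 10); every class needs at least
#'   \code{n_folds} samples.
#' @param n_repeats Repeats (default 10).
#' @param seed Integer seed.
#' @param num_trees Random-forest size (default 500).
#' @return List of class \code{ffl_metrics}: mean \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{accuracy}, \code{auc},
#'   plus \code{folds} (per-fold counts and metrics), \code{n_folds},
#'   \code{n_repeats}, \code{seed}, \code{positive_class},
#'   \code{n_samples} and \code{undefined_metrics}.
#' @export
evaluate_ffl <- function(features, labels, n_folds = 10L, n_repeats = 10L,
                         seed = 1L, num_trees = 500L) {
  x <- features[, vapply(features, is.numeric, TRUE), drop = FALSE]
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  class_n <- table(labels)
  if (any(class_n < n_folds))
    stop("class '", names(class_n)[which.min(class_n)], "' has only ",
         min(class_n), " samples; use n_folds <= ", min(class_n),
         call. = FALSE)
  positive <- classes[1L]
  negative <- classes[2L]
  y <- factor(labels, levels = c(negative, positive))

  rows <- vector("list", n_folds * n_repeats)
  ri <- 0L
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + rep_i - 1L)
    fold <- stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      test <- fold == f
      fit <- randomForest::randomForest(x = x[!test, , drop = FALSE],
                                        y = y[!test], ntree = num_trees)
      pred <- predict(fit, x[test, , drop = FALSE])
      prob <- predict(fit, x[test, , drop = FALSE], type = "prob")[, positive]
      truth <- labels[test]
      tp <- sum(pred == positive & truth == positive)
      fn <- sum(pred != positive & truth == positive)
      fp <- sum(pred == positive & truth != positive)
      tn <- sum(pred != positive & truth != positive)
      cm <- confusion_metrics(tp, fn, fp, tn)
      roc <- pROC::roc(response = factor(truth, levels = c(negative, positive)),
                       predictor = prob, levels = c(negative, positive),
                       direction = "<", quiet = TRUE)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        repeat_i = rep_i, fold = f, TP = tp, FN = fn, FP = fp, TN = tn,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        precision = cm$precision, accuracy = cm$accuracy,
        auc = as.numeric(pROC::auc(roc)), stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "precision", "accuracy",
                   "auc")
  means <- vapply(folds[metric_cols], mean, numeric(1), na.rm = TRUE)
  undefined <- metric_cols[vapply(folds[metric_cols],
                                  function(v) anyNA(v), TRUE)]
  structure(c(as.list(means),
              list(folds = folds, n_folds = n_folds, n_repeats = n_repeats,
                   seed = seed, positive_class = positive,
                   n_samples = nrow(x), undefined_metrics = undefined)),
            class = "ffl_metrics")
}

#' @export
print.ffl_metrics <- function(x, ...) {
  cat(sprintf("<ffl_metrics> %dx%d-fold CV, positive class '%s', %d samples\n",
              x$n_repeats, x$n_folds, x$positive_class, x$n_samples))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  precision %.3f  accuracy %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$accuracy, x$auc))
  if (length(x$undefined_metrics))
    cat("  undefined in some folds:",
        paste(x$undefined_metrics, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a table of FFLs as classifiers
#'
#' Runs \code{\link{evaluate_ffl}} for every row of an FFL table and returns
#' a summary table (members, category, average sensitivity/specificity/
#' precision/accuracy and AUC per FFL).
#'
#' @param ffls FFL data.frame (e.g. the output of \code{\link{rank_ffls}}).
#' @param mrna,mirna Expression matrices holding the members.
#' @param sheet Sample sheet assigning each sample to one of two groups.
#' @param ... Passed on to \code{\link{evaluate_ffl}}.
#' @return Data.frame with one row per FFL.
#' @export
evaluate_ffl_table <- function(ffls, mrna, mirna, sheet, ...) {
  do.call(rbind, lapply(seq_len(nrow(ffls)), function(i) {
    feats <- ffl_features(ffls[i, ], mrna, mirna)
    lab <- sheet$group[match(feats$sample_id, sheet$sample_id)]
    rep <- evaluate_ffl(feats[, c("tf", "mirna", "gene")], lab, ...)
    data.frame(tf_id = ffls$tf_id[i], mirna_id = ffls$mirna_id[i],
               gene_id = ffls$gene_id[i], category = ffls$category[i],
               sensitivity = rep$sensitivity, specificity = rep$specificity,
               precision = rep$precision, accuracy = rep$accuracy,
               auc = rep$auc, stringsAsFactors = FALSE)
  }))
}
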