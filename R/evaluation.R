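#' Binary confusion counts
#'
#' @param truth,calls Binary 0/1 vectors of equal length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, calls) {
  stopifnot(length(truth) == length(calls))
  truth <- as.integer(truth); calls <- as.integer(calls)
  stopifnot(all(truth %in% 0:1), all(calls %in% 0:1))
  structure(list(tp = sum(truth == 1 & calls == 1),
                 fp = sum(truth == 0 & calls == 1),
                 tn = sum(truth == 0 & calls == 0),
                 fn = sum(truth == 1 & calls == 0)),
            class = "confusion_counts")
}

#' Binary classification metrics
#'
#' Direct evaluation of the standard confusion-count formulas:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall).
#' Ratios with a zero denominator are reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param counts A [confusion_counts()] object, or a list with elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  tot <- tp + fp + tn + fn
  if (tot == 0) stop("empty evaluation: all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / tot, precision = precision, recall = recall,
       f1 = f1)
}

#' ROC AUC (Mann-Whitney form)
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic: the probability that a random positive scores above a random
#' negative, ties counted 1/2.  Implemented with midranks, which is exactly
#' the pairwise count.
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate labels: AUC needs both classes present")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-frequency weighted average of per-class metrics
#'
#' @param values Per-class metric values.
#' @param freqs Class frequencies, non-negative and summing to 1 (within
#'   1e-9).
#' @return `sum(freqs * values)`.
#' @export
weighted_average <- function(values, freqs) {
  if (length(values) != length(freqs))
    stop("`values` and `freqs` differ in length")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("`freqs` must be non-negative and sum to 1")
  sum(freqs * values)
}

#' Binary metrics report from probabilities
#'
#' @param truth Binary 0/1 truth vector.
#' @param prob Predicted probability of class 1.
#' @param threshold Decision threshold (call 1 iff `prob > threshold`).
#' @return A `metrics_report` list: confusion counts, `accuracy`, `auc`,
#'   `precision`, `recall`, `f1`, and `n`.
#' @export
binary_report <- function(truth, prob, threshold = 0.5) {
  calls <- as.integer(prob > threshold)
  cc <- confusion_counts(truth, calls)
  m <- binary_metrics(cc)
  structure(c(list(counts = cc, n = length(truth),
                   auc = roc_auc(truth, prob)), m),
            class = "metrics_report")
}

#' One-vs-rest multiclass metrics report
#'
#' Calls are the per-row argmax of the probability matrix (ties toward the
#' lowest class index).  For each class c the report binarizes c vs rest:
#' per-class accuracy is the recall of that class (the fraction of true
#' class-c samples called c), AUC uses the class-c probability column, and
#' precision/recall/F1 come from the binarized confusion counts.  The
#' weighted row is the class-frequency-weighted average of the per-class
#' values, and categorical accuracy is the fraction of argmax calls that
#' equal the truth (algebraically identical to weighted recall).
#'
#' @param labels Integer labels `0..K-1`, all K classes present, K >= 3.
#' @param probs N x K matrix of class probabilities; rows must lie on the
#'   simplex within 1e-6.
#' @return A `metrics_report` list: `per_class` data frame (`class`, `n`,
#'   `freq`, `accuracy`, `auc`, `precision`, `recall`, `f1`), `weighted`
#'   row, and `categorical_accuracy`.
#' @export
one_vs_rest_report <- function(labels, probs) {
  labels <- as.integer(labels)
  probs <- as.matrix(probs)
  k <- ncol(probs)
  if (k < 3) stop("one_vs_rest_report() is for K >= 3 classes")
  if (!all(labels %in% 0:(k - 1))) stop("labels must lie in 0..K-1")
  if (length(unique(labels)) < k) stop("all K classes must be present")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must be non-negative and sum to 1 (within 1e-6)")
  calls <- max.col(probs, ties.method = "first") - 1L
  per <- lapply(0:(k - 1), function(c) {
    cc <- confusion_counts(as.integer(labels == c), as.integer(calls == c))
    m <- binary_metrics(cc)
    data.frame(class = c, n = sum(labels == c),
               freq = mean(labels == c),
               accuracy = m$recall,   # per-class accuracy == class recall
               auc = roc_auc(as.integer(labels == c), probs[, c + 1L]),
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  per <- do.call(rbind, per)
  wavg <- function(v) {
    if (anyNA(v)) return(NA_real_)
    weighted_average(v, per$freq)
  }
  weighted <- data.frame(accuracy = wavg(per$accuracy), auc = wavg(per$auc),
                         precision = wavg(per$precision),
                         recall = wavg(per$recall), f1 = wavg(per$f1))
  structure(list(per_class = per, weighted = weighted,
                 categorical_accuracy = mean(calls == labels),
                 n = length(labels)),
            class = "metrics_report")
}

#' Stratified k-fold assignment
#'
#' Shuffles samples within class (seed-controlled) and deals them into k
#' folds so that folds are disjoint and exhaustive, fold sizes differ by at
#' most 1, and per-class counts per fold differ by at most 1.
#'
#' @param labels Class labels (any atomic type).
#' @param k Number of folds (default 5, the 80-20 split).
#' @param seed RNG seed making the plan reproducible.
#' @return A `cv_plan` integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  f <- as.factor(labels)
  tab <- table(f)
  if (any(tab < k))
    stop("stratification impossible: class(es) ",
         paste(names(tab)[tab < k], collapse = ", "),
         " have fewer than k = ", k, " members")
  set.seed(seed)
  folds <- integer(length(f))
  nxt <- 0L
  for (cl in levels(f)) {
    idx <- which(f == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((nxt + seq_along(idx) - 1L) %% k) + 1L
    nxt <- nxt + length(idx)
  }
  structure(folds, k = as.integer(k), seed = as.integer(seed),
            class = "cv_plan")
}

subset_x <- function(x, idx) {
  if (inherits(x, "aio_stack"))
    return(structure(list(tensors = x$tensors[idx, , , , drop = FALSE],
                          sample_ids = x$sample_ids[idx],
                          pixel_map = x$pixel_map), class = "aio_stack"))
  if (inherits(x, "scaled_matrix"))
    return(structure(list(values = x$values[idx, , drop = FALSE],
                          order = x$order, scaler = x$scaler),
                     class = "scaled_matrix"))
  if (is.matrix(x)) return(x[idx, , drop = FALSE])
  d <- length(dim(x))
  if (d == 4L) return(x[idx, , , , drop = FALSE])
  if (d == 3L) return(x[idx, , , drop = FALSE])
  stop("unsupported input container")
}

n_samples_of <- function(x) {
  if (inherits(x, "aio_stack")) dim(x$tensors)[1L]
  else if (inherits(x, "scaled_matrix")) nrow(x$values)
  else if (is.matrix(x)) nrow(x)
  else dim(x)[1L]
}

pool_metrics <- function(truth, prob_mat, n_classes, threshold = 0.5) {
  if (n_classes == 2L) binary_report(truth, prob_mat[, 1L], threshold)
  else one_vs_rest_report(truth, prob_mat)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' For each fold, trains a freshly built model on the other k-1 folds (80%
#' for k = 5) and predicts the held-out 20%.  Held-out predictions are
#' pooled across folds -- every sample is predicted exactly once -- and the
#' metrics are computed once on the pooled predictions; per-fold accuracies
#' are logged alongside.
#'
#' @param x AIO tensors (any container [train_model()] accepts).
#' @param labels Integer labels `0/1` or `0..K-1`, non-missing.
#' @param builder Function `(seed) -> aio_model` building an untrained
#'   model; called once per fold with seed `cfg$seed + fold`.
#' @param cfg A [train_config()].
#' @param k Number of folds.
#' @param n_classes 2 or K; inferred from the labels when `NULL`.
#' @return A `cv_result`: `metrics` (pooled report), `predictions` (pooled
#'   data frame with `fold`, `truth`, probabilities and `call`),
#'   `per_fold`, and `plan`.
#' @export
cross_validate <- function(x, labels, builder, cfg = train_config(), k = 5,
                           n_classes = NULL) {
  n <- n_samples_of(x)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be non-missing for cross-validation")
  if (is.null(n_classes)) n_classes <- max(2L, max(labels) + 1L)
  plan <- stratified_kfold(labels, k = k, seed = cfg$seed)
  ncolp <- if (n_classes == 2L) 1L else n_classes
  prob <- matrix(NA_real_, n, ncolp)
  call <- integer(n)
  per_fold <- data.frame(fold = integer(0), n_test = integer(0),
                         accuracy = numeric(0))
  for (fold in seq_len(k)) {
    te <- which(plan == fold)
    tr <- which(plan != fold)
    model <- builder(cfg$seed + fold)
    train_model(model, subset_x(x, tr), labels[tr], cfg)
    pred <- predict_proba(model, subset_x(x, te))
    pm <- as.matrix(pred[, grep("^prob", names(pred)), drop = FALSE])
    prob[te, ] <- pm
    call[te] <- pred$call
    per_fold <- rbind(per_fold,
                      data.frame(fold = fold, n_test = length(te),
                                 accuracy = mean(pred$call == labels[te])))
  }
  metrics <- pool_metrics(labels, prob, n_classes)
  preds <- data.frame(index = seq_len(n), fold = as.integer(plan),
                      truth = labels, prob, call = call)
  names(preds)[3L + seq_len(ncolp)] <-
    if (ncolp == 1L) "prob" else paste0("prob_", seq_len(ncolp) - 1L)
  structure(list(metrics = metrics, predictions = preds,
                 per_fold = per_fold, plan = plan, n_classes = n_classes),
            class = "cv_result")
}

#' Train on one cohort, test on an external cohort
#'
#' Fits a model on all labeled training samples and evaluates it on an
#' independent cohort, the generalizability protocol.  Both cohorts must
#' share the same gene order (checked before any training when orders are
#' supplied), and when the two expression matrices are supplied the
#' per-gene mean-expression consistency diagnostic
#' ([diagnose_consistency()]) is reported alongside the metrics.
#'
#' @param train_x,test_x AIO tensors for the two cohorts.
#' @param train_labels,test_labels Integer labels.
#' @param builder Function `(seed) -> aio_model`.
#' @param cfg A [train_config()].
#' @param train_order,test_order Optional `gene_order`s; a mismatch is an
#'   error raised before training.
#' @param train_expression,test_expression Optional `expression_matrix`
#'   pair for the consistency diagnostic.
#' @param n_classes 2 or K; inferred when `NULL`.
#' @return A list: `metrics` (report on the external cohort),
#'   `predictions`, `consistency_r` (or `NA` when no expression given),
#'   and `model`.
#' @export
external_test <- function(train_x, train_labels, test_x, test_labels,
                          builder, cfg = train_config(),
                          train_order = NULL, test_order = NULL,
                          train_expression = NULL, test_expression = NULL,
                          n_classes = NULL) {
  if (!is.null(train_order) || !is.null(test_order)) {
    if (is.null(train_order) || is.null(test_order) ||
        !identical(as.character(train_order), as.character(test_order)))
      stop("train and test cohorts must share the same gene order")
  }
  train_labels <- as.integer(train_labels)
  test_labels <- as.integer(test_labels)
  if (is.null(n_classes))
    n_classes <- max(2L, max(c(train_labels, test_labels)) + 1L)
  r <- NA_real_
  if (!is.null(train_expression) && !is.null(test_expression))
    r <- diagnose_consistency(train_expression, test_expression)
  model <- builder(cfg$seed)
  train_model(model, train_x, train_labels, cfg)
  pred <- predict_proba(model, test_x)
  pm <- as.matrix(pred[, grep("^prob", names(pred)), drop = FALSE])
  metrics <- pool_metrics(test_labels, pm, n_classes)
  list(metrics = metrics, predictions = pred, consistency_r = r,
       model = model)
}

#' Dataset-consistency diagnostic
#'
#' Pearson correlation, across shared genes, of the per-gene mean log2
#' expression in two cohorts.  Matched cohorts sit near r = 1; systematic
#' cross-dataset shift (platform, sample treatment) attenuates r and
#' predicts degraded model transfer.
#'
#' @param mat_a,mat_b `expression_matrix` objects on either scale (FPKM
#'   values are log2(x+1)-transformed internally).
#' @return Pearson r of the per-gene mean log2 expression.
#' @export
diagnose_consistency <- function(mat_a, mat_b) {
  stopifnot(inherits(mat_a, "expression_matrix"),
            inherits(mat_b, "expression_matrix"))
  tolog <- function(m) if (m$scale == "fpkm") log2(m$values + 1) else m$values
  a <- tolog(mat_a); b <- tolog(mat_b)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3)
    stop("insufficient data: need at least 3 shared genes, have ",
         length(shared))
  stats::cor(colMeans(a[, shared, drop = FALSE]),
             colMeans(b[, shared, drop = FALSE]))
}

#' @export
print.metrics_report <- function(x, ...) {
  if (!is.null(x$per_class)) {
    cat(sprintf("multiclass metrics report (n = %d)\n", x$n))
    print(format(x$per_class, digits = 3), row.names = FALSE)
    cat(sprintf("weighted: acc %.3f, AUC %.3f; categorical accuracy %.3f\n",
                x$weighted$accuracy, x$weighted$auc,
                x$categorical_accuracy))
  } else {
    cat(sprintf(paste0("binary metrics report (n = %d): acc %.3f, AUC ",
                       "%.3f, prec %.3f, rec %.3f, F1 %.3f\n"),
                x$n, x$accuracy, x$auc, x$precision, x$recall, x$f1))
  }
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (pooled held-out predictions)\n",
              attr(x$plan, "k")))
  print(x$metrics)
  invisible(x)
}
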