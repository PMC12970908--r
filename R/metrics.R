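# Evaluation metrics: precision/recall/F1, confusion matrix and accuracy,
# ROC/AUC, and the detection-rate arithmetic with its truncate-then-
# complement convention.

#' Precision, recall and F1 from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)` (the harmonic mean, so
#' `min(P, R) <= F1 <= max(P, R)`). A zero denominator yields 0 with a
#' warning rather than an error, so batch evaluation never aborts.
#'
#' @param tp,fp,fn non-negative counts
#' @return named list with `precision`, `recall`, `f1`
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) {
    if (tp + fp + fn > 0) 0 else { # all-zero counts already warned above
      0
    }
  } else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Confusion matrix and accuracy
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`; accuracy is the trace over the total. Row sums equal per-class
#' sample counts.
#'
#' @param y_true,y_pred equal-length integer label vectors in `1..C`
#'   (factors are converted)
#' @param C number of classes (inferred from the labels if missing)
#' @param classes optional class names for the matrix dimnames
#' @return list with `confusion` (`C x C` integer matrix) and `accuracy`
#' @export
confusion_and_accuracy <- function(y_true, y_pred, C = NULL, classes = NULL) {
  if (is.factor(y_true)) {
    if (is.null(classes)) classes <- levels(y_true)
    y_true <- as.integer(y_true)
  }
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(C)) C <- max(y_true, y_pred)
  if (any(y_true < 1L | y_true > C) || any(y_pred < 1L | y_pred > C)) {
    stop("labels out of range 1..", C, call. = FALSE)
  }
  cm <- matrix(0L, C, C)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  if (!is.null(classes)) dimnames(cm) <- list(true = classes, predicted = classes)
  list(confusion = cm, accuracy = sum(diag(cm)) / length(y_true))
}

#' Per-class and macro-averaged metrics from a confusion matrix
#'
#' One-vs-rest precision, recall and F1 per class, and their unweighted
#' (macro) averages.
#'
#' @param cm a `C x C` confusion matrix (rows = true class)
#' @return list with `per_class` (tibble) and `macro_precision`,
#'   `macro_recall`, `macro_f1`
#' @export
macro_metrics <- function(cm) {
  C <- nrow(cm)
  rows <- lapply(seq_len(C), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    m <- suppressWarnings(precision_recall_f1(tp, fp, fn))
    tibble::tibble(class = if (!is.null(rownames(cm))) rownames(cm)[i] else
      as.character(i), precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  per <- do.call(rbind, rows)
  list(per_class = per,
       macro_precision = mean(per$precision),
       macro_recall = mean(per$recall),
       macro_f1 = mean(per$f1))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the true-positive-rate vs false-positive-rate
#' curve as the decision threshold sweeps the scores; tied scores are
#' grouped, which is equivalent to mid-rank handling (the Mann-Whitney
#' identity `AUC = U / (n+ * n-)`). Perfectly separated scores give 1,
#' constant scores give 0.5. AUC is invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores, larger meaning more likely positive
#' @param binary_labels logical (or 0/1) true labels; both classes must be
#'   present
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, binary_labels) {
  y <- as.logical(binary_labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # cumulative TP/FP at each distinct threshold (tie groups collapse)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(yy)[last]; fp <- cumsum(!yy)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Detection count table
#'
#' The leaf-detection outcome counts from which recognition rates are
#' computed: how many diseased and healthy leaves were detected and how many
#' of each were misidentified (with the diseased-as-healthy subset tracked
#' separately).
#'
#' @param detected_diseased,detected_healthy totals of detected leaves
#' @param diseased_misidentified diseased leaves given a wrong label
#' @param diseased_as_healthy the subset of those labeled healthy
#' @param healthy_misidentified healthy leaves labeled diseased
#' @return a `detection_counts` list
#' @export
detection_counts <- function(detected_diseased, diseased_misidentified,
                             diseased_as_healthy = 0L,
                             detected_healthy, healthy_misidentified) {
  stopifnot(diseased_misidentified <= detected_diseased,
            diseased_as_healthy <= diseased_misidentified,
            healthy_misidentified <= detected_healthy)
  structure(list(detected_diseased = detected_diseased,
                 diseased_misidentified = diseased_misidentified,
                 diseased_as_healthy = diseased_as_healthy,
                 detected_healthy = detected_healthy,
                 healthy_misidentified = healthy_misidentified),
            class = "detection_counts")
}

trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Detection recognition rates
#'
#' False-recognition rates in percent under the truncate-then-complement
#' convention: the false rate is truncated to two decimals and the correct
#' rate is `100 - false`, so the pair always sums to exactly 100. For 12
#' misidentified out of 243 detected diseased leaves this gives 4.93 / 95.07;
#' for 9 of 583 healthy leaves, 1.54 / 98.46; 1 diseased leaf taken for
#' healthy out of 243 is 0.41. `method = "round"` rounds instead of
#' truncating (the complement is still taken from the reported false rate).
#'
#' @param counts a [detection_counts()]
#' @param method `"truncate"` (default) or `"round"`
#' @return named list of rates in percent: `diseased_false`,
#'   `diseased_correct`, `diseased_as_healthy`, `diseased_as_other`,
#'   `healthy_false`, `healthy_correct`
#' @export
detection_rates <- function(counts, method = c("truncate", "round")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "detection_counts"))
  if (counts$detected_diseased == 0 || counts$detected_healthy == 0) {
    stop("zero detected totals", call. = FALSE)
  }
  rate <- function(num, den) {
    r <- 100 * num / den
    if (method == "truncate") trunc2(r) else round(r, 2)
  }
  d_false <- rate(counts$diseased_misidentified, counts$detected_diseased)
  h_false <- rate(counts$healthy_misidentified, counts$detected_healthy)
  list(
    diseased_false = d_false,
    diseased_correct = 100 - d_false,
    diseased_as_healthy = rate(counts$diseased_as_healthy,
                               counts$detected_diseased),
    diseased_as_other = rate(counts$diseased_misidentified -
                               counts$diseased_as_healthy,
                             counts$detected_diseased),
    healthy_false = h_false,
    healthy_correct = 100 - h_false
  )
}

#' Evaluate a model on labeled images
#'
#' Runs inference-mode prediction and computes accuracy, the confusion
#' matrix, and macro precision/recall/F1.
#'
#' @param model an `rgn_model` or `rgn_inference` model
#' @param images `(N,H,W,C)` array
#' @param labels integer labels in `1..C`
#' @param batch_size prediction batch size
#' @return list with `accuracy`, `confusion`, `macro` (see
#'   [macro_metrics()]), `pred` (integer predictions)
#' @export
evaluate_model <- function(model, images, labels, batch_size = 64L) {
  n <- dim(images)[1]
  pred <- integer(n)
  pos <- 1L
  while (pos <= n) {
    idx <- pos:min(pos + batch_size - 1L, n)
    pred[idx] <- predict(model, images[idx, , , , drop = FALSE])$label
    pos <- pos + batch_size
  }
  ca <- confusion_and_accuracy(labels, pred, C = model$cfg$num_classes,
                               classes = model$classes)
  list(accuracy = ca$accuracy, confusion = ca$confusion,
       macro = macro_metrics(ca$confusion), pred = pred)
}
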