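test_that("precision/recall/F1 from counts", {
  expect_equal(precision_recall_f1(1, 0, 0),
               list(precision = 1, recall = 1, f1 = 1))
  m <- precision_recall_f1(9, 3, 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 2 * 0.75 * 0.9 / 1.65) # 9/11
  expect_warning(z <- precision_recall_f1(0, 5, 5), NA) # denominators fine
  expect_equal(z, list(precision = 0, recall = 0, f1 = 0))
  expect_warning(precision_recall_f1(0, 0, 5), "precision")
})

test_that("F1 is the harmonic mean: bounded by precision and recall", {
  set.seed(2)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- suppressWarnings(precision_recall_f1(tp, fp, fn))
    expect_gte(m$f1 + 1e-12, min(m$precision, m$recall) *
                 (m$f1 > 0 || min(m$precision, m$recall) == 0))
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    if (m$precision == m$recall) expect_equal(m$f1, m$precision)
  }
})

test_that("confusion matrix counts true-by-predicted and accuracy is the
           diagonal fraction", {
  y <- c(1L, 2L, 3L, 2L, 1L)
  ca <- confusion_and_accuracy(y, y, C = 3L)
  expect_true(all(ca$confusion[upper.tri(ca$confusion)] == 0))
  expect_true(all(ca$confusion[lower.tri(ca$confusion)] == 0))
  expect_equal(ca$accuracy, 1)
  set.seed(3)
  yt <- sample(1:4, 200, replace = TRUE)
  yp <- sample(1:4, 200, replace = TRUE)
  ca2 <- confusion_and_accuracy(yt, yp, C = 4L)
  expect_equal(as.vector(rowSums(ca2$confusion)),
               as.vector(table(factor(yt, levels = 1:4))))
  expect_equal(ca2$accuracy, mean(yt == yp))
  expect_error(confusion_and_accuracy(c(1L, 5L), c(1L, 1L), C = 4L),
               "out of range")
})

# A 10-class tomato confusion table used as a worked input.
tomato_confusion <- function() {
  matrix(c(
    903, 9, 15, 12, 6, 3, 3, 0, 3, 0,
    18, 1215, 9, 6, 9, 6, 6, 3, 3, 3,
    15, 6, 567, 0, 3, 0, 6, 0, 0, 3,
    12, 6, 9, 1083, 12, 9, 6, 3, 6, 0,
    9, 6, 3, 0, 534, 9, 0, 6, 3, 0,
    6, 0, 3, 0, 3, 207, 0, 0, 0, 3,
    15, 6, 3, 3, 9, 6, 993, 9, 12, 6,
    3, 3, 6, 9, 6, 3, 3, 798, 9, 3,
    12, 6, 0, 6, 0, 9, 3, 12, 951, 6,
    21, 9, 12, 15, 6, 21, 24, 15, 33, 3060), 10, 10, byrow = TRUE)
}

test_that("accuracy of the printed tomato confusion table matches an
           independent summation oracle", {
  cm <- tomato_confusion()
  # oracle: explicit double loop over cells
  diag_sum <- 0; total <- 0
  for (i in 1:10) for (j in 1:10) {
    total <- total + cm[i, j]
    if (i == j) diag_sum <- diag_sum + cm[i, j]
  }
  # reconstruct label vectors from the counts and run the module under test
  yt <- integer(0); yp <- integer(0)
  for (i in 1:10) for (j in 1:10) {
    yt <- c(yt, rep(i, cm[i, j])); yp <- c(yp, rep(j, cm[i, j]))
  }
  ca <- confusion_and_accuracy(yt, yp, C = 10L)
  expect_identical(ca$confusion, matrix(as.integer(cm), 10, 10))
  expect_equal(ca$accuracy, diag_sum / total)
  mm <- macro_metrics(ca$confusion)
  expect_true(all(mm$per_class$f1 > 0.8))
})

test_that("ROC AUC: separation, ties, the Mann-Whitney identity, and
           monotone invariance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # 4-sample hand case: scores 0.9, 0.7, 0.4, 0.2; labels 1, 0, 1, 0
  s <- c(0.9, 0.7, 0.4, 0.2); y <- c(1, 0, 1, 0)
  # U = #(pos > neg pairs) + 0.5 #ties = (2 + 1) / 4
  expect_equal(roc_auc(s, y), 3 / 4)
  set.seed(9)
  sc <- rnorm(60); lab <- runif(60) < 0.4
  a <- roc_auc(sc, lab)
  pos <- sc[lab]; neg <- sc[!lab]
  u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(a, u / (length(pos) * length(neg)))
  expect_equal(roc_auc(exp(3 * sc), lab), a) # strictly monotone transform
  expect_error(roc_auc(sc, rep(TRUE, 60)), "positive")
})

test_that("own AUC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    sc <- rnorm(80)
    lab <- runif(80) < 0.5
    if (!any(lab) || all(lab)) next
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
  }
})

test_that("detection rates follow truncate-then-complement", {
  counts <- detection_counts(detected_diseased = 243,
                             diseased_misidentified = 12,
                             diseased_as_healthy = 1,
                             detected_healthy = 583,
                             healthy_misidentified = 9)
  r <- detection_rates(counts)
  expect_equal(r$diseased_false, 4.93)
  expect_equal(r$diseased_correct, 95.07)
  expect_equal(r$healthy_false, 1.54)
  expect_equal(r$healthy_correct, 98.46)
  expect_equal(r$diseased_as_healthy, 0.41)
  expect_equal(r$diseased_as_other, 4.52) # 11/243 truncated
  # rounding instead reproduces the alternative printed figure
  expect_equal(detection_rates(counts, method = "round")$diseased_as_other,
               4.53)
  # complements always sum to exactly 100
  for (mis in c(0, 7, 40)) {
    rr <- detection_rates(detection_counts(101, mis, 0, 77, 3))
    expect_identical(rr$diseased_false + rr$diseased_correct, 100)
  }
  zero <- detection_rates(detection_counts(50, 0, 0, 60, 0))
  expect_equal(zero$diseased_false, 0)
  expect_equal(zero$diseased_correct, 100)
  expect_error(detection_counts(10, 12, 0, 5, 1), "diseased_misidentified")
})

test_that("evaluate_model ties predictions, confusion and macro metrics
           together", {
  model <- micro_model(num_classes = 3L)
  ds <- micro_dataset(n_per_class = 2L)
  x <- leafrgn:::stack_images(ds$images[1:6])
  y <- rep(1:3, each = 2L)
  ev <- evaluate_model(model, x, y)
  expect_equal(ev$accuracy, mean(ev$pred == y))
  expect_equal(sum(ev$confusion), 6)
  expect_true(ev$macro$macro_f1 >= 0 && ev$macro$macro_f1 <= 1)
})
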