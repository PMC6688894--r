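# Brute-force metric oracle working directly on label pairs.
brute_metrics <- function(y, p) {
  tp <- sum(y == 1 & p == 1); fp <- sum(y == 0 & p == 1)
  fn <- sum(y == 1 & p == 0); tn <- sum(y == 0 & p == 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  c(accuracy = div(tp + tn, length(y)), precision = prec, recall = rec,
    balanced_accuracy = (prec + rec) / 2)
}

# Pairwise-comparison AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("confusion counts match hand counts", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unlist(cm[c("TP", "FP", "FN", "TN")]),
                   c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  cm2 <- confusion(c(1, 0), c(1, 1))
  expect_identical(unlist(cm2[c("TP", "FP", "FN", "TN")]),
                   c(TP = 1L, FP = 1L, FN = 0L, TN = 0L))
  cm3 <- confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                   c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))
  expect_identical(unlist(cm3[c("TP", "FP", "FN", "TN")]),
                   c(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  expect_error(confusion(c(1, 0), c(1)), "lengths")
})

test_that("metrics match direct formula evaluation and flag undefined cases", {
  cm <- confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                  c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))
  m <- metrics(cm)
  expect_equal(unname(m), c(0.7, 0.75, 0.6, 0.675))

  perfect <- metrics(confusion(c(1, 0), c(1, 0)))
  expect_equal(unname(perfect), rep(1, 4))

  degenerate <- metrics(confusion(c(1, 1), c(0, 0)))
  expect_identical(unname(degenerate["recall"]), 0)
  expect_true(is.na(degenerate["precision"]))

  std <- metrics(cm, variant = "standard")
  expect_equal(unname(std["balanced_accuracy"]), (0.6 + 0.8) / 2)
})

test_that("metrics agree with brute-force recomputation on random sets", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rbinom(n, 1, 0.5)
    p <- rbinom(n, 1, runif(1, 0.2, 0.8))
    m <- metrics(confusion(y, p))
    b <- brute_metrics(y, p)
    expect_identical(is.na(m), is.na(b))
    expect_equal(m[!is.na(m)], b[!is.na(b)], tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the pairwise oracle, exhaustively at small n", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.4))$auc, 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(123)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- sample(round(runif(n), sample(1:3, 1)))  # plenty of ties
    expect_equal(roc_auc(y, s)$auc, pairwise_auc(y, s), tolerance = 1e-12)
  }
})

test_that("ROC curves run from (0,0) to (1,1) with monotone rates", {
  set.seed(5)
  y <- rbinom(30, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- runif(30)
  r <- roc_auc(y, s)$curve
  expect_equal(r$TPR[1], 0)
  expect_equal(r$FPR[1], 0)
  expect_equal(r$TPR[nrow(r)], 1)
  expect_equal(r$FPR[nrow(r)], 1)
  expect_true(all(diff(r$TPR) >= 0))
  expect_true(all(diff(r$FPR) >= 0))
  expect_true(all(diff(r$threshold) < 0))
})

test_that("AUC matches an established implementation on random scores", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(30, 1, 0.5))
    s <- round(runif(32), 2)
    ours <- roc_auc(y, s)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("stratified folds partition samples with proportional class counts", {
  labels <- c(rep("good", 90), rep("artefact", 10))
  fa <- stratified_kfold(labels, k = 10, seed = 3)
  expect_identical(sort(unique(fa$fold)), 1:10)
  for (f in 1:10) {
    idx <- fa$index[fa$fold == f]
    expect_identical(sum(labels[idx] == "good"), 9L)
    expect_identical(sum(labels[idx] == "artefact"), 1L)
  }
  # partition property
  expect_identical(sort(fa$index), 1:100)

  # repeats: each sample appears once per repeat, assignments differ
  fr <- stratified_kfold(labels, k = 5, repeats = 3, seed = 3)
  for (r in 1:3) expect_identical(sort(fr$index[fr$rep == r]), 1:100)
  expect_false(identical(fr$fold[fr$rep == 1], fr$fold[fr$rep == 2]))

  # within-1-of-proportional for non-divisible counts
  labels2 <- c(rep("a", 23), rep("b", 11))
  f2 <- stratified_kfold(labels2, k = 5, seed = 1)
  for (f in 1:5) {
    idx <- f2$index[f2$fold == f]
    expect_lte(abs(sum(labels2[idx] == "a") - 23 / 5), 1)
    expect_lte(abs(sum(labels2[idx] == "b") - 11 / 5), 1)
  }

  expect_error(stratified_kfold(c(rep("a", 30), rep("b", 5)), k = 10), "b")
  expect_identical(stratified_kfold(labels, k = 10, seed = 8),
                   stratified_kfold(labels, k = 10, seed = 8))
})

test_that("variance of Laplacian scores blur correctly", {
  const <- cine_sequence(array(0.8, c(12, 12, 3)))
  expect_equal(variance_of_laplacian(const), 0)

  sharp <- tiny_phantom(seed = 4, noise_sigma = 0)
  blurred <- augment_gaussian_blur(sharp, sigma = 2)
  expect_gt(variance_of_laplacian(sharp), variance_of_laplacian(blurred))

  # checkerboard: verify against a direct double-loop evaluation
  n <- 10
  chk <- outer(1:n, 1:n, function(i, j) ((i + j) %% 2) * 2 - 1) * 0.5 + 0.5
  s <- cine_sequence(array(chk, c(n, n, 1)))
  lap <- matrix(0, n - 2, n - 2)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    lap[i - 1, j - 1] <- chk[i - 1, j] + chk[i + 1, j] + chk[i, j - 1] +
      chk[i, j + 1] - 4 * chk[i, j]
  }
  expect_equal(variance_of_laplacian(s), mean((lap - mean(lap))^2),
               tolerance = 1e-12)
})

test_that("multiclass evaluation reduces to hand-built one-vs-rest tables", {
  y <- c("good", "good", "breathing", "breathing", "mistriggering",
         "mistriggering")
  perfect <- evaluate_multiclass(y, y)
  expect_equal(unname(perfect), c(1, 1))

  # a predictor collapsing both artefact classes into "breathing"
  collapsed <- c("good", "good", "breathing", "breathing", "breathing",
                 "breathing")
  m <- evaluate_multiclass(y, collapsed)
  # breathing one-vs-rest: TP=2, FP=2, FN=0 -> precision 0.5, recall 1
  expect_equal(unname(m["breathing"]), (0.5 + 1) / 2)
  # mistriggering: TP=0, FN=2, FP=0 -> precision undefined
  expect_true(is.na(m["mistriggering"]))

  # reduction to binary when the third class is absent
  y2 <- c("good", "breathing", "breathing", "good")
  p2 <- c("good", "breathing", "good", "breathing")
  m2 <- evaluate_multiclass(y2, p2)
  bin <- metrics(confusion(as.integer(y2 == "breathing"),
                           as.integer(p2 == "breathing")))
  expect_equal(unname(m2["breathing"]), unname(bin["balanced_accuracy"]))
})
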