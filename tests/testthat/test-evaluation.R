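# Confusion counts, averaged metrics and one-vs-rest AUC

test_that("confusion counts match a hand-counted 6-sample example", {
  y_true <- c(0L, 0L, 1L, 1L, 2L, 2L)
  y_pred <- c(0L, 0L, 1L, 2L, 2L, 2L)
  cc <- confusion_counts(y_true, y_pred)
  expect_identical(unname(diag(cc$matrix)), c(2L, 1L, 2L))
  c1 <- cc$per_class[cc$per_class$class == 1L, ]
  expect_identical(c1$tp, 1L)
  expect_identical(c1$fn, 1L)
  expect_identical(c1$fp, 0L)
  expect_identical(c1$tn, 4L)
  # every class's four counts total the sample count
  expect_true(all(cc$per_class$tp + cc$per_class$fp +
                    cc$per_class$tn + cc$per_class$fn == 6L))
  # micro accuracy on this example: 5 of 6 correct
  rep <- compute_metrics(cc, "micro")
  expect_equal(rep$overall_accuracy, 5 / 6)
  expect_error(confusion_counts(0:2, 0:1), class = "omicsgsn_validation_error")
})

test_that("perfect predictions yield unit metrics and a diagonal matrix", {
  y <- rep(0:3, 5)
  cc <- confusion_counts(y, y)
  expect_true(all(cc$matrix[upper.tri(cc$matrix) | lower.tri(cc$matrix)] == 0L))
  rep <- compute_metrics(cc, "micro")
  expect_equal(c(rep$accuracy, rep$precision, rep$recall, rep$f1),
               rep(1, 4))
})

test_that("swapping y_true and y_pred transposes the confusion matrix", {
  set.seed(10)
  a <- sample(0:2, 40, TRUE); b <- sample(0:2, 40, TRUE)
  expect_identical(unname(confusion_counts(a, b)$matrix),
                   unname(t(confusion_counts(b, a)$matrix)))
})

test_that("metrics agree with an independent per-formula oracle on random
           draws, and the micro identity holds", {
  set.seed(123)
  for (rep in 1:200) {
    K <- sample(2:5, 1)
    n <- sample(10:60, 1)
    y <- sample(0:(K - 1), n, TRUE)
    p <- sample(0:(K - 1), n, TRUE)
    cc <- confusion_counts(y, p, K)
    # oracle: recount everything from scratch with the four defining sums
    tp <- sapply(0:(K - 1), function(k) sum(y == k & p == k))
    fp <- sapply(0:(K - 1), function(k) sum(y != k & p == k))
    fn <- sapply(0:(K - 1), function(k) sum(y == k & p != k))
    micro <- suppressWarnings(compute_metrics(cc, "micro"))
    expect_equal(micro$precision, sum(tp) / (sum(tp) + sum(fp)),
                 tolerance = 1e-12)
    expect_equal(micro$recall, sum(tp) / (sum(tp) + sum(fn)),
                 tolerance = 1e-12)
    # single-label multi-class: micro precision = micro recall = accuracy
    expect_equal(micro$precision, micro$recall, tolerance = 1e-12)
    expect_equal(micro$precision, mean(y == p), tolerance = 1e-12)
    macro <- suppressWarnings(compute_metrics(cc, "macro"))
    prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rec_k <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    expect_equal(macro$precision, mean(prec_k), tolerance = 1e-12)
    expect_equal(macro$recall, mean(rec_k), tolerance = 1e-12)
    f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
    expect_equal(macro$f1, mean(f1_k), tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant under consistent class relabeling", {
  set.seed(77)
  y <- sample(0:2, 60, TRUE); p <- sample(0:2, 60, TRUE)
  perm <- c(2L, 0L, 1L)
  m1 <- suppressWarnings(compute_metrics(confusion_counts(y, p, 3L), "macro"))
  m2 <- suppressWarnings(compute_metrics(
    confusion_counts(perm[y + 1L], perm[p + 1L], 3L), "macro"))
  expect_equal(m1$precision, m2$precision)
  expect_equal(m1$recall, m2$recall)
  expect_equal(m1$f1, m2$f1)
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("0/0 metric divisions report zero with a warning", {
  # class 2 never predicted and never true -> its precision/recall are 0/0
  cc <- confusion_counts(c(0L, 1L), c(0L, 1L), n_classes = 3L)
  w <- testthat::capture_warnings(rep <- compute_metrics(cc, "macro"))
  expect_true(any(grepl("0/0", w)))
  expect_true(is.finite(rep$f1))
})

test_that("AUC handles perfect ordering, ties, and matches Mann-Whitney", {
  # perfectly ordered scores
  y <- c(1L, 1L, 0L, 0L)
  p <- cbind(c(.4, .3, .8, .9), c(.6, .7, .2, .1))
  expect_equal(compute_auc(y, p), 1)
  # identical scores for everyone: 0.5 by the tie convention
  pt <- matrix(0.5, 4, 2)
  expect_equal(compute_auc(y, pt), 0.5)
  # 8-sample two-class fixture vs the exhaustive pair-counting oracle
  scores <- c(.9, .8, .7, .6, .4, .35, .3, .1)
  labs <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  probs <- cbind(1 - scores, scores)
  pos <- which(labs == 1L); neg <- which(labs == 0L)
  pairs <- expand.grid(i = pos, j = neg)
  u <- mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                   ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
  # class-0 column is the mirror image, so the macro average equals u too
  expect_equal(compute_auc(labs, probs), u)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 50
    y <- sample(0:1, n, TRUE)
    s <- round(runif(n), 2)          # rounding forces ties
    probs <- cbind(1 - s, s)
    ours <- compute_auc(y, probs)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(55)
  y <- sample(0:2, 45, TRUE)
  p <- matrix(runif(45 * 3), 45, 3)
  p <- p / rowSums(p)
  a1 <- compute_auc(y, p)
  a2 <- compute_auc(y, exp(3 * p))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("evaluate_predictions assembles a full report", {
  set.seed(21)
  y <- sample(0:2, 30, TRUE)
  p <- matrix(runif(90), 30, 3); p <- p / rowSums(p)
  rep <- suppressWarnings(evaluate_predictions(y, p))
  expect_s3_class(rep, "evaluation_report")
  expect_true(!is.na(rep$auc))
  g <- glance(rep)
  expect_identical(names(g),
                   c("accuracy", "precision", "recall", "f1", "auc", "averaging"))
  td <- tidy(rep)
  expect_identical(nrow(td), 3L)
  path <- tempfile(fileext = ".json")
  write_evaluation(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$accuracy, rep$accuracy)
})
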