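test_that("confusion matrices count pairs and keep marginals", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unname(cm), matrix(c(1L, 1L, 1L, 1L), 2))

  y <- c(0L, 1L, 2L, 2L, 1L, 0L)
  cm2 <- confusion_matrix(y, y)
  expect_equal(unname(cm2), diag(c(2L, 2L, 2L)))

  set.seed(1)
  yt <- sample(0:3, 50, replace = TRUE)
  yp <- sample(0:3, 50, replace = TRUE)
  cm3 <- confusion_matrix(yt, yp, 4)
  expect_identical(unname(rowSums(cm3)), vapply(0:3, function(k) sum(yt == k), 0))
  expect_identical(unname(colSums(cm3)), vapply(0:3, function(k) sum(yp == k), 0))
  expect_error(confusion_matrix(0:2, 0:1), "pairing")
})

test_that("binary rates reproduce the worked TP=3 TN=4 FP=2 FN=1 case", {
  # construct a 2-class confusion matrix realising those counts for class 1
  cm <- matrix(c(4L, 2L, 1L, 3L), 2, byrow = TRUE)
  r <- binary_rates(cm, 1)
  expect_identical(c(r$TP, r$TN, r$FP, r$FN), c(3L, 4L, 2L, 1L))
  expect_equal(r$ACC, 0.7)
  expect_equal(r$SE, 0.75)
  expect_equal(r$SP, 2 / 3)
  expect_equal(r$PR, 0.6)
  expect_equal(r$RE, r$SE)
  expect_equal(r$F1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(r$F1, 2 / 3)
  expect_false(r$degenerate)
})

test_that("perfect and degenerate classes behave per the stated conventions", {
  cm <- diag(c(5L, 3L))
  r <- binary_rates(cm, 0)
  expect_equal(c(r$SE, r$SP, r$PR, r$F1), rep(1, 4))

  # class never predicted and never true: 0/0 rates report 0 with a flag
  cm2 <- matrix(0L, 3, 3); cm2[1, 1] <- 4L; cm2[2, 2] <- 4L
  r2 <- binary_rates(cm2, 2)
  expect_equal(c(r2$SE, r2$PR, r2$F1), c(0, 0, 0))
  expect_true(r2$degenerate)
  expect_error(binary_rates(matrix(0L, 2, 2), 0), "empty")
})

test_that("F1 is the harmonic-mean fixed point when PR equals RE", {
  # 8 true positives, 2 false negatives, 2 false positives: PR = RE = 0.8
  cm <- matrix(c(88L, 2L, 2L, 8L), 2, byrow = TRUE)
  r <- binary_rates(cm, 1)
  expect_equal(r$PR, r$RE)
  expect_equal(r$F1, r$PR)
})

test_that("Cohen's kappa matches hand-computed cases", {
  expect_equal(cohen_kappa(0:4, 0:4)$kappa, 1)
  k <- cohen_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(k$Po, 0.5); expect_equal(k$Pe, 0.5); expect_equal(k$kappa, 0)
  # confusion [[2,1],[1,2]]: Po 4/6, Pe 1/2, kappa 1/3
  yt <- c(0, 0, 0, 1, 1, 1)
  yp <- c(0, 0, 1, 0, 1, 1)
  k2 <- cohen_kappa(yt, yp)
  expect_equal(k2$Po, 4 / 6); expect_equal(k2$Pe, 0.5)
  expect_equal(k2$kappa, 1 / 3)
  # single shared category is flagged degenerate
  k3 <- cohen_kappa(c(1, 1), c(1, 1))
  expect_true(k3$degenerate); expect_equal(k3$kappa, 1)
})

test_that("kappa and AUC agree with brute-force oracles on 200 random sets", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    K <- sample(2:5, 1)
    yt <- sample(0:(K - 1), n, replace = TRUE)
    yp <- sample(0:(K - 1), n, replace = TRUE)
    if (length(union(yt, yp)) < 2) next
    k <- cohen_kappa(yt, yp)
    if (!k$degenerate)
      expect_equal(k$kappa, kappa_bruteforce(yt, yp), tolerance = 1e-9)

    scores <- matrix(rnorm(n * K), n, K)
    if (sample(c(TRUE, FALSE), 1)) # exercise the tie path too
      scores <- round(scores, 1)
    a <- roc_auc_ovr(yt, scores)
    for (kk in 1:K) {
      pos <- yt == (kk - 1)
      if (sum(pos) == 0 || sum(!pos) == 0) {
        expect_true(is.na(a$per_class[kk]))
        next
      }
      expect_equal(unname(a$per_class[kk]),
                   auc_bruteforce(scores[pos, kk], scores[!pos, kk]),
                   tolerance = 1e-9)
    }
  }
})

test_that("AUC endpoints and tie convention hold", {
  yt <- c(1, 1, 0, 0)
  perfect <- cbind(c(0.1, 0.2, 0.9, 0.8), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(roc_auc_ovr(yt, perfect)$per_class), c(1, 1))
  expect_equal(unname(roc_auc_ovr(yt, -perfect)$per_class), c(0, 0))
  flat <- matrix(0.5, 4, 2)
  expect_equal(unname(roc_auc_ovr(yt, flat)$per_class), c(0.5, 0.5))
  expect_equal(roc_auc_ovr(yt, flat)$macro, 0.5)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  yt <- sample(0:1, 60, replace = TRUE)
  s <- rnorm(60) + yt
  ours <- roc_auc_ovr(yt, cbind(-s, s))$per_class[2]
  ref <- as.numeric(pROC::auc(pROC::roc(yt, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(unname(ours), ref, tolerance = 1e-9)
})

test_that("full reports aggregate correctly for perfect predictions", {
  y <- rep(0:4, each = 4)
  rep_ <- multiclass_report(y, y)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
  expect_equal(rep_$macro_sensitivity, 1)
  expect_equal(rep_$macro_f1, 1)
  g <- glance(rep_)
  expect_identical(nrow(g), 1L)
  expect_equal(g$accuracy, 1)
  td <- tidy(rep_)
  expect_identical(nrow(td), 5L)
  expect_identical(td$class, ecg_classes)
})

test_that("uniform random predictions sit at chance level", {
  set.seed(0)
  n <- 10000
  yt <- sample(0:4, n, replace = TRUE)
  yp <- sample(0:4, n, replace = TRUE)
  rep_ <- multiclass_report(yt, yp)
  expect_equal(rep_$accuracy, 0.2, tolerance = 0.02 / 0.2)
  expect_lt(abs(rep_$kappa), 0.03)
  # accuracy is the micro-average recall
  expect_equal(rep_$accuracy, rep_$micro_recall)
})

test_that("macro F1 is invariant under class relabelling", {
  set.seed(10)
  yt <- sample(0:3, 200, replace = TRUE)
  yp <- sample(0:3, 200, replace = TRUE)
  perm <- c(2L, 0L, 3L, 1L)
  r1 <- multiclass_report(yt, yp, n_classes = 4)
  r2 <- multiclass_report(perm[yt + 1L], perm[yp + 1L], n_classes = 4)
  expect_equal(r1$macro_f1, r2$macro_f1)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$kappa, r2$kappa)
})

test_that("rates stay in range over fuzzed inputs", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    K <- sample(2:6, 1)
    yt <- sample(0:(K - 1), n, replace = TRUE)
    yp <- sample(0:(K - 1), n, replace = TRUE)
    r <- multiclass_report(yt, yp, n_classes = K)
    rates <- c(r$accuracy, r$per_class$sensitivity, r$per_class$specificity,
               r$per_class$precision, r$per_class$f1)
    expect_true(all(rates >= 0 & rates <= 1))
    expect_true(r$kappa >= -1 && r$kappa <= 1)
  }
})
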