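mk_tagged <- function(counts) {
  n <- sum(counts)
  labels <- rep(seq_along(counts) - 1L, counts)
  beats <- matrix(seq_len(n), n, 1) # tag each row with its source index
  list(beats = beats, labels = labels)
}

test_that("resampling balances classes exactly, up and down", {
  d <- mk_tagged(c(A = 100, B = 7, C = 30))
  r <- resample_to_balance(d$beats, d$labels, target_per_class = 20, seed = 1)
  expect_identical(unname(table(r$labels)), table(rep(0:2, each = 20)) |> unname())

  # class above target: all distinct source rows; below target: duplicates
  rows_a <- r$beats[r$labels == 0L, 1]
  rows_b <- r$beats[r$labels == 1L, 1]
  expect_identical(anyDuplicated(rows_a), 0L)
  expect_gt(sum(duplicated(rows_b)), 0)
  expect_true(all(rows_b %in% which(d$labels == 1L)))

  r1 <- resample_to_balance(d$beats, d$labels, 20, seed = 9)
  r2 <- resample_to_balance(d$beats, d$labels, 20, seed = 9)
  expect_identical(r1, r2)

  tiny <- resample_to_balance(d$beats, d$labels, 1, seed = 1)
  expect_identical(sort(unique(tiny$labels)), 0:2)
  expect_identical(length(tiny$labels), 3L)
})

test_that("resampling preserves row/label pairing", {
  d <- mk_tagged(c(40, 5))
  r <- resample_to_balance(d$beats, d$labels, 10, seed = 2)
  # every drawn row's tag must map back to a source row of the same class
  expect_true(all(d$labels[r$beats[, 1]] == r$labels))
  expect_identical(sort(unique(r$labels)), sort(unique(d$labels)))
})

test_that("majority subsampling reduces only the majority class", {
  d <- mk_tagged(c(500, 30, 20))
  s <- subsample_majority(d$beats, d$labels, majority_class = 0, n_keep = 50,
                          seed = 3)
  expect_identical(unname(table(s$labels)), table(rep(0:2, c(50, 30, 20))) |> unname())
  kept <- s$beats[s$labels == 0L, 1]
  expect_identical(anyDuplicated(kept), 0L)

  s1 <- subsample_majority(d$beats, d$labels, 0, 50, seed = 3)
  s2 <- subsample_majority(d$beats, d$labels, 0, 50, seed = 4)
  expect_false(identical(sort(s1$beats[s1$labels == 0L, 1]),
                         sort(s2$beats[s2$labels == 0L, 1])))

  ident <- subsample_majority(d$beats, d$labels, 0, 500, seed = 1)
  expect_identical(sort(ident$beats[ident$labels == 0L, 1]),
                   which(d$labels == 0L))
  expect_error(subsample_majority(d$beats, d$labels, 1, 100, seed = 1),
               "insufficient")
})

test_that("train/test split follows the floor rule and partitions the data", {
  d <- mk_tagged(c(50, 50))
  sp <- split_train_test(d$beats, d$labels, 0.8, stratified = TRUE, seed = 5)
  expect_identical(length(sp$train$labels), 80L)
  expect_identical(length(sp$test$labels), 20L)
  expect_identical(unname(table(sp$train$labels)), table(rep(0:1, 40)) |> unname())
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(100))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  small <- mk_tagged(c(5))
  sp2 <- split_train_test(small$beats, small$labels, 0.8,
                          stratified = FALSE, seed = 1)
  expect_identical(length(sp2$train$labels), 4L)
  expect_identical(length(sp2$test$labels), 1L)
  expect_error(split_train_test(matrix(0, 0, 1), integer(0)), "empty")
})

test_that("k-fold indices partition rows with near-equal sizes", {
  folds <- kfold_indices(10, 5, seed = 1)
  expect_identical(lengths(folds), rep(2L, 5))
  folds11 <- kfold_indices(11, 5, seed = 1)
  expect_identical(sort(lengths(folds11), decreasing = TRUE),
                   c(3L, 2L, 2L, 2L, 2L))
  expect_identical(sort(unlist(folds11)), 1:11)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(folds11[[i]], folds11[[j]]), 0)
  expect_identical(kfold_indices(11, 5, seed = 2), kfold_indices(11, 5, seed = 2))
  expect_error(kfold_indices(3, 5), "folds")
})

test_that("resampling never invents labels", {
  d <- mk_tagged(c(12, 3, 9))
  r <- resample_to_balance(d$beats, d$labels, 6, seed = 7)
  expect_true(all(r$labels %in% d$labels))
  s <- subsample_majority(d$beats, d$labels, 0, 5, seed = 7)
  expect_true(all(s$labels %in% d$labels))
})
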