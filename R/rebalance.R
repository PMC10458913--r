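#' Resample every class to a common size
#'
#' Brings each class to exactly `target_per_class` rows: classes above the
#' target are downsampled without replacement, classes below it are
#' upsampled with replacement. Row/label pairing is preserved; the result is
#' exactly class-balanced.
#'
#' @param beats Numeric matrix, one beat per row.
#' @param labels Integer class labels, one per row.
#' @param target_per_class Desired per-class count (default 20000, the
#'   balanced corpus size used by the five-class benchmark).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List with resampled `beats` and `labels`.
#' @export
resample_to_balance <- function(beats, labels, target_per_class = 20000,
                                seed = 0) {
  beats <- as.matrix(beats)
  stopifnot(nrow(beats) == length(labels))
  target_per_class <- check_count(target_per_class, "target_per_class", min = 1L)
  classes <- sort(unique(labels))
  if (length(classes) == 0L) stop("empty dataset", call. = FALSE)
  idx <- with_local_seed(seed, {
    unlist(lapply(classes, function(k) {
      rows <- which(labels == k)
      if (length(rows) >= target_per_class)
        sample(rows, target_per_class, replace = FALSE)
      else
        sample(rows, target_per_class, replace = TRUE)
    }))
  })
  list(beats = beats[idx, , drop = FALSE], labels = labels[idx])
}

#' Subsample the majority class
#'
#' Reduces the (overrepresented) majority class to exactly `n_keep` rows
#' drawn uniformly without replacement; all other classes pass through
#' untouched.
#'
#' @inheritParams resample_to_balance
#' @param majority_class Class id to subsample (default 0, the normal-beat
#'   class).
#' @param n_keep Rows to retain from the majority class (default 5000).
#' @return List with reduced `beats` and `labels`.
#' @export
subsample_majority <- function(beats, labels, majority_class = 0,
                               n_keep = 5000, seed = 0) {
  beats <- as.matrix(beats)
  stopifnot(nrow(beats) == length(labels))
  n_keep <- check_count(n_keep, "n_keep", min = 1L)
  maj <- which(labels == majority_class)
  if (length(maj) < n_keep)
    stop(sprintf(
      "insufficient samples: class %s has %d rows, cannot keep %d",
      format(majority_class), length(maj), n_keep), call. = FALSE)
  keep_maj <- with_local_seed(seed, sample(maj, n_keep, replace = FALSE))
  idx <- sort(c(setdiff(seq_along(labels), maj), keep_maj))
  list(beats = beats[idx, , drop = FALSE], labels = labels[idx])
}

#' Split a dataset into training and test partitions
#'
#' Default is a stratified 80:20 split: within each class,
#' `floor(train_fraction * n_k)` rows go to training and the remainder to
#' test, so the partitions are disjoint and exhaustive. Unstratified splits
#' use the same floor rule on the whole dataset.
#'
#' @inheritParams resample_to_balance
#' @param train_fraction Fraction of rows assigned to training
#'   (default 0.8).
#' @param stratified Stratify by class (default `TRUE`).
#' @return List with `train` and `test`, each a list of `beats` and
#'   `labels`, plus the row indices used (`train_idx`, `test_idx`).
#' @export
split_train_test <- function(beats, labels, train_fraction = 0.8,
                             stratified = TRUE, seed = 0) {
  beats <- as.matrix(beats)
  n <- nrow(beats)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  stopifnot(nrow(beats) == length(labels),
            train_fraction > 0, train_fraction < 1)
  train_idx <- with_local_seed(seed, {
    if (stratified) {
      unlist(lapply(sort(unique(labels)), function(k) {
        rows <- which(labels == k)
        sample(rows, floor(train_fraction * length(rows)))
      }))
    } else {
      sample.int(n, floor(train_fraction * n))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = list(beats = beats[train_idx, , drop = FALSE],
                    labels = labels[train_idx]),
       test = list(beats = beats[test_idx, , drop = FALSE],
                   labels = labels[test_idx]),
       train_idx = train_idx, test_idx = test_idx)
}

#' Disjoint cross-validation folds
#'
#' Partitions row indices `1..n` into `k` folds whose sizes differ by at
#' most one (the first `n %% k` folds get the extra row), after a seeded
#' shuffle.
#'
#' @param n Number of rows.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer vectors of 1-based row indices.
#' @export
#' @examples
#' lengths(kfold_indices(11, 5))
kfold_indices <- function(n, k = 5, seed = 0) {
  n <- check_count(n, "n", min = 1L)
  k <- check_count(k, "k", min = 2L)
  if (n < k)
    stop(sprintf("cannot make %d folds from %d rows", k, n), call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}
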