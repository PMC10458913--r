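# Shared fixtures, all generated in code.

# Two well-separated 2-D Gaussian clusters (the separable SVM fixture).
separable_clusters <- function(n_per = 20, centers = c(-5, 5), sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  features <- rbind(
    matrix(rnorm(2 * n_per, centers[1], sd), n_per, 2),
    matrix(rnorm(2 * n_per, centers[2], sd), n_per, 2))
  list(features = features, labels = rep(c(0L, 1L), each = n_per))
}

# Small noise-free, well-separated beat set: `per_class` beats per class.
clean_beat_set <- function(per_class = 10, beat_length = 187, seed = 1) {
  generate_dataset(stats::setNames(rep(per_class, 5), 0:4),
                   beat_length = beat_length, spec = noise_spec(),
                   seed = seed)
}

# Tiny fast network configuration for training tests.
tiny_rdcnn <- function(...) {
  rdcnn_config(num_res_blocks = 1, num_dense_blocks = 1, num_res_layers = 1,
               num_dense_layers = 1, filters = 8, kernel = 3, head_units = 16,
               dropout_rate = 0, n_classes = 5, ...)
}

# Brute-force Cohen's kappa from the full contingency table.
kappa_bruteforce <- function(y_true, y_pred) {
  cats <- sort(union(y_true, y_pred))
  tab <- outer(cats, cats, Vectorize(function(a, b)
    sum(y_true == a & y_pred == b)))
  n <- length(y_true)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Brute-force AUC by counting over all positive-negative pairs.
auc_bruteforce <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores)
    wins <- wins + sum(p > neg_scores) + 0.5 * sum(p == neg_scores)
  wins / (length(pos_scores) * length(neg_scores))
}
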