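#' Fit a one-versus-all support vector machine
#'
#' Trains one binary maximum-margin classifier per class (class versus
#' rest) on extracted features. The default kernel is linear with `C = 1`,
#' matching a linear SVM head; a radial-basis kernel (with its gamma) is
#' selectable. Binary problems are solved by libsvm (via e1071) at a fixed
#' tolerance of 1e-4, recorded in the model for reproducibility.
#'
#' @param features Numeric feature matrix, one row per observation.
#' @param labels Integer class labels (at least two distinct classes).
#' @param C Regularisation cost (> 0, default 1).
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param gamma RBF kernel width (default 1e-4; ignored for linear).
#' @param seed Integer seed (the solver is deterministic at fixed tolerance;
#'   the seed is kept for interface uniformity and recorded).
#' @return An object of class `ova_svm` holding one binary classifier per
#'   class in increasing class order; for the linear kernel each also
#'   carries its primal hyperplane (`w`, `b`).
#' @export
fit_ova_svm <- function(features, labels, C = 1, kernel = c("linear", "rbf"),
                        gamma = 1e-4, seed = 0) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), C > 0)
  if (!all(is.finite(features)))
    stop("features must be finite", call. = FALSE)
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2L)
    stop("degenerate labels: need at least two classes", call. = FALSE)
  tolerance <- 1e-4
  fits <- lapply(classes, function(k) {
    y <- factor(ifelse(labels == k, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(features, y, scale = FALSE, cost = C,
                      kernel = if (kernel == "linear") "linear" else "radial",
                      gamma = if (kernel == "rbf") gamma else 1 / ncol(features),
                      tolerance = tolerance)
    out <- list(fit = fit)
    if (kernel == "linear") {
      w <- drop(t(fit$coefs) %*% fit$SV)
      out$w <- w
      out$b <- -fit$rho
    }
    out
  })
  structure(list(classes = classes, fits = fits, C = C, kernel = kernel,
                 gamma = gamma, tolerance = tolerance, seed = seed,
                 n_features = ncol(features)),
            class = "ova_svm")
}

#' @export
print.ova_svm <- function(x, ...) {
  cat(sprintf("<ova_svm> %d binary classifiers (%s kernel, C = %g)\n",
              length(x$fits), x$kernel, x$C))
  invisible(x)
}

#' Predict labels from a one-versus-all SVM
#'
#' Evaluates every per-class decision function and assigns each row the
#' class with the largest decision value; exact ties break to the lowest
#' class id. The raw decision scores are returned for downstream ROC/AUC
#' computation.
#'
#' @param model An [fit_ova_svm()] result.
#' @param features Feature matrix with the same column count used in
#'   fitting.
#' @return List with `labels` (integer predictions) and `scores`
#'   (`n x n_classes` matrix of decision values, columns in class order).
#' @export
predict_labels <- function(model, features) {
  stopifnot(inherits(model, "ova_svm"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(features), model$n_features), call. = FALSE)
  scores <- vapply(model$fits, function(f) {
    p <- predict(f$fit, features, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # orient so larger means "this class" regardless of libsvm level order
    if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
  }, numeric(nrow(features)))
  scores <- matrix(scores, nrow = nrow(features))
  colnames(scores) <- as.character(model$classes)
  labels <- model$classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

#' Margin of a separating hyperplane
#'
#' Width of the margin associated with a weight vector, computed as
#' `d = 2 / ||w||^2`. Note this follows the source formulation; the textbook
#' geometric margin is `2 / ||w||`.
#'
#' @param w Non-zero numeric weight vector.
#' @return The scalar margin `2 / sum(w^2)`.
#' @export
#' @examples
#' decision_margin(c(3, 4)) # 2 / 25
decision_margin <- function(w) {
  stopifnot(is.numeric(w))
  nrm2 <- sum(w^2)
  if (nrm2 == 0)
    stop("undefined margin: weight vector is zero", call. = FALSE)
  2 / nrm2
}
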