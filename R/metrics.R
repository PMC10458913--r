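#' Confusion matrix
#'
#' `K x K` table of counts with rows indexing the true class and columns the
#' predicted class: entry `(i, j)` counts observations of true class `i - 1`
#' predicted as class `j - 1`.
#'
#' @param y_true,y_pred Equal-length integer label vectors with values in
#'   `0..(n_classes - 1)`.
#' @param n_classes Number of classes (default: one more than the largest
#'   label seen).
#' @return Integer matrix with class ids as dimnames.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 0, 1))
confusion_matrix <- function(y_true, y_pred,
                             n_classes = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred))
    stop("pairing error: y_true and y_pred differ in length", call. = FALSE)
  if (length(y_true) == 0L) stop("empty evaluation", call. = FALSE)
  n_classes <- check_count(n_classes, "n_classes", min = 1L)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= n_classes | y_pred < 0L | y_pred >= n_classes))
    stop("labels outside 0..(n_classes-1)", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' One-versus-rest rates for a single class
#'
#' Reduces a multiclass confusion matrix to the binary problem "class k
#' versus rest" and evaluates the standard rates: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, recall (= sensitivity) and the F1
#' score `2*PR*RE/(PR+RE)`. A zero-denominator rate is reported as 0 and
#' flagged.
#'
#' @param cm A [confusion_matrix()].
#' @param class_id Class id (0-based) to treat as positive.
#' @return Named list with `TP`, `TN`, `FP`, `FN`, `ACC`, `SE`, `SP`, `PR`,
#'   `RE`, `F1` and a logical `degenerate` flag.
#' @export
binary_rates <- function(cm, class_id) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) == 0) stop("empty evaluation: confusion matrix is empty",
                         call. = FALSE)
  k <- check_count(class_id, "class_id") + 1L
  stopifnot(k >= 1L, k <= nrow(cm))
  TP <- cm[k, k]
  FN <- sum(cm[k, ]) - TP
  FP <- sum(cm[, k]) - TP
  TN <- sum(cm) - TP - FN - FP
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  SE <- safe(TP, TP + FN)
  SP <- safe(TN, TN + FP)
  PR <- safe(TP, TP + FP)
  F1 <- safe(2 * PR * SE, PR + SE)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       ACC = (TP + TN) / (TP + TN + FP + FN),
       SE = SE, SP = SP, PR = PR, RE = SE, F1 = F1,
       degenerate = degenerate)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors:
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement `Po` (the
#' accuracy) and expected agreement `Pe = sum_k row_k * col_k / n^2` from
#' the confusion-matrix marginals. If `Pe = 1` (a single shared category)
#' kappa is 1 when agreement is perfect and 0 otherwise, flagged degenerate.
#'
#' @param y_true,y_pred Equal-length nonempty label vectors.
#' @return List with `kappa`, `Po`, `Pe` and a `degenerate` flag.
#' @export
#' @examples
#' cohen_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1)) # kappa 0
cohen_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("pairing error: y_true and y_pred differ in length", call. = FALSE)
  n <- length(y_true)
  if (n == 0L) stop("empty evaluation", call. = FALSE)
  Po <- mean(y_true == y_pred)
  cats <- union(y_true, y_pred)
  rowm <- vapply(cats, function(k) sum(y_true == k), 0)
  colm <- vapply(cats, function(k) sum(y_pred == k), 0)
  Pe <- sum(rowm * colm) / n^2
  if (abs(1 - Pe) < 1e-15) {
    return(list(kappa = if (Po == 1) 1 else 0, Po = Po, Pe = Pe,
                degenerate = TRUE))
  }
  list(kappa = (Po - Pe) / (1 - Pe), Po = Po, Pe = Pe, degenerate = FALSE)
}

#' One-versus-rest ROC AUC
#'
#' Per class, the rank statistic of the class-versus-rest scores: the
#' probability that a random positive outranks a random negative, with tied
#' scores contributing 1/2 (equivalent to trapezoidal ROC integration).
#' The macro AUC is the unweighted mean over classes present in `y_true`;
#' classes with a score column but no positive (or no negative) example are
#' skipped and reported.
#'
#' @param y_true Integer labels.
#' @param scores `n x K` matrix of per-class decision values, columns in
#'   class-id order (0-based).
#' @return List with `macro`, `per_class` (named numeric, `NA` for skipped
#'   classes) and `skipped` (class ids).
#' @export
roc_auc_ovr <- function(y_true, scores) {
  scores <- as.matrix(scores)
  stopifnot(length(y_true) == nrow(scores))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  K <- ncol(scores)
  per_class <- rep(NA_real_, K)
  names(per_class) <- as.character(0:(K - 1L))
  for (k in seq_len(K)) {
    pos <- y_true == (k - 1L)
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) next
    r <- rank(scores[, k]) # average ranks handle ties as 1/2
    per_class[k] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  skipped <- as.integer(names(per_class)[is.na(per_class)])
  list(macro = mean(per_class, na.rm = TRUE), per_class = per_class,
       skipped = skipped)
}

#' Full multiclass evaluation report
#'
#' Computes the evaluation suite on predicted labels: overall accuracy,
#' per-class and macro (unweighted mean) sensitivity, specificity,
#' precision, recall and F1, Cohen's kappa with its observed and expected
#' agreements, and — when decision scores are supplied — macro
#' one-versus-rest AUC.
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param scores Optional `n x K` decision-score matrix for AUC.
#' @param n_classes Number of classes (default inferred).
#' @return An object of class `metrics_report`; see [tidy.metrics_report()]
#'   and [glance.metrics_report()] for tabular access.
#' @export
multiclass_report <- function(y_true, y_pred, scores = NULL,
                              n_classes = max(y_true, y_pred) + 1L) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  K <- nrow(cm)
  per <- lapply(0:(K - 1L), function(k) binary_rates(cm, k))
  per_tbl <- tibble::tibble(
    class_id = 0:(K - 1L),
    class = if (K == 5L) ecg_classes else as.character(0:(K - 1L)),
    support = as.integer(rowSums(cm)),
    sensitivity = vapply(per, `[[`, 0, "SE"),
    specificity = vapply(per, `[[`, 0, "SP"),
    precision = vapply(per, `[[`, 0, "PR"),
    recall = vapply(per, `[[`, 0, "RE"),
    f1 = vapply(per, `[[`, 0, "F1"),
    degenerate = vapply(per, `[[`, TRUE, "degenerate")
  )
  kap <- cohen_kappa(y_true, y_pred)
  auc <- if (!is.null(scores)) roc_auc_ovr(y_true, scores) else NULL
  structure(list(
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_tbl,
    macro_sensitivity = mean(per_tbl$sensitivity),
    macro_specificity = mean(per_tbl$specificity),
    macro_precision = mean(per_tbl$precision),
    macro_recall = mean(per_tbl$recall),
    macro_f1 = mean(per_tbl$f1),
    micro_recall = sum(diag(cm)) / sum(cm),
    kappa = kap$kappa, Po = kap$Po, Pe = kap$Pe,
    auc_macro = if (!is.null(auc)) auc$macro else NA_real_,
    auc_per_class = if (!is.null(auc)) auc$per_class else NULL,
    confusion = cm, n = sum(cm)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  accuracy %.*f | macro SE %.*f SP %.*f PR %.*f F1 %.*f\n",
              digits, x$accuracy, digits, x$macro_sensitivity,
              digits, x$macro_specificity, digits, x$macro_precision,
              digits, x$macro_f1))
  cat(sprintf("  kappa %.*f (Po %.*f, Pe %.*f)", digits, x$kappa,
              digits, x$Po, digits, x$Pe))
  if (!is.na(x$auc_macro)) cat(sprintf(" | macro AUC %.*f", digits, x$auc_macro))
  cat("\n")
  invisible(x)
}

#' Tidy per-class metrics
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: support, sensitivity, specificity,
#'   precision, recall, F1 and (when available) one-versus-rest AUC.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$auc_per_class)) out$auc <- unname(x$auc_per_class)
  out
}

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.metrics_report
#' @return One-row tibble with the scalar metrics (accuracy, macro rates,
#'   kappa and its components, macro AUC, n).
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_sensitivity = x$macro_sensitivity,
    macro_specificity = x$macro_specificity,
    macro_precision = x$macro_precision,
    macro_f1 = x$macro_f1,
    kappa = x$kappa, Po = x$Po, Pe = x$Pe,
    auc_macro = x$auc_macro, n = x$n
  )
}
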