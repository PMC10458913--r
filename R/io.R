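#' Read a fixed-length beat dataset from delimited text
#'
#' Reads the widely used pre-segmented heartbeat CSV dialect: one beat per
#' row, waveform samples first, the integer class label as the final column,
#' no header. Row order is preserved.
#'
#' @param path File to read.
#' @param delimiter Field delimiter (default `","`).
#' @return List with `beats` (numeric matrix, one beat per row) and `labels`
#'   (integer vector of class ids).
#' @export
read_beats <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nf <- count.fields(path, sep = delimiter, blank.lines.skip = TRUE)
  if (length(nf) == 0L)
    return(list(beats = matrix(0, 0, 0), labels = integer(0)))
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged rows: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  if (nf[1] < 2L)
    stop("each row needs at least one sample column plus a label column",
         call. = FALSE)
  m <- as.matrix(read.table(path, sep = delimiter, header = FALSE,
                            colClasses = "numeric"))
  dimnames(m) <- NULL
  lab <- m[, ncol(m)]
  if (any(!is.finite(lab)) || any(lab != round(lab))) {
    bad <- which(!is.finite(lab) | lab != round(lab))[1]
    stop(sprintf("non-integral label on line %d: %s", bad, format(lab[bad])),
         call. = FALSE)
  }
  list(beats = m[, -ncol(m), drop = FALSE], labels = as.integer(lab))
}

#' Write a beat dataset as delimited text
#'
#' Inverse of [read_beats()]: one row per beat, samples then label, no
#' header, full double precision (round-trips within 1e-9).
#'
#' @param beats Numeric matrix, one beat per row.
#' @param labels Integer class labels, one per row of `beats`.
#' @inheritParams read_beats
#' @return The path, invisibly.
#' @export
write_beats <- function(beats, labels, path, delimiter = ",") {
  beats <- as.matrix(beats)
  if (nrow(beats) != length(labels))
    stop(sprintf("pairing error: %d beats but %d labels",
                 nrow(beats), length(labels)), call. = FALSE)
  if (nrow(beats) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- cbind(as.data.frame(format(beats, digits = 15, trim = TRUE)),
              label = as.integer(labels))
  write.table(df, path, sep = delimiter, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Per-class counts of a label vector
#'
#' Tabulates a label vector over the full class range (including classes with
#' zero observations), in the layout of the standard five-class corpus
#' summaries. The counts always sum to `length(labels)`.
#'
#' @param labels Integer class ids.
#' @param n_classes Number of classes (default 5).
#' @return A tibble with columns `class_id`, `class` (beat code for the
#'   five-class case, otherwise the id as character) and `count`, plus a
#'   `total` attribute.
#' @export
#' @examples
#' summarize_dataset(c(0L, 0L, 1L, 4L))
summarize_dataset <- function(labels, n_classes = 5) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  n_classes <- check_count(n_classes, "n_classes", min = 1L)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes))
    stop("labels outside 0..(n_classes-1)", call. = FALSE)
  counts <- tabulate(labels + 1L, nbins = n_classes)
  code <- if (n_classes == 5L) ecg_classes else as.character(seq_len(n_classes) - 1L)
  out <- tibble::tibble(class_id = seq_len(n_classes) - 1L,
                        class = code, count = counts)
  attr(out, "total") <- sum(counts)
  out
}
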