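#' Denoiser configuration
#'
#' Collects every tunable of the beat-level denoising pipeline. Stages run in
#' the fixed order interpolate -> baseline -> notch -> wavelet ->
#' z-normalise; each can be toggled independently, and a disabled stage is
#' the identity map.
#'
#' @param interpolation_kind `"linear"` or `"cubic"` gap interpolation.
#' @param baseline_window_short,baseline_window_long Running-median window
#'   lengths in seconds for the two-pass baseline estimate (defaults 0.2 s
#'   and 0.8 s; the short pass flattens QRS-scale deflections, the long
#'   pass keeps only sub-Hz trends).
#' @param notch_freq,notch_quality Notch centre frequency in Hz (50 Hz mains
#'   default) and dimensionless quality factor (default 30).
#' @param wavelet_family `"db2"`, `"db4"` (default) or `"db8"` Daubechies
#'   wavelet (named by tap count as in common wavelet libraries).
#' @param decomposition_levels Number of dyadic decomposition levels
#'   (default 4).
#' @param threshold_rule `"universal-soft"` (default) or `"universal-hard"`
#'   shrinkage of detail coefficients.
#' @param stages Named logical vector enabling the `interpolate`, `baseline`,
#'   `notch` and `wavelet` stages.
#' @param znormalize Whether to z-normalise each beat after filtering.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(interpolation_kind = c("linear", "cubic"),
                           baseline_window_short = 0.2,
                           baseline_window_long = 0.8,
                           notch_freq = 50, notch_quality = 30,
                           wavelet_family = c("db4", "db2", "db8"),
                           decomposition_levels = 4,
                           threshold_rule = c("universal-soft", "universal-hard"),
                           stages = c(interpolate = TRUE, baseline = TRUE,
                                      notch = TRUE, wavelet = TRUE),
                           znormalize = TRUE) {
  stopifnot(baseline_window_short > 0, baseline_window_long > 0,
            notch_freq > 0, notch_quality > 0, decomposition_levels >= 1)
  defaults <- c(interpolate = TRUE, baseline = TRUE, notch = TRUE, wavelet = TRUE)
  defaults[names(stages)] <- stages
  cfg <- list(
    interpolation_kind = match.arg(interpolation_kind),
    baseline_window_short = baseline_window_short,
    baseline_window_long = baseline_window_long,
    notch_freq = notch_freq, notch_quality = notch_quality,
    wavelet_family = match.arg(wavelet_family),
    decomposition_levels = check_count(decomposition_levels,
                                       "decomposition_levels", min = 1L),
    threshold_rule = match.arg(threshold_rule),
    stages = defaults, znormalize = isTRUE(znormalize)
  )
  class(cfg) <- "denoise_config"
  cfg
}

#' Fill contact-loss gaps by interpolation
#'
#' Replaces masked (lost) samples with values interpolated from the observed
#' samples; gaps touching a beat edge are filled with the nearest observed
#' value (constant extension). Observed samples are never altered.
#'
#' @param beat Numeric waveform, possibly containing `NA` at lost samples.
#' @param mask Logical vector flagging lost samples; defaults to
#'   `is.na(beat)`.
#' @param kind `"linear"` (default) or `"cubic"`.
#' @return Finite numeric waveform of the same length.
#' @export
interpolate_missing <- function(beat, mask = is.na(beat),
                                kind = c("linear", "cubic")) {
  kind <- match.arg(kind)
  stopifnot(length(mask) == length(beat))
  if (!any(mask)) return(beat)
  obs <- which(!mask)
  if (length(obs) == 0L)
    stop("unrecoverable beat: every sample is missing", call. = FALSE)
  miss <- which(mask)
  out <- beat
  if (length(obs) == 1L) {
    out[miss] <- beat[obs]
    return(out)
  }
  if (kind == "linear") {
    out[miss] <- approx(obs, beat[obs], xout = miss, rule = 2)$y
  } else {
    out[miss] <- spline(obs, beat[obs], xout = miss, method = "natural")$y
    # constant extension outside the observed range
    out[miss[miss < min(obs)]] <- beat[min(obs)]
    out[miss[miss > max(obs)]] <- beat[max(obs)]
  }
  out
}

# Internal: odd running-median window of `seconds` at `fs`, >= 3 samples.
odd_window <- function(seconds, fs) {
  w <- max(3L, as.integer(round(seconds * fs)))
  if (w %% 2L == 0L) w + 1L else w
}

#' Remove baseline wander with a two-pass running median
#'
#' Estimates the slow baseline as a running median with a short window
#' followed by one with a long window (robust to QRS peaks), then subtracts
#' the estimate. Cardiac deflections are much narrower than the long window,
#' so they do not leak into the estimate.
#'
#' @param beat Finite numeric waveform.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_short,window_long Window lengths in seconds
#'   (defaults 0.2 / 0.8).
#' @return Waveform with the baseline estimate subtracted.
#' @export
remove_baseline_drift <- function(beat, sampling_rate = 125,
                                  window_short = 0.2, window_long = 0.8) {
  stopifnot(is.numeric(beat), all(is.finite(beat)))
  ws <- odd_window(window_short, sampling_rate)
  wl <- odd_window(window_long, sampling_rate)
  n <- length(beat)
  if (max(ws, wl) > n)
    stop(sprintf("baseline window of %d samples exceeds beat length %d",
                 max(ws, wl), n), call. = FALSE)
  # odd-reflection padding continues the local trend at the beat edges, so
  # the medians see full windows and drift is tracked to the boundary
  pad <- min(n - 1L, wl)
  ext <- c(2 * beat[1] - beat[(pad + 1):2], beat,
           2 * beat[n] - beat[(n - 1):(n - pad)])
  baseline <- runmed(runmed(ext, ws, endrule = "median"), wl,
                     endrule = "median")[(pad + 1):(pad + n)]
  beat - as.numeric(baseline)
}

# Internal: second-order IIR notch (constrained biquad, standard audio-EQ
# cookbook design). Returns list(b, a) with a[1] == 1.
design_notch <- function(notch_freq, sampling_rate, quality) {
  w0 <- 2 * pi * notch_freq / sampling_rate
  alpha <- sin(w0) / (2 * quality)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Internal: single-pass biquad (direct form II transposed) with initial
# state `zi * x[1]` chosen so a constant input produces a constant output
# from the first sample.
biquad_pass <- function(b, a, x, zi_scale) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi_scale[1] * x[1]
  z2 <- zi_scale[2] * x[1]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

#' Zero-phase IIR notch filter
#'
#' Applies a second-order IIR notch forward and backward (zero phase, so the
#' beat shape is not skewed), with odd-reflection edge padding and
#' steady-state initial conditions to suppress startup transients. DC gain
#' is exactly 1.
#'
#' @param beat Finite numeric waveform.
#' @param sampling_rate Sampling rate in Hz.
#' @param notch_freq Centre frequency to reject, in Hz (must be below the
#'   Nyquist frequency).
#' @param quality Quality factor; the -3 dB notch width is
#'   `notch_freq / quality` Hz.
#' @return Filtered waveform of the same length.
#' @export
notch_filter <- function(beat, sampling_rate = 125, notch_freq = 50,
                         quality = 30) {
  if (!all(is.finite(beat)))
    stop("notch_filter requires a finite input (interpolate gaps first)",
         call. = FALSE)
  if (notch_freq >= sampling_rate / 2)
    stop(sprintf("notch_freq %.3g Hz must be below Nyquist %.3g Hz",
                 notch_freq, sampling_rate / 2), call. = FALSE)
  n <- length(beat)
  if (n < 4L) return(beat)
  f <- design_notch(notch_freq, sampling_rate, quality)
  # steady-state unit-step state for direct form II transposed
  zi <- c(1 - f$b[1], f$b[3] - f$a[3])
  padlen <- min(n - 1L, 12L)
  ext <- c(2 * beat[1] - beat[(padlen + 1):2],
           beat,
           2 * beat[n] - beat[(n - 1):(n - padlen)])
  y <- biquad_pass(f$b, f$a, ext, zi)
  y <- rev(biquad_pass(f$b, f$a, rev(y), zi))
  y[(padlen + 1):(padlen + n)]
}

# Daubechies scaling (low-pass) filters in standard order, named by tap
# count as in common wavelet libraries ("db4" = 8 taps).
daubechies_filters <- list(
  db2 = c(0.48296291314453416, 0.83651630373780794,
          0.22414386804201339, -0.12940952255126037),
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953)
)

# Internal: one level of the periodised orthogonal DWT. x must have even
# length. Returns list(a, d) each of length(x)/2.
dwt_step <- function(x, h, g) {
  N <- length(x)
  half <- N %/% 2L
  a <- numeric(half); d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    xs <- x[((base + (m - 1L)) %% N) + 1L]
    a <- a + h[m] * xs
    d <- d + g[m] * xs
  }
  list(a = a, d = d)
}

# Internal: inverse of dwt_step.
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    idx <- ((base + (m - 1L)) %% N) + 1L
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

# Internal: multi-level periodised DWT. Odd-length stages are padded by
# repeating the final sample; original lengths are recorded so the inverse
# restores the input length exactly.
dwt_periodic <- function(x, family, levels) {
  h <- daubechies_filters[[family]]
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    st <- dwt_step(cur, h, g)
    details[[l]] <- st$d
    cur <- st$a
  }
  list(approx = cur, details = details, lens = lens, h = h, g = g)
}

idwt_periodic <- function(decomp) {
  cur <- decomp$approx
  for (l in rev(seq_along(decomp$details))) {
    cur <- idwt_step(cur, decomp$details[[l]], decomp$h, decomp$g)
    cur <- cur[seq_len(decomp$lens[l])]
  }
  cur
}

#' Wavelet shrinkage denoising
#'
#' Decomposes the beat with a periodised orthogonal Daubechies discrete
#' wavelet transform, thresholds every detail band with the universal
#' threshold `sigma * sqrt(2 log N)` (noise scale `sigma` estimated as
#' `median(|finest details|) / 0.6745`), and reconstructs. With the
#' threshold forced to zero the transform round-trips the input exactly
#' (perfect reconstruction).
#'
#' @param beat Finite numeric waveform with `length(beat) >= 2^levels`.
#' @param family Wavelet family: `"db2"`, `"db4"` (default) or `"db8"`.
#' @param levels Decomposition depth (default 4).
#' @param rule `"universal-soft"` (default) or `"universal-hard"`.
#' @param threshold Optional fixed threshold overriding the universal rule.
#' @return Denoised waveform of the same length.
#' @export
wavelet_denoise <- function(beat, family = c("db4", "db2", "db8"), levels = 4,
                            rule = c("universal-soft", "universal-hard"),
                            threshold = NULL) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  levels <- check_count(levels, "levels", min = 1L)
  stopifnot(all(is.finite(beat)))
  if (length(beat) < 2^levels)
    stop(sprintf("%d decomposition levels need at least %d samples, got %d",
                 levels, 2^levels, length(beat)), call. = FALSE)
  dec <- dwt_periodic(beat, family, levels)
  if (is.null(threshold)) {
    sigma <- median(abs(dec$details[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(beat)))
  }
  if (threshold > 0) {
    for (l in seq_along(dec$details)) {
      d <- dec$details[[l]]
      dec$details[[l]] <- if (rule == "universal-soft")
        sign(d) * pmax(abs(d) - threshold, 0)
      else
        d * (abs(d) > threshold)
    }
  }
  idwt_periodic(dec)
}

#' Per-beat z-normalisation
#'
#' Standardises a beat to mean 0 and population standard deviation 1. A
#' constant beat (zero variance) maps to all zeros rather than raising.
#'
#' @param beat Finite numeric waveform.
#' @return Normalised waveform.
#' @export
#' @examples
#' znormalize_beat(c(1, 2, 3))
znormalize_beat <- function(beat) {
  stopifnot(all(is.finite(beat)))
  mu <- mean(beat)
  sdev <- sqrt(mean((beat - mu)^2))
  if (sdev < 1e-12) return(rep(0, length(beat)))
  (beat - mu) / sdev
}

#' Denoise a beat matrix
#'
#' Applies the configured stages to every row, in the fixed order
#' interpolate -> baseline removal -> notch -> wavelet -> z-normalise.
#' Disabled stages are skipped (identity). The output contains no missing
#' values.
#'
#' @param beats Numeric matrix, one beat per row; `NA` marks lost samples.
#' @param masks Optional logical matrix of contact-loss flags (defaults to
#'   `is.na(beats)`).
#' @param config A [denoise_config()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Denoised beat matrix of the same shape.
#' @export
denoise_beats <- function(beats, masks = NULL, config = denoise_config(),
                          sampling_rate = 125) {
  stopifnot(inherits(config, "denoise_config"), is.matrix(beats))
  if (is.null(masks)) masks <- is.na(beats)
  stopifnot(identical(dim(masks), dim(beats)))
  out <- beats
  st <- config$stages
  for (i in seq_len(nrow(beats))) {
    b <- tryCatch({
      b <- beats[i, ]
      if (st[["interpolate"]])
        b <- interpolate_missing(b, masks[i, ], config$interpolation_kind)
      if (anyNA(b))
        stop("beat contains missing samples and the interpolate stage is off",
             call. = FALSE)
      if (st[["baseline"]])
        b <- remove_baseline_drift(b, sampling_rate,
                                   config$baseline_window_short,
                                   config$baseline_window_long)
      if (st[["notch"]])
        b <- notch_filter(b, sampling_rate, config$notch_freq,
                          config$notch_quality)
      if (st[["wavelet"]])
        b <- wavelet_denoise(b, config$wavelet_family,
                             config$decomposition_levels,
                             config$threshold_rule)
      if (config$znormalize) b <- znormalize_beat(b)
      b
    }, error = function(e)
      stop(sprintf("denoising failed at beat %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    out[i, ] <- b
  }
  out
}
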