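#' Noise specification for synthetic heartbeats
#'
#' Bundles the parameters of the five noise processes that contaminate raw
#' beat-level ECG: additive Gaussian noise, sinusoidal baseline wander,
#' sinusoidal powerline interference, transient motion-artifact bursts, and
#' electrode contact loss. All amplitudes are in the same (z-)units as the
#' beat waveform.
#'
#' @param gaussian_sigma Standard deviation of white Gaussian noise.
#' @param baseline_amplitude,baseline_freq Amplitude and frequency (Hz) of the
#'   baseline-wander sinusoid. Respiratory wander sits well below 1 Hz.
#' @param powerline_amplitude,powerline_freq Amplitude and frequency (Hz) of
#'   mains interference (50 Hz default).
#' @param motion_burst_rate Expected number of motion-artifact bursts per beat
#'   (Poisson rate).
#' @param motion_amplitude Peak amplitude of each random-walk motion burst.
#' @param contact_loss_prob Probability that a beat contains one contact-loss
#'   gap.
#' @param gap_length Length of a contact-loss gap, in samples.
#'
#' @return An object of class `noise_spec`.
#' @seealso [apply_noise()], [generate_dataset()]
#' @export
#' @examples
#' noise_spec(gaussian_sigma = 0.1, powerline_amplitude = 0.2)
noise_spec <- function(gaussian_sigma = 0,
                       baseline_amplitude = 0, baseline_freq = 0.3,
                       powerline_amplitude = 0, powerline_freq = 50,
                       motion_burst_rate = 0, motion_amplitude = 0,
                       contact_loss_prob = 0, gap_length = 10) {
  spec <- list(
    gaussian_sigma = gaussian_sigma,
    baseline_amplitude = baseline_amplitude, baseline_freq = baseline_freq,
    powerline_amplitude = powerline_amplitude, powerline_freq = powerline_freq,
    motion_burst_rate = motion_burst_rate, motion_amplitude = motion_amplitude,
    contact_loss_prob = contact_loss_prob, gap_length = as.integer(gap_length)
  )
  class(spec) <- "noise_spec"
  nonneg <- c("gaussian_sigma", "baseline_amplitude", "baseline_freq",
              "powerline_amplitude", "powerline_freq", "motion_burst_rate",
              "motion_amplitude", "contact_loss_prob", "gap_length")
  for (f in nonneg) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("noise_spec field `%s` must be a single finite value >= 0", f),
           call. = FALSE)
  }
  if (spec$contact_loss_prob > 1)
    stop("`contact_loss_prob` is a probability and must be <= 1", call. = FALSE)
  spec
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec>\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Internal: frequencies must sit below Nyquist for the given sampling rate.
validate_noise_spec <- function(spec, sampling_rate) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, as.list(spec))
  nyq <- sampling_rate / 2
  for (f in c("baseline_freq", "powerline_freq")) {
    amp <- spec[[sub("freq", "amplitude", f)]]
    if (amp > 0 && spec[[f]] >= nyq)
      stop(sprintf("`%s` (%.3g Hz) must be below the Nyquist frequency %.3g Hz",
                   f, spec[[f]], nyq), call. = FALSE)
  }
  spec
}

# Gaussian-bump wave table defining the five class morphologies.
# Columns: bump centre and width as fractions of the beat, amplitude in
# z-units. Class-specific distortions: S has an early complex with a reduced
# P wave; V has no P wave, a widened high-amplitude QRS and a discordant T;
# F is the pointwise mean of the N and V templates; Q is an irregular
# low-correlation shape.
beat_wave_table <- list(
  N = cbind(center = c(0.30, 0.445, 0.475, 0.505, 0.680),
            width  = c(0.030, 0.012, 0.018, 0.014, 0.042),
            amp    = c(0.20, -0.12, 1.00, -0.28, 0.40)),
  S = cbind(center = c(0.22, 0.385, 0.415, 0.445, 0.600),
            width  = c(0.025, 0.012, 0.018, 0.014, 0.040),
            amp    = c(0.06, -0.12, 0.95, -0.26, 0.35)),
  V = cbind(center = c(0.460, 0.560, 0.720),
            width  = c(0.050, 0.040, 0.055),
            amp    = c(1.30, -0.55, -0.45)),
  Q = cbind(center = c(0.15, 0.35, 0.55, 0.80),
            width  = c(0.035, 0.040, 0.025, 0.032),
            amp    = c(0.45, -0.40, 0.70, 0.30))
)

#' Noise-free canonical template of a heartbeat class
#'
#' Each class morphology is a sum of Gaussian bumps (P/QRS/T components) with
#' class-specific distortions; the fusion class (id 3) is defined as the
#' pointwise mean of the normal (0) and ventricular (2) templates.
#'
#' @param class_id Integer class id in 0..4 (see [ecg_classes]).
#' @param beat_length Number of samples per beat (>= 32; default 187, the
#'   common pre-segmented beat layout at 125 Hz).
#' @return Numeric vector of length `beat_length`.
#' @export
#' @examples
#' plot(beat_template(0), type = "l")
beat_template <- function(class_id, beat_length = 187) {
  class_id <- check_class_id(class_id)
  beat_length <- check_count(beat_length, "beat_length", min = 32L)
  if (class_id == 3L)
    return((beat_template(0L, beat_length) + beat_template(2L, beat_length)) / 2)
  tab <- beat_wave_table[[ecg_classes[class_id + 1L]]]
  t <- seq(0, 1, length.out = beat_length)
  y <- numeric(beat_length)
  for (i in seq_len(nrow(tab)))
    y <- y + tab[i, "amp"] * exp(-0.5 * ((t - tab[i, "center"]) / tab[i, "width"])^2)
  y
}

check_class_id <- function(class_id) {
  if (!is.numeric(class_id) || length(class_id) != 1L || !is.finite(class_id) ||
      class_id != round(class_id) || class_id < 0 || class_id > 4)
    stop("`class_id` must be a single integer in 0..4 (N, S, V, F, Q)",
         call. = FALSE)
  as.integer(class_id)
}

#' Generate one synthetic heartbeat
#'
#' Draws a beat of the requested class: the class template plus a small
#' seeded beat-to-beat variation (global amplitude scaling and a sub-beat
#' time shift), emulating physiological variability. The variation is a
#' linear operator drawn from the seed alone, so mixtures of templates are
#' preserved (the fusion class stays the mean of jittered N and V beats at
#' the same seed).
#'
#' @inheritParams beat_template
#' @param seed Integer seed; identical arguments give bitwise-identical beats.
#' @param amp_jitter Standard deviation of the log-amplitude scaling
#'   (default 0.05).
#' @param shift_jitter Standard deviation of the circular time shift as a
#'   fraction of the beat (default 0.01).
#' @return Numeric vector of length `beat_length`.
#' @export
#' @examples
#' b <- generate_beat(2, seed = 7)
generate_beat <- function(class_id, beat_length = 187, seed = 0,
                          amp_jitter = 0.05, shift_jitter = 0.01) {
  class_id <- check_class_id(class_id)
  beat_length <- check_count(beat_length, "beat_length", min = 32L)
  tmpl <- beat_template(class_id, beat_length)
  with_local_seed(seed, {
    a <- exp(rnorm(1, 0, amp_jitter))
    k <- round(rnorm(1, 0, shift_jitter * beat_length))
    k <- k %% beat_length
    if (k > 0) tmpl <- c(tmpl[(k + 1):beat_length], tmpl[1:k])
    a * tmpl
  })
}

#' Contaminate a beat with the standard ECG noise taxonomy
#'
#' Adds, in order: white Gaussian noise, a baseline-wander sinusoid, a
#' powerline sinusoid, and random-walk motion bursts at Poisson-placed
#' locations; then, with probability `contact_loss_prob`, blanks one
#' contiguous contact-loss gap. Lost samples are recorded in the returned
#' mask and replaced by `NA` so the beat stays rectangular alongside its
#' neighbours.
#'
#' @param beat Numeric waveform.
#' @param spec A [noise_spec()].
#' @param sampling_rate Sampling rate in Hz (default 125).
#' @param seed Integer seed; the operation is deterministic given its
#'   arguments.
#' @return List with elements `beat` (noisy waveform, `NA` at lost samples)
#'   and `mask` (logical vector, `TRUE` where contact was lost).
#' @export
#' @examples
#' out <- apply_noise(beat_template(0), noise_spec(gaussian_sigma = 0.1), seed = 1)
apply_noise <- function(beat, spec = noise_spec(), sampling_rate = 125, seed = 0) {
  stopifnot(is.numeric(beat), length(beat) >= 1L)
  spec <- validate_noise_spec(spec, sampling_rate)
  L <- length(beat)
  tt <- (seq_len(L) - 1L) / sampling_rate
  with_local_seed(seed, {
    out <- beat
    if (spec$gaussian_sigma > 0)
      out <- out + rnorm(L, 0, spec$gaussian_sigma)
    if (spec$baseline_amplitude > 0)
      out <- out + spec$baseline_amplitude *
        sin(2 * pi * spec$baseline_freq * tt + runif(1, 0, 2 * pi))
    if (spec$powerline_amplitude > 0)
      out <- out + spec$powerline_amplitude *
        sin(2 * pi * spec$powerline_freq * tt + runif(1, 0, 2 * pi))
    if (spec$motion_burst_rate > 0 && spec$motion_amplitude > 0) {
      n_bursts <- rpois(1, spec$motion_burst_rate)
      for (b in seq_len(n_bursts)) {
        len <- max(4L, round(L * runif(1, 0.05, 0.2)))
        start <- sample.int(L, 1)
        walk <- cumsum(rnorm(len))
        walk <- spec$motion_amplitude * walk / max(abs(walk))
        walk <- walk * 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1))) # Hann
        idx <- start:min(L, start + len - 1L)
        out[idx] <- out[idx] + walk[seq_along(idx)]
      }
    }
    mask <- rep(FALSE, L)
    if (spec$contact_loss_prob > 0 && runif(1) <= spec$contact_loss_prob) {
      gl <- min(spec$gap_length, L)
      start <- sample.int(L - gl + 1L, 1)
      mask[start:(start + gl - 1L)] <- TRUE
      out[mask] <- NA_real_
    }
    list(beat = out, mask = mask)
  })
}

#' Generate a labelled synthetic beat dataset
#'
#' Produces `sum(class_counts)` beats with the requested per-class counts,
#' contaminates each with `spec`, and shuffles the rows deterministically.
#'
#' @param class_counts Named numeric vector mapping class ids ("0".."4") to
#'   counts, or an unnamed length-5 vector in class-id order.
#' @inheritParams beat_template
#' @inheritParams apply_noise
#' @param seed Master seed controlling per-beat variation, noise and row
#'   shuffling.
#' @return List with `beats` (matrix, one beat per row), `labels` (integer
#'   class ids 0..4) and `masks` (logical matrix of contact-loss flags).
#' @export
#' @examples
#' d <- generate_dataset(c(`0` = 5, `2` = 5), seed = 1)
#' table(d$labels)
generate_dataset <- function(class_counts, beat_length = 187,
                             spec = noise_spec(), sampling_rate = 125,
                             seed = 0) {
  if (is.null(names(class_counts))) {
    if (length(class_counts) != 5L)
      stop("unnamed `class_counts` must have length 5 (classes 0..4)",
           call. = FALSE)
    names(class_counts) <- as.character(0:4)
  }
  ids <- as.integer(names(class_counts))
  if (anyNA(ids) || any(ids < 0 | ids > 4))
    stop("`class_counts` names must be class ids in 0..4", call. = FALSE)
  counts <- vapply(class_counts, function(x) check_count(x, "class_counts"), 0L)
  n <- sum(counts)
  if (n == 0L) stop("empty dataset: all class counts are zero", call. = FALSE)
  spec <- validate_noise_spec(spec, sampling_rate)
  labels <- rep(ids, counts)
  with_local_seed(seed, {
    beat_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    order_idx <- sample.int(n)
  })
  beats <- matrix(0, n, beat_length)
  masks <- matrix(FALSE, n, beat_length)
  for (i in seq_len(n)) {
    clean <- generate_beat(labels[i], beat_length, seed = beat_seeds[i])
    noisy <- apply_noise(clean, spec, sampling_rate, seed = beat_seeds[n + i])
    beats[i, ] <- noisy$beat
    masks[i, ] <- noisy$mask
  }
  list(beats = beats[order_idx, , drop = FALSE],
       labels = labels[order_idx],
       masks = masks[order_idx, , drop = FALSE])
}
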