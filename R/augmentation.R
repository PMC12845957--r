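# Stochastic waveform augmentation, applied to training segments only.
# Four operators, each fired with independent probability 0.5; if a draw
# applies none, the whole Bernoulli vector is redrawn until at least one
# operator fires, so no unaltered audio ever reaches the augmented set.
# Every operator preserves the 132,300-sample length exactly.

#' Augmentation configuration
#'
#' Parameter draws are uniform within the stated ranges. The noise standard
#' deviation is a fraction of digital full scale (1.0), not of the clip's own
#' peak. Pitch shifting is length-preserving (phase vocoder). The high-pass is
#' a 4th-order Butterworth applied forward-backward (zero phase). Time shifts
#' roll over: samples pushed past the end re-enter at the start.
#'
#' @param p_apply per-operator application probability (recycled to 4:
#'   noise, pitch, high-pass, time shift).
#' @param noise_sd_range Gaussian noise sd as a fraction of full scale.
#' @param pitch_range pitch shift range in semitones.
#' @param highpass_cutoff_range high-pass cutoff range in Hz.
#' @param timeshift_range circular time shift range in seconds.
#' @param variants_per_clip independently augmented variants per original.
#' @param seed integer seed for reproducible expansion.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(p_apply = 0.5,
                           noise_sd_range = c(0.010, 0.015),
                           pitch_range = c(-12, 12),
                           highpass_cutoff_range = c(1000, 2000),
                           timeshift_range = c(-3, 3),
                           variants_per_clip = 5L,
                           seed = 1L) {
  p <- rep_len(p_apply, 4L)
  if (any(p < 0 | p > 1)) stop("p_apply must lie in [0, 1]")
  if (all(p == 0)) stop("at least one operator must have p_apply > 0")
  structure(list(p_apply = p, noise_sd_range = noise_sd_range,
                 pitch_range = pitch_range,
                 highpass_cutoff_range = highpass_cutoff_range,
                 timeshift_range = timeshift_range,
                 variants_per_clip = as.integer(variants_per_clip),
                 seed = as.integer(seed)),
            class = "augment_config")
}

AUGMENT_OPS <- c("noise", "pitch", "highpass", "timeshift")

#' Draw which operators fire, with the rejection rule
#'
#' Redraws the whole Bernoulli vector whenever no operator fires. With all
#' probabilities at 0.5, the per-operator application frequency conditional on
#' acceptance is (1/2) / (1 - (1/2)^4) = 8/15.
#'
#' @param p_apply length-4 probability vector.
#' @return logical vector of length 4 named by operator.
#' @export
draw_operator_mask <- function(p_apply = rep(0.5, 4L)) {
  repeat {
    mask <- runif(4L) < p_apply
    if (any(mask)) break
  }
  names(mask) <- AUGMENT_OPS
  mask
}

aug_add_noise <- function(x, sd_range) {
  sd <- runif(1L, sd_range[1L], sd_range[2L])
  list(x = x + rnorm(length(x), 0, sd), param = sd)
}

aug_highpass <- function(x, cutoff_range, sr) {
  cutoff <- runif(1L, cutoff_range[1L], cutoff_range[2L])
  bf <- signal::butter(4, cutoff / (sr / 2), type = "high")
  list(x = signal::filtfilt(bf, x), param = cutoff)
}

aug_timeshift <- function(x, range_s, sr) {
  repeat {
    shift_s <- runif(1L, range_s[1L], range_s[2L])
    k <- as.integer(round(shift_s * sr))
    if (k != 0L) break # a zero-sample shift would leave the audio unaltered
  }
  list(x = roll_shift(x, k), param = shift_s)
}

# Circular shift: positive k moves content later; sample at index i lands at
# index (i + k - 1) mod n + 1.
roll_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

aug_pitch_shift <- function(x, range_semitones, sr) {
  s <- runif(1L, range_semitones[1L], range_semitones[2L])
  list(x = pitch_shift(x, s, sr), param = s)
}

#' Length-preserving pitch shift
#'
#' Phase-vocoder time stretch by `2^(semitones/12)` followed by resampling
#' back to the original length, so pitch scales while duration is unchanged.
#'
#' @param x mono waveform.
#' @param semitones shift in semitones (positive = up).
#' @param sr sampling rate in Hz.
#' @return waveform of `length(x)` samples.
#' @export
pitch_shift <- function(x, semitones, sr) {
  if (abs(semitones) < 1e-9) return(x)
  rate <- 2^(semitones / 12)
  n <- length(x)
  # Stretch duration by `rate` (pitch unchanged), then decimate time by the
  # same factor: duration returns to n samples and every frequency scales by
  # `rate`.
  stretched <- phase_vocoder_stretch(x, rate, n_fft = 1024L)
  frac <- rational_approx(rate, max_den = 1000L)
  fft_resample(stretched, frac[2L], frac[1L], n_out = n)
}

# best rational p/q ~ r with q <= max_den (continued fractions)
rational_approx <- function(r, max_den = 1000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  val <- r
  repeat {
    a <- floor(val)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(val - a) < 1e-12) break
    val <- 1 / (val - a)
  }
  c(as.integer(p1), as.integer(q1))
}

# Phase vocoder: stretch duration by `factor` (> 1 = longer output) while
# preserving pitch. Hann-windowed STFT, hop n_fft/4, phase accumulation with
# wrapped deviation, overlap-add resynthesis with window-sum normalization.
phase_vocoder_stretch <- function(x, factor, n_fft = 2048L) {
  hop <- n_fft %/% 4L
  n <- length(x)
  pad <- n_fft %/% 2L
  xp <- c(numeric(pad), x, numeric(pad + n_fft))
  n_frames <- 1L + (length(xp) - n_fft) %/% hop
  w <- hann_window(n_fft)
  n_bins <- n_fft %/% 2L + 1L
  D <- matrix(0+0i, n_bins, n_frames)
  for (t in seq_len(n_frames)) {
    start <- (t - 1L) * hop
    D[, t] <- fft(xp[(start + 1L):(start + n_fft)] * w)[seq_len(n_bins)]
  }
  steps <- seq(1, n_frames - 1L, by = 1 / factor)
  exp_advance <- 2 * pi * hop * (seq_len(n_bins) - 1) / n_fft
  phase <- Arg(D[, 1L])
  mag0 <- Mod(D)
  phi <- Arg(D)
  out_spec <- matrix(0+0i, n_bins, length(steps))
  for (i in seq_along(steps)) {
    t0 <- floor(steps[i]); frac <- steps[i] - t0
    mag <- (1 - frac) * mag0[, t0] + frac * mag0[, t0 + 1L]
    out_spec[, i] <- mag * exp(1i * phase)
    dphi <- phi[, t0 + 1L] - phi[, t0] - exp_advance
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + exp_advance + dphi
  }
  # inverse STFT, overlap-add
  out_len <- n_fft + (length(steps) - 1L) * hop
  y <- numeric(out_len)
  wsum <- numeric(out_len)
  for (i in seq_along(steps)) {
    full <- c(out_spec[, i], Conj(out_spec[(n_bins - 1L):2L, i]))
    frame <- Re(fft(full, inverse = TRUE)) / n_fft
    idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + n_fft)
    y[idx] <- y[idx] + frame * w
    wsum[idx] <- wsum[idx] + w^2
  }
  y <- y / pmax(wsum, 1e-8)
  target <- as.integer(round(n * factor))
  y <- y[(pad + 1L):min(length(y), pad + target)]
  if (length(y) < target) y <- c(y, numeric(target - length(y)))
  y
}

#' Apply the stochastic augmentation pipeline to one window
#'
#' Draws the operator mask with the rejection rule, applies the firing
#' operators in a fixed order (noise, pitch shift, high-pass, time shift) with
#' uniformly drawn parameters, and clips the result to `[-1, 1]`. Output
#' length equals input length exactly. Uses the current RNG state; seed
#' beforehand (or use [expand_training()]) for reproducibility.
#'
#' @param seg a [segment()] or mono [AudioClip-class] at 22,050 Hz.
#' @param config an [augment_config()].
#' @return Object of the same type as the input, with attributes
#'   `operators_applied` (character) and `draw_parameters` (named list).
#' @export
apply_augmentations <- function(seg, config = augment_config()) {
  is_seg <- inherits(seg, "whale_segment")
  if (is_seg) {
    x <- seg$samples
    sr <- FEATURE_RATE
  } else {
    if (seg@sample_rate != FEATURE_RATE) {
      stop(sprintf("augmentation runs on %d Hz audio; resample first", FEATURE_RATE))
    }
    x <- mono_samples(seg)
    sr <- seg@sample_rate
  }
  n_in <- length(x)
  mask <- draw_operator_mask(config$p_apply)
  params <- list()
  if (mask[["noise"]]) {
    r <- aug_add_noise(x, config$noise_sd_range)
    x <- r$x; params$noise_sd <- r$param
  }
  if (mask[["pitch"]]) {
    r <- aug_pitch_shift(x, config$pitch_range, sr)
    x <- r$x; params$pitch_semitones <- r$param
  }
  if (mask[["highpass"]]) {
    r <- aug_highpass(x, config$highpass_cutoff_range, sr)
    x <- r$x; params$highpass_cutoff_hz <- r$param
  }
  if (mask[["timeshift"]]) {
    r <- aug_timeshift(x, config$timeshift_range, sr)
    x <- r$x; params$timeshift_s <- r$param
  }
  x[x > 1] <- 1
  x[x < -1] <- -1
  stopifnot(length(x) == n_in)
  out <- if (is_seg) {
    segment(x, seg$source_id, seg$start_s, seg$label)
  } else {
    audio_clip(x, sr, seg@source_id, seg@label)
  }
  attr(out, "operators_applied") <- AUGMENT_OPS[mask]
  attr(out, "draw_parameters") <- params
  out
}

# Deterministic per-variant sub-seed; kept below 2^31.
variant_seed <- function(base_seed, seg_index, variant) {
  (as.numeric(base_seed) * 100003 + seg_index * 1009 + variant * 7919) %% 2147483647
}

# internal: variant `v` of training segment `segments[[i]]`, reproducible
# from (config$seed, i, v) alone.
augment_variant <- function(seg, i, v, config) {
  with_seed(variant_seed(config$seed, i, v), {
    out <- apply_augmentations(seg, config)
    out$variant_index <- v
    out$parent_index <- i
    out
  })
}

#' Expand training segments with augmented variants
#'
#' Emits `variants_per_clip` independently augmented variants per segment
#' (5 by default, so 100 segments become 500 variants). Variant `v` of
#' segment `i` is reproducible from `(config$seed, i, v)`. The rejection rule
#' guarantees no variant is bit-identical to its original. Refuses to run on
#' validation or test segments: augmentation is a training-only operation.
#'
#' @param segments list of training [segment()]s (each may carry a `split`
#'   field; anything other than `"train"` is refused).
#' @param config an [augment_config()].
#' @param callback optional function applied to each variant in place of
#'   collecting waveforms (e.g. featurize-and-discard to bound memory); when
#'   given, the list of callback results is returned instead.
#' @return list of `5 x length(segments)` augmented segments (or callback
#'   results), ordered by (segment, variant).
#' @export
expand_training <- function(segments, config = augment_config(),
                            callback = NULL) {
  splits <- unlist(lapply(segments, function(s) s$split))
  if (!is.null(splits) && any(splits != "train")) {
    stop("augmentation is training-only: refusing val/test segments (leakage guard)")
  }
  out <- vector("list", length(segments) * config$variants_per_clip)
  k <- 0L
  for (i in seq_along(segments)) {
    for (v in seq_len(config$variants_per_clip)) {
      k <- k + 1L
      var <- augment_variant(segments[[i]], i, v, config)
      out[[k]] <- if (is.null(callback)) var else callback(var)
    }
  }
  out
}
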