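# Waveform standardization: every recording entering the pipeline is reduced
# to mono, 44.1 kHz, 16-bit-quantized amplitude, matching how the field audio
# was normalized at collection time. Feature extraction then runs at 22,050 Hz.

STANDARD_RATE <- 44100L
FEATURE_RATE <- 22050L

#' Standardize a clip to mono, 44.1 kHz, 16-bit amplitude grid
#'
#' Channel mixdown is the arithmetic mean across channels. The waveform is
#' resampled to 44,100 Hz with an anti-aliased polyphase filter, then snapped
#' once to the signed 16-bit amplitude grid and rescaled to `[-1, 1]`.
#' Amplitudes are held as floats afterwards, so the operation is idempotent.
#'
#' @param clip an [AudioClip-class] with at least one channel.
#' @return A mono [AudioClip-class] at 44,100 Hz.
#' @export
standardize <- function(clip) {
  if (nrow(clip@samples) == 0L) stop("empty clip")
  x <- rowMeans(clip@samples)
  mono <- audio_clip(x, clip@sample_rate, clip@source_id, clip@label)
  if (mono@sample_rate != STANDARD_RATE) {
    mono <- resample(mono, STANDARD_RATE)
  }
  q <- round(mono_samples(mono) * WAV_FULL_SCALE) / WAV_FULL_SCALE
  q[q > 1] <- 1
  q[q < -1] <- -1
  audio_clip(q, STANDARD_RATE, clip@source_id, clip@label)
}

#' Resample a clip with an anti-aliased polyphase filter
#'
#' Output length is `round(duration_s * target_rate)`, so duration is
#' preserved to within half an output sample period. Content above the target
#' Nyquist frequency is suppressed by the polyphase low-pass.
#'
#' @param clip a mono [AudioClip-class].
#' @param target_rate target sampling rate in Hz (positive).
#' @return An [AudioClip-class] at `target_rate`.
#' @export
resample <- function(clip, target_rate) {
  target_rate <- as.integer(round(target_rate))
  if (is.na(target_rate) || target_rate <= 0L) stop("target_rate must be positive")
  if (target_rate == clip@sample_rate) return(clip)
  x <- mono_samples(clip)
  g <- gcd_int(target_rate, clip@sample_rate)
  p <- target_rate %/% g
  q <- clip@sample_rate %/% g
  n_out <- round(length(x) * (target_rate / clip@sample_rate))
  y <- fft_resample(x, p, q, n_out)
  y[y > 1] <- 1
  y[y < -1] <- -1
  audio_clip(y, target_rate, clip@source_id, clip@label)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# smallest 5-smooth integer >= n (keeps mixed-radix FFTs fast)
next_fast_len <- function(n) {
  if (n <= 6L) return(as.integer(n))
  best <- Inf
  p5 <- 1
  while (p5 < n * 2) {
    p35 <- p5
    while (p35 < n * 2) {
      p2 <- p35 * 2^max(0, ceiling(log2(n / p35)))
      if (p2 >= n && p2 < best) best <- p2
      if (p35 >= n && p35 < best) best <- p35
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

# Rational-factor resampling in the frequency domain: zero-pad to a 5-smooth
# length divisible by q, truncate/extend the spectrum (an ideal low-pass at
# the narrower Nyquist), invert, and trim to n_out samples.
fft_resample <- function(x, p, q, n_out = round(length(x) * p / q)) {
  n <- length(x)
  n2 <- next_fast_len(as.integer(ceiling(n / q)))
  n2 <- n2 * q
  m2 <- (n2 %/% q) * p
  xp <- c(x, numeric(n2 - n))
  X <- fft(xp)
  half <- (min(n2, m2) - 1L) %/% 2L
  Y <- complex(m2)
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  if (half > 0L) Y[(m2 - half + 1L):m2] <- X[(n2 - half + 1L):n2]
  y <- Re(fft(Y, inverse = TRUE)) / n2
  if (n_out <= m2) y[seq_len(n_out)] else c(y, numeric(n_out - m2))
}
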