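# Shared fixtures, generated in code at test time.

FEATURE_SR <- 22050L
SEG_N <- 132300L

# mono sine clip
tone_clip <- function(freq = 440, dur_s = 1, sr = FEATURE_SR, amp = 0.5,
                      source_id = "tone", label = "unknown") {
  t <- seq_len(round(dur_s * sr)) - 1
  audio_clip(amp * sin(2 * pi * freq * t / sr), sr, source_id, label)
}

# full 6 s analysis window containing a pure tone
tone_segment <- function(freq = 1000, amp = 0.5, label = "humpback",
                         source_id = "tone_src") {
  t <- seq_len(SEG_N) - 1
  segment(amp * sin(2 * pi * freq * t / FEATURE_SR), source_id, 0, label)
}

# window with a single unit impulse at time t_s
click_segment <- function(t_s, source_id = "click_src", label = "no_call") {
  x <- numeric(SEG_N)
  x[round(t_s * FEATURE_SR) + 1] <- 1
  segment(x, source_id, 0, label)
}

# dominant DFT frequency of a waveform (Hz)
dominant_freq <- function(x, sr) {
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * sr / n
}

# two visually distinct, linearly separable feature-image families:
# class 1 lights up the top band, class 2 the bottom band, plus noise.
toy_image_set <- function(n_per_class, noise_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    x <- array(rnorm(125 * 50 * 3 * n, sd = noise_sd), c(125, 50, 3, n))
    y <- integer(n)
    for (i in seq_len(n)) {
      cls <- if (i <= n_per_class) 1L else 2L
      rows <- if (cls == 1L) 1:40 else 86:125
      x[rows, , , i] <- x[rows, , , i] + 1.5
      y[i] <- cls
    }
    for (i in seq_len(n)) x[, , , i] <- unclass(standardize_image(x[, , , i]))
    list(x = x, y = y)
  })
}

# tiny synthetic corpus parameters for fast structural tests
tiny_synth_params <- function() {
  synth_params(n_call_sources = 3L, n_nocall_sources = 3L,
               duration_range_s = c(4, 14))
}
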