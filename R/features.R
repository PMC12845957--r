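# Time-frequency feature images. A 6 s / 132,300-sample window becomes a
# 125 x 50 matrix (mel bins x time frames) or a delta-MFCC matrix resized to
# the same shape, then a min-max-scaled RGB rendering of 125 x 50 x 3, and
# finally a per-image standardized float tensor fed to the classifiers.
#
# Framing is uncentered so the frame-count identity is exact:
#   frames = 1 + floor((132300 - 2048) / 2646) = 50.

#' Spectrogram parameter set
#'
#' Defaults fix the analysis geometry: 22,050 Hz audio, 2048-point FFT, Hann
#' window, hop of 2646 samples (132,300 / 50, giving exactly 50 frames per
#' window), 125 mel bins spanning 0-10 kHz, log-power scaling with an 80 dB
#' floor referenced to the per-segment maximum, and no frame centering.
#'
#' @param sample_rate audio rate in Hz.
#' @param n_fft FFT size in samples.
#' @param hop hop between frame starts in samples.
#' @param n_mels number of mel filter bank bins (image height).
#' @param f_max top of the mel filter bank in Hz.
#' @param db_floor dynamic range floor in dB below the per-segment maximum.
#' @param n_mfcc number of cepstral coefficients kept for the delta-MFCC path.
#' @return list of class `spectro_params`.
#' @export
spectro_params <- function(sample_rate = 22050L, n_fft = 2048L, hop = 2646L,
                           n_mels = 125L, f_max = 10000, db_floor = 80,
                           n_mfcc = 20L) {
  structure(list(sample_rate = as.integer(sample_rate),
                 n_fft = as.integer(n_fft), hop = as.integer(hop),
                 n_mels = as.integer(n_mels), f_max = f_max,
                 db_floor = db_floor, n_mfcc = as.integer(n_mfcc)),
            class = "spectro_params")
}

# Periodic Hann window, the STFT convention.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Short-time power spectrum without centering: frames x (n_fft/2 + 1) bins.
stft_power <- function(x, n_fft, hop) {
  n <- length(x)
  if (n < n_fft) stop("signal shorter than one analysis frame")
  n_frames <- 1L + (n - n_fft) %/% hop
  w <- hann_window(n_fft)
  n_bins <- n_fft %/% 2L + 1L
  out <- matrix(0, nrow = n_bins, ncol = n_frames)
  for (t in seq_len(n_frames)) {
    start <- (t - 1L) * hop
    fr <- x[(start + 1L):(start + n_fft)] * w
    sp <- fft(fr)[seq_len(n_bins)]
    out[, t] <- Re(sp)^2 + Im(sp)^2
  }
  out
}

# Mel scale (Slaney variant): linear below 1 kHz, logarithmic above.
hz_to_mel <- function(f) {
  f_sp <- 200 / 3
  brk <- 1000
  logstep <- log(6.4) / 27
  ifelse(f < brk, f / f_sp, brk / f_sp + log(f / brk) / logstep)
}

mel_to_hz <- function(m) {
  f_sp <- 200 / 3
  brk_mel <- 1000 / f_sp
  logstep <- log(6.4) / 27
  ifelse(m < brk_mel, m * f_sp, 1000 * exp(logstep * (m - brk_mel)))
}

#' Mel filter bank matrix
#'
#' Triangular filters with centers equally spaced on the mel scale between
#' 0 Hz and `f_max`, area-normalized (each filter scaled by 2 / bandwidth).
#'
#' @param params a [spectro_params()].
#' @return matrix `n_mels` x `n_fft/2 + 1`.
#' @export
mel_filterbank <- function(params = spectro_params()) {
  n_bins <- params$n_fft %/% 2L + 1L
  fft_freqs <- (seq_len(n_bins) - 1) * params$sample_rate / params$n_fft
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(params$f_max),
                 length.out = params$n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, nrow = params$n_mels, ncol = n_bins)
  for (m in seq_len(params$n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (fft_freqs - lo) / (ctr - lo)
    down <- (hi - fft_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

# internal: validate a segment-or-vector argument to the feature ops
segment_vector <- function(seg, params) {
  x <- if (inherits(seg, "whale_segment")) seg$samples else as.numeric(seg)
  if (length(x) != SEGMENT_SAMPLES) {
    stop(sprintf("feature extraction expects a full %d-sample window, got %d",
                 SEGMENT_SAMPLES, length(x)))
  }
  x
}

#' Log-power mel spectrogram of one window
#'
#' @param seg a [segment()] or a 132,300-sample numeric vector.
#' @param params a [spectro_params()].
#' @return matrix of class `feature_matrix` (`n_mels` x 50, dB), row 1 the
#'   lowest mel bin, with attribute `kind = "mel"`.
#' @export
mel_spectrogram <- function(seg, params = spectro_params()) {
  x <- segment_vector(seg, params)
  pw <- stft_power(x, params$n_fft, params$hop)
  mel <- mel_filterbank(params) %*% pw
  db <- power_to_db(mel, floor_db = params$db_floor)
  structure(db, kind = "mel", class = c("feature_matrix", "matrix"))
}

# dB relative to the matrix maximum, floored.
power_to_db <- function(s, floor_db = 80) {
  ref <- max(s, 1e-30)
  db <- 10 * log10(pmax(s, 1e-30) / ref)
  db[db < -floor_db] <- -floor_db
  db
}

# Orthonormal DCT-II matrix (n_out x n_in), the MFCC compression transform.
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  m <- sqrt(2 / n_in) * cos(pi / n_in * outer(k, n + 0.5))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' MFCC matrix of one window
#'
#' DCT-II (orthonormal) of the log-mel spectrum, keeping the first `n_mfcc`
#' coefficients; same framing as [mel_spectrogram()], so 50 frames.
#'
#' @inheritParams mel_spectrogram
#' @return matrix `n_mfcc` x 50.
#' @export
mfcc <- function(seg, params = spectro_params()) {
  if (params$n_mfcc < 2L) stop("n_mfcc must be >= 2")
  db <- unclass(mel_spectrogram(seg, params))
  dct_matrix(params$n_mfcc, params$n_mels) %*% db
}

#' First-order delta of the MFCCs
#'
#' Local-slope estimate of each cepstral trajectory over time, computed with a
#' Savitzky-Golay first-derivative filter (window 9 frames, linear fit), so the
#' delta of a linear-in-time ramp is exactly its slope, including at the edges.
#'
#' @inheritParams mel_spectrogram
#' @param n_mfcc number of cepstral coefficients (overrides `params$n_mfcc`).
#' @return matrix of class `feature_matrix` (`n_mfcc` x 50) with
#'   `kind = "delta_mfcc"`.
#' @export
delta_mfcc <- function(seg, params = spectro_params(), n_mfcc = params$n_mfcc) {
  if (n_mfcc < 2L) stop("n_mfcc must be >= 2")
  params$n_mfcc <- as.integer(n_mfcc)
  c0 <- mfcc(seg, params)
  d <- t(apply(c0, 1L, function(row) {
    signal::sgolayfilt(row, p = 1, n = 9, m = 1, ts = 1)
  }))
  structure(d, kind = "delta_mfcc", class = c("feature_matrix", "matrix"))
}

# Linear resize of matrix rows to n_rows (per-column interpolation).
resize_rows <- function(m, n_rows) {
  if (nrow(m) == n_rows) return(m)
  xin <- seq_len(nrow(m))
  xout <- seq(1, nrow(m), length.out = n_rows)
  apply(m, 2L, function(col) approx(xin, col, xout = xout)$y)
}

#' Render a feature matrix as a 125 x 50 x 3 color image
#'
#' Values are min-max scaled to `[0, 1]` per image (an affine-invariant
#' mapping; a constant matrix maps to mid-scale 0.5), passed through a
#' perceptually uniform colormap, and resized along the row axis to 125 if
#' needed (the delta-MFCC path). Orientation contract: row index 1 of the
#' output is the lowest frequency / first cepstral coefficient.
#'
#' @param m a `feature_matrix` (or plain matrix) with 50 columns.
#' @param colormap_name palette passed to [grDevices::hcl.colors()].
#' @return numeric array 125 x 50 x 3 in `[0, 1]` of class `feature_image`,
#'   attribute `standardized = FALSE`.
#' @export
render_rgb <- function(m, colormap_name = "viridis") {
  m <- unclass(m)
  if (any(!is.finite(m))) stop("feature matrix must be finite")
  m <- resize_rows(m, 125L)
  rng <- max(m) - min(m)
  v <- if (rng < 1e-12) matrix(0.5, nrow(m), ncol(m)) else (m - min(m)) / rng
  lut <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, colormap_name))) / 255
  idx <- round(v * 255) + 1L
  img <- array(0, dim = c(125L, ncol(m), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(lut[idx, ch], nrow(m), ncol(m))
  structure(img, standardized = FALSE, class = "feature_image")
}

#' Per-image standardization
#'
#' Optionally rescales 8-bit exports by 1/255, then removes the per-image mean
#' and divides by the per-image standard deviation (population convention,
#' epsilon-guarded so a constant image maps to all zeros). Standardizing an
#' already standardized image is a no-op.
#'
#' @param img a `feature_image` array (any shape).
#' @param from_8bit logical; TRUE when pixels are 0-255 integers.
#' @return standardized `feature_image` with `standardized = TRUE`.
#' @export
standardize_image <- function(img, from_8bit = FALSE) {
  x <- unclass(img)
  if (any(!is.finite(x))) stop("image must be finite")
  if (from_8bit) x <- x / 255
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  out <- if (sigma < 1e-8) array(0, dim = dim(x)) else (x - mu) / sigma
  structure(out, standardized = TRUE, class = "feature_image")
}

#' Feature image for one segment
#'
#' Convenience wrapper: mel spectrogram or delta-MFCC, rendered and
#' standardized, ready for the classifiers.
#'
#' @param seg a [segment()].
#' @param kind `"mel"` or `"delta_mfcc"`.
#' @param params a [spectro_params()].
#' @param colormap_name palette name.
#' @return standardized 125 x 50 x 3 `feature_image`.
#' @export
featurize_segment <- function(seg, kind = c("mel", "delta_mfcc"),
                              params = spectro_params(),
                              colormap_name = "viridis") {
  kind <- match.arg(kind)
  m <- if (kind == "mel") mel_spectrogram(seg, params) else delta_mfcc(seg, params)
  standardize_image(render_rgb(m, colormap_name))
}

#' Export a feature image as an 8-bit PNG
#'
#' Optional I/O path; the in-memory pipeline keeps float images. The PNG is
#' written with frequency increasing upward (row 1 of the array, the lowest
#' frequency, ends up at the bottom of the picture).
#'
#' @param img an unstandardized `feature_image` in `[0, 1]`.
#' @param path output file path.
#' @export
export_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  x <- unclass(img)
  png::writePNG(x[rev(seq_len(dim(x)[1])), , , drop = FALSE], path)
  invisible(path)
}
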