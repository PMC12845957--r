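# Minimal PCM WAV (RIFF) reader/writer. 16-bit integer PCM, mono or multi-
# channel. Amplitudes map to floats in [-1, 1] via the signed 16-bit grid.

WAV_FULL_SCALE <- 32767

#' Read a PCM WAV file
#'
#' Parses the RIFF container and returns the file's native sample rate and
#' channel layout (multi-channel input is preserved so that [standardize()] can
#' do the mixdown). Only uncompressed 16-bit integer PCM is supported; other
#' encodings raise a format error.
#'
#' @param path file path to a `.wav` file.
#' @param source_id identifier recorded on the clip; defaults to the file name.
#' @param label class label for the clip.
#' @return An [AudioClip-class].
#' @export
read_wav <- function(path, source_id = basename(path), label = "unknown") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(sprintf("not a WAV file (no RIFF header): %s", path))
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop(sprintf("not a WAV file (no WAVE tag): %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(
        audio_format = u16(0L), channels = u16(2L),
        sample_rate = u32(4L), bits = u16(14L)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("malformed WAV (missing fmt/data chunk): %s", path))
  }
  if (fmt$audio_format != 1L) {
    stop(sprintf("unsupported WAV encoding (format tag %d, need PCM): %s",
                 fmt$audio_format, path))
  }
  if (fmt$bits != 16L) {
    stop(sprintf("unsupported bit depth %d (only 16-bit PCM): %s", fmt$bits, path))
  }

  n_vals <- length(data_raw) %/% 2L
  ints <- readBin(data_raw, "integer", n = n_vals, size = 2L, signed = TRUE,
                  endian = "little")
  ch <- fmt$channels
  n_frames <- n_vals %/% ch
  x <- matrix(ints[seq_len(n_frames * ch)] / WAV_FULL_SCALE,
              nrow = n_frames, ncol = ch, byrow = TRUE)
  x[x < -1] <- -1
  audio_clip(x, fmt$sample_rate, source_id = source_id, label = label)
}

#' Write an AudioClip as a 16-bit PCM WAV file
#'
#' Amplitudes are clamped to `[-1, 1]` and quantized to the signed 16-bit grid.
#'
#' @param clip an [AudioClip-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- clip@samples
  x[x > 1] <- 1
  x[x < -1] <- -1
  ints <- as.integer(round(t(x) * WAV_FULL_SCALE)) # interleave channels
  ch <- ncol(clip@samples)
  sr <- clip@sample_rate
  byte_rate <- sr * ch * 2L
  block_align <- ch * 2L
  data_size <- length(ints) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(ch, con, size = 2L, endian = "little")
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4L, endian = "little")
  writeBin(block_align, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an ingestion manifest
#'
#' A manifest CSV lists one recording per row with columns `file_path`,
#' `source_id`, `label`. Comment lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return data.frame with the three manifest columns.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("file_path", "source_id", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("manifest %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}
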