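#' @import methods
#' @importFrom stats approx fft rnorm runif rbinom sd quantile
#' @importFrom utils head tail read.csv write.csv
NULL

#' Class labels used throughout the pipeline
#'
#' Binary detection alphabet: a window either contains a humpback call
#' (`"humpback"`) or it does not (`"no_call"`). Raw ingested audio may carry
#' `"unknown"` until labeled.
#' @export
whale_classes <- function() c("humpback", "no_call")

#' AudioClip: a labeled waveform
#'
#' An S4 container for a (possibly multi-channel) waveform tied to a recording
#' source. `samples` is a numeric matrix with one column per channel and
#' amplitudes in `[-1, 1]`; `sample_rate` is in Hz. `source_id` identifies the
#' originating recording: whole sources are later assigned to
#' train/validation/test as one unit so that temporally adjacent windows can
#' never straddle splits.
#'
#' @slot samples numeric matrix, frames x channels, amplitudes in `[-1, 1]`.
#' @slot sample_rate integer scalar, Hz.
#' @slot source_id character scalar.
#' @slot label one of `"humpback"`, `"no_call"`, `"unknown"`.
#' @export
setClass("AudioClip",
  representation(
    samples = "matrix",
    sample_rate = "integer",
    source_id = "character",
    label = "character"
  )
)

setValidity("AudioClip", function(object) {
  msgs <- character()
  if (!is.numeric(object@samples)) msgs <- c(msgs, "samples must be numeric")
  if (length(object@sample_rate) != 1L || is.na(object@sample_rate) ||
      object@sample_rate <= 0L) {
    msgs <- c(msgs, "sample_rate must be a positive integer")
  }
  if (!object@label %in% c(whale_classes(), "unknown")) {
    msgs <- c(msgs, sprintf("label must be one of %s",
                            paste(c(whale_classes(), "unknown"), collapse = ", ")))
  }
  if (any(!is.finite(object@samples))) msgs <- c(msgs, "samples must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric vector (mono) or matrix (frames x channels).
#' @param sample_rate sampling rate in Hz.
#' @param source_id identifier of the originating recording.
#' @param label class label (`"humpback"`, `"no_call"` or `"unknown"`).
#' @return An [AudioClip-class] object.
#' @export
audio_clip <- function(samples, sample_rate, source_id = "anonymous",
                       label = "unknown") {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  if (nrow(samples) == 0L) stop("empty clip: no samples")
  new("AudioClip",
      samples = samples,
      sample_rate = as.integer(round(sample_rate)),
      source_id = as.character(source_id),
      label = as.character(label))
}

#' @rdname audio_clip
#' @param clip an [AudioClip-class].
#' @export
clip_samples <- function(clip) clip@samples

#' @rdname audio_clip
#' @export
sample_rate <- function(clip) clip@sample_rate

#' @rdname audio_clip
#' @export
source_id <- function(clip) clip@source_id

#' @rdname audio_clip
#' @export
clip_label <- function(clip) clip@label

#' @rdname audio_clip
#' @export
n_channels <- function(clip) ncol(clip@samples)

#' Duration of a clip in seconds
#'
#' Defined as sample count divided by sample rate, so
#' `duration_s(clip) * sample_rate(clip)` recovers the sample count exactly.
#' @param clip an [AudioClip-class].
#' @export
duration_s <- function(clip) nrow(clip@samples) / clip@sample_rate

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %s | %d ch | %d Hz | %.3f s | label=%s\n",
              object@source_id, ncol(object@samples), object@sample_rate,
              duration_s(object), object@label))
})

# internal: mono waveform as plain vector (errors on multi-channel)
mono_samples <- function(clip) {
  if (ncol(clip@samples) != 1L) {
    stop("expected a mono clip; call standardize() first")
  }
  as.numeric(clip@samples[, 1L])
}
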