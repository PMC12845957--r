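# Fixed-window segmentation and source-based splitting. Windows are 6 s with a
# 3 s hop at 22,050 Hz, i.e. exactly 132,300 samples each, and consecutive
# windows share 66,150 samples. Whole sources are assigned to splits before
# segmentation so adjacent windows can never leak across train/val/test.

WINDOW_S <- 6
HOP_S <- 3
SEGMENT_SAMPLES <- 132300L

#' A single 6-second analysis window
#'
#' @param samples numeric vector of exactly 132,300 samples at 22,050 Hz.
#' @param source_id originating recording.
#' @param start_s window start offset in seconds (a multiple of 3).
#' @param label class label.
#' @return list of class `whale_segment`.
#' @export
segment <- function(samples, source_id, start_s, label) {
  samples <- as.numeric(samples)
  if (length(samples) != SEGMENT_SAMPLES) {
    stop(sprintf("segment must have %d samples, got %d",
                 SEGMENT_SAMPLES, length(samples)))
  }
  structure(
    list(samples = samples, source_id = as.character(source_id),
         start_s = start_s, label = as.character(label)),
    class = "whale_segment"
  )
}

#' @export
print.whale_segment <- function(x, ...) {
  cat(sprintf("whale_segment: %s @ %gs | label=%s\n",
              x$source_id, x$start_s, x$label))
  invisible(x)
}

#' Cut a clip into 6-second windows with 3-second overlap
#'
#' Window starts are 0, 3, 6, ... seconds; a trailing remainder shorter than a
#' full window is dropped, so a clip shorter than 6 s yields no segments. The
#' number of windows is `floor((duration - 6) / 3) + 1` for durations >= 6 s.
#'
#' @param clip a mono [AudioClip-class] at 22,050 Hz (resample first).
#' @param window_s window length in seconds.
#' @param hop_s hop between window starts in seconds.
#' @return list of [segment()] objects (possibly empty).
#' @export
window_clip <- function(clip, window_s = WINDOW_S, hop_s = HOP_S) {
  if (clip@sample_rate != FEATURE_RATE) {
    stop(sprintf("window_clip expects %d Hz audio, got %d Hz; resample first",
                 FEATURE_RATE, clip@sample_rate))
  }
  x <- mono_samples(clip)
  win <- as.integer(round(window_s * FEATURE_RATE))
  hop <- as.integer(round(hop_s * FEATURE_RATE))
  n <- length(x)
  if (n < win) return(list())
  n_win <- (n - win) %/% hop + 1L
  lapply(seq_len(n_win) - 1L, function(k) {
    start <- k * hop
    segment(x[(start + 1L):(start + win)], clip@source_id,
            start_s = k * hop_s, label = clip@label)
  })
}

#' Assign whole sources to train/validation/test
#'
#' Sources are shuffled deterministically by `seed` and partitioned. The
#' validation and test sizes are `round(n * ratio)` (half away from zero) and
#' the remainder goes to train, so 20 sources at 70/15/15 give 14/3/3.
#'
#' @param source_ids character vector of unique source identifiers.
#' @param ratios length-3 numeric summing to 1: train, validation, test.
#' @param seed integer seed controlling the shuffle.
#' @return A `split_manifest`: data.frame (source_id, split) with attributes
#'   `ratios` and `seed`.
#' @export
assign_splits <- function(source_ids, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  source_ids <- as.character(source_ids)
  if (length(source_ids) == 0L) stop("no sources to split")
  if (anyDuplicated(source_ids)) stop("source_ids must be unique")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three numbers summing to 1")
  }
  n <- length(source_ids)
  shuffled <- with_seed(seed, sample(source_ids))
  rha <- function(x) floor(x + 0.5) # round half away from zero (x >= 0)
  n_val <- rha(n * ratios[2L])
  n_test <- rha(n * ratios[3L])
  n_train <- n - n_val - n_test
  if (n_train < 0L) stop("infeasible split: rounding leaves no training sources")
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  manifest <- data.frame(source_id = shuffled, split = split,
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$source_id), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "ratios") <- ratios
  attr(manifest, "seed") <- seed
  class(manifest) <- c("split_manifest", "data.frame")
  manifest
}

#' Look up the split of a source
#' @param manifest a [assign_splits()] manifest.
#' @param source source_id to look up.
#' @export
split_of <- function(manifest, source) {
  i <- match(source, manifest$source_id)
  if (anyNA(i)) {
    stop(sprintf("unknown source_id: %s",
                 paste(source[is.na(i)], collapse = ", ")))
  }
  manifest$split[i]
}

#' Cap the number of segments taken from one source
#'
#' Over-long recordings would otherwise dominate their class; the first
#' `max_segments` windows are retained in temporal order. `NULL` means no cap.
#'
#' @param segments list of [segment()]s from a single source.
#' @param max_segments integer cap, or `NULL` for identity.
#' @return The capped list.
#' @export
cap_source <- function(segments, max_segments = NULL) {
  if (is.null(max_segments)) return(segments)
  max_segments <- as.integer(max_segments)
  if (is.na(max_segments) || max_segments < 0L) {
    stop("max_segments must be a non-negative integer or NULL")
  }
  if (length(segments) > 1L) {
    src <- unique(vapply(segments, `[[`, "", "source_id"))
    if (length(src) != 1L) stop("cap_source expects segments from one source")
  }
  head(segments, max_segments)
}

#' Check a segment set for split leakage
#'
#' A source leaks when its segments occupy more than one split. Any manifest
#' produced by [assign_splits()] is leak-free by construction; this guard
#' exists to catch hand-edited manifests or segment lists.
#'
#' @param manifest a [assign_splits()] manifest.
#' @param segments list of segments, each carrying `source_id` and (optionally)
#'   a `split` field; segments without one inherit the manifest's assignment.
#' @return data.frame of offending sources (zero rows means no leakage).
#' @export
check_no_leakage <- function(manifest, segments) {
  src <- vapply(segments, `[[`, "", "source_id")
  unknown <- setdiff(unique(src), manifest$source_id)
  if (length(unknown)) {
    stop(sprintf("segments reference unknown source_id: %s",
                 paste(unknown, collapse = ", ")))
  }
  seg_split <- vapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (!is.null(s$split)) s$split else split_of(manifest, s$source_id)
  }, "")
  tab <- tapply(seg_split, src, function(s) length(unique(s)))
  bad <- names(tab)[tab > 1L]
  out <- data.frame(source_id = bad, stringsAsFactors = FALSE)
  out$splits <- vapply(bad, function(b) {
    paste(sort(unique(seg_split[src == b])), collapse = "+")
  }, "")
  out
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
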