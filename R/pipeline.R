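# End-to-end experiment driver: corpus -> standardization -> source split ->
# windowing (with per-source capping) -> optional training-set augmentation ->
# feature images -> classifier training -> held-out evaluation.

#' Prepare a segmented, split dataset from a corpus
#'
#' Standardizes every clip (mono, 44.1 kHz, 16-bit grid), resamples to
#' 22,050 Hz, assigns whole sources to train/val/test, windows each source,
#' and caps over-long sources at the 95th percentile of per-source segment
#' counts. Each segment carries its source's split.
#'
#' @param clips list of [AudioClip-class] objects.
#' @param seed integer seed for the source shuffle.
#' @param ratios train/val/test ratios.
#' @param cap_quantile quantile of per-source segment counts used as the
#'   truncation threshold; `NULL` disables capping.
#' @param stratify assign sources to splits within each class label
#'   separately, so every split contains both classes (the 70/15/15 ratios
#'   apply per class). Without stratification a small corpus can draw a
#'   single-class validation split, which makes validation-loss
#'   checkpointing meaningless.
#' @return list: `segments` (list of [segment()]s with `split` fields) and
#'   `split_manifest`.
#' @export
prepare_dataset <- function(clips, seed = 1L, ratios = c(0.70, 0.15, 0.15),
                            cap_quantile = 0.95, stratify = TRUE) {
  prepared <- lapply(clips, function(cl) resample(standardize(cl), FEATURE_RATE))
  ids <- vapply(prepared, source_id, "")
  labels <- vapply(prepared, clip_label, "")
  if (stratify && length(unique(labels)) > 1L) {
    parts <- lapply(unique(labels), function(lb) {
      as.data.frame(assign_splits(ids[labels == lb], ratios, seed))
    })
    manifest <- do.call(rbind, parts)
    manifest <- manifest[order(manifest$source_id), , drop = FALSE]
    rownames(manifest) <- NULL
    attr(manifest, "ratios") <- ratios
    attr(manifest, "seed") <- seed
    class(manifest) <- c("split_manifest", "data.frame")
  } else {
    manifest <- assign_splits(ids, ratios, seed)
  }
  per_source <- lapply(prepared, window_clip)
  counts <- vapply(per_source, length, 0L)
  if (!is.null(cap_quantile)) {
    cap <- as.integer(ceiling(quantile(counts[counts > 0], cap_quantile)))
    per_source <- lapply(per_source, cap_source, max_segments = cap)
  }
  segments <- list()
  for (i in seq_along(per_source)) {
    segs <- per_source[[i]]
    if (length(segs) == 0L) next
    spl <- split_of(manifest, ids[i])
    segs <- lapply(segs, function(s) {
      s$split <- spl
      s
    })
    segments <- c(segments, segs)
  }
  leak <- check_no_leakage(manifest, segments)
  stopifnot(nrow(leak) == 0L)
  list(segments = segments, split_manifest = manifest)
}

segment_split <- function(segments) {
  vapply(segments, function(s) s$split %||% NA_character_, "")
}

segment_labels <- function(segments) vapply(segments, `[[`, "", "label")

# label string -> integer index in the class alphabet
label_index <- function(labels) match(labels, whale_classes())

# list of segments -> standardized feature image batch (125 x 50 x 3 x N)
featurize_batch <- function(segments, kind = "mel", params = spectro_params(),
                            colormap_name = "viridis") {
  n <- length(segments)
  x <- array(0, c(125L, 50L, 3L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- featurize_segment(segments[[i]], kind, params, colormap_name)
  }
  x
}

#' Run one detection experiment on a synthetic corpus
#'
#' Generates the corpus, prepares the split dataset, optionally expands the
#' training split with five augmented variants per window (keeping the
#' originals alongside), renders feature images, trains the requested
#' classifier, and evaluates on the held-out test sources.
#'
#' @param params a [synth_params()] describing the corpus.
#' @param seed master seed for corpus, split, augmentation and training.
#' @param augment logical: apply training-set augmentation.
#' @param include_originals keep original windows alongside their augmented
#'   variants in the training set.
#' @param arch `"cnn"` or `"vit"`.
#' @param features `"mel"` or `"delta_mfcc"`.
#' @param train_cfg a [train_config()]; defaults to the architecture's
#'   standard configuration.
#' @param verbose print progress.
#' @return list of class `whale_experiment`: `report` (an `eval_report` with
#'   curves), `model`, `history`, `split_manifest`, `counts`.
#' @export
run_experiment <- function(params = synth_params(), seed = 1L,
                           augment = TRUE, include_originals = TRUE,
                           arch = c("cnn", "vit"),
                           features = c("mel", "delta_mfcc"),
                           train_cfg = NULL, verbose = FALSE) {
  arch <- match.arg(arch)
  features <- match.arg(features)
  say <- function(...) if (verbose) message(sprintf(...))

  say("synthesizing corpus (%d sources)...",
      params$n_call_sources + params$n_nocall_sources)
  corpus <- synth_corpus(params, seed)
  say("segmenting and splitting sources...")
  ds <- prepare_dataset(corpus$clips, seed = seed)
  split <- segment_split(ds$segments)
  train_segs <- ds$segments[split == "train"]
  val_segs <- ds$segments[split == "val"]
  test_segs <- ds$segments[split == "test"]
  if (!length(train_segs) || !length(val_segs) || !length(test_segs)) {
    stop("a split is empty; enlarge the corpus")
  }
  sp <- spectro_params()

  say("featurizing %d train / %d val / %d test windows...",
      length(train_segs), length(val_segs), length(test_segs))
  train_imgs <- featurize_batch(train_segs, features, sp)
  train_lab <- label_index(segment_labels(train_segs))
  if (augment) {
    acfg <- augment_config(seed = seed)
    say("augmenting training split (%d windows x %d variants)...",
        length(train_segs), acfg$variants_per_clip)
    aug_feats <- expand_training(train_segs, acfg, callback = function(v) {
      list(img = featurize_segment(v, features, sp), label = v$label)
    })
    aug_x <- array(0, c(125L, 50L, 3L, length(aug_feats)))
    for (i in seq_along(aug_feats)) aug_x[, , , i] <- aug_feats[[i]]$img
    aug_lab <- label_index(vapply(aug_feats, `[[`, "", "label"))
    if (include_originals) {
      train_x <- array(0, c(125L, 50L, 3L, length(train_lab) + length(aug_lab)))
      train_x[, , , seq_along(train_lab)] <- train_imgs
      train_x[, , , length(train_lab) + seq_along(aug_lab)] <- aug_x
      train_y <- c(train_lab, aug_lab)
    } else {
      train_x <- aug_x
      train_y <- aug_lab
    }
  } else {
    train_x <- train_imgs
    train_y <- train_lab
  }
  val_x <- featurize_batch(val_segs, features, sp)
  val_y <- label_index(segment_labels(val_segs))
  test_x <- featurize_batch(test_segs, features, sp)
  test_y <- label_index(segment_labels(test_segs))

  if (is.null(train_cfg)) train_cfg <- train_config(arch, seed = seed)
  say("training %s on %d windows (batch %d, max %d epochs)...",
      arch, length(train_y), train_cfg$batch_size, train_cfg$max_epochs)
  model <- if (arch == "cnn") build_cnn(seed = seed) else build_vit(seed = seed)
  model <- train_model(model, train_x, train_y, val_x, val_y, train_cfg,
                       verbose = verbose)

  say("evaluating on held-out test sources...")
  probs <- predict(model, test_x)
  true_lab <- whale_classes()[test_y]
  eps <- 1e-12
  losses <- -log(pmax(probs[cbind(seq_along(test_y), test_y)], eps))
  report <- evaluate_predictions(true_lab, probs[, 1L], losses)

  structure(list(report = report, model = model, history = model$history,
                 split_manifest = ds$split_manifest,
                 counts = c(train = length(train_y), val = length(val_y),
                            test = length(test_y)),
                 arch = arch, features = features, augment = augment,
                 seed = seed),
            class = "whale_experiment")
}

#' @export
print.whale_experiment <- function(x, ...) {
  cat(sprintf("whale_experiment: %s + %s features, augmentation %s, seed %d\n",
              x$arch, x$features, if (x$augment) "on" else "off", x$seed))
  cat(sprintf("  windows: %d train / %d val / %d test\n",
              x$counts["train"], x$counts["val"], x$counts["test"]))
  print(x$report)
  invisible(x)
}

#' Sliding-window detection over an arbitrary recording
#'
#' Applies the full preprocessing chain (standardize, resample, 6 s window
#' with 3 s hop, featurize) and returns per-window call probabilities — the
#' real-time pattern in which predictions refresh every three seconds.
#'
#' @param model a trained `whale_model`.
#' @param clip an [AudioClip-class] of any length >= 6 s.
#' @param features `"mel"` or `"delta_mfcc"`.
#' @return data.frame: start_s, p_humpback, p_no_call, predicted.
#' @export
detect_calls <- function(model, clip, features = "mel") {
  prepared <- resample(standardize(clip), FEATURE_RATE)
  segs <- window_clip(prepared)
  if (length(segs) == 0L) {
    return(data.frame(start_s = numeric(), p_humpback = numeric(),
                      p_no_call = numeric(), predicted = character()))
  }
  probs <- predict(model, featurize_batch(segs, features))
  data.frame(
    start_s = vapply(segs, `[[`, 0, "start_s"),
    p_humpback = probs[, "humpback"],
    p_no_call = probs[, "no_call"],
    predicted = whale_classes()[max.col(probs, "first")]
  )
}
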