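test_that("noise-only path adds Gaussian noise in the 1-1.5% full-scale range", {
  seg <- tone_segment(300, amp = 0.3)
  cfg <- augment_config(p_apply = c(1, 0, 0, 0))
  withr::with_seed(2, {
    for (rep in 1:5) {
      out <- apply_augmentations(seg, cfg)
      expect_length(out$samples, SEG_N)
      resid_sd <- sd(out$samples - seg$samples)
      expect_gte(resid_sd, 0.010 * 0.93) # sampling noise on sd at n = 132300 is tiny
      expect_lte(resid_sd, 0.015 * 1.07)
      expect_identical(attr(out, "operators_applied"), "noise")
    }
  })
})

test_that("every operator preserves the exact window length", {
  seg <- tone_segment(500, amp = 0.4)
  for (op in 1:4) {
    p <- rep(0, 4)
    p[op] <- 1
    withr::with_seed(op, {
      out <- apply_augmentations(seg, augment_config(p_apply = p))
      expect_length(out$samples, SEG_N)
      expect_true(all(abs(out$samples) <= 1))
    })
  }
})

test_that("pitch shift scales the dominant frequency by 2^(semitones/12)", {
  x <- 0.5 * sin(2 * pi * 440 * (seq_len(SEG_N) - 1) / FEATURE_SR)
  for (s in c(-12, -5, 7, 12)) {
    y <- pitch_shift(x, s, FEATURE_SR)
    expect_length(y, SEG_N)
    # measure away from the vocoder edges
    got <- dominant_freq(y[20000:100000], FEATURE_SR)
    expect_equal(got, 440 * 2^(s / 12), tolerance = 0.02)
  }
})

test_that("high-pass augmentation attenuates sub-cutoff energy", {
  seg <- tone_segment(200, amp = 0.5) # 200 Hz tone, far below the 1-2 kHz cutoff
  withr::with_seed(5, {
    out <- apply_augmentations(seg, augment_config(p_apply = c(0, 0, 1, 0)))
  })
  expect_lt(sqrt(mean(out$samples^2)), 0.05 * sqrt(mean(seg$samples^2)))
})

test_that("rollover time shift moves a click modularly: +3 s on a click at 4 s lands at 1 s", {
  seg <- click_segment(4)
  shifted <- whaledet:::roll_shift(seg$samples, as.integer(3 * FEATURE_SR))
  expect_equal((which.max(shifted) - 1) / FEATURE_SR, 1, tolerance = 1e-6)
  # negative shift wraps the other way: -2 s on a click at 1 s lands at 5 s
  seg2 <- click_segment(1)
  back <- whaledet:::roll_shift(seg2$samples, as.integer(-2 * FEATURE_SR))
  expect_equal((which.max(back) - 1) / FEATURE_SR, 5, tolerance = 1e-6)
})

test_that("the rejection rule guarantees at least one operator fires", {
  withr::with_seed(9, {
    for (rep in 1:200) {
      mask <- draw_operator_mask(rep(0.5, 4))
      expect_true(any(mask))
    }
  })
})

test_that("expand_training emits exactly five reproducible variants per window", {
  segs <- lapply(c(350, 520), function(f) {
    s <- tone_segment(f)
    s$split <- "train"
    s
  })
  cfg <- augment_config(seed = 77)
  v1 <- expand_training(segs, cfg)
  v2 <- expand_training(segs, cfg)
  expect_length(v1, 10L)
  expect_identical(lapply(v1, `[[`, "samples"), lapply(v2, `[[`, "samples"))
  for (v in v1) expect_length(v$samples, SEG_N)
  # labels ride along untouched
  expect_identical(vapply(v1, `[[`, "", "label"), rep("humpback", 10L))
})

test_that("no augmented variant is bit-identical to its original", {
  seg <- tone_segment(640)
  seg$split <- "train"
  for (sd in 1:6) {
    vs <- expand_training(list(seg), augment_config(seed = sd))
    for (v in vs) expect_false(identical(v$samples, seg$samples))
  }
})

test_that("augmentation refuses validation and test segments", {
  seg <- tone_segment(500)
  for (spl in c("val", "test")) {
    seg$split <- spl
    expect_error(expand_training(list(seg), augment_config()), "training-only")
  }
})

test_that("variant metadata records operators and drawn parameters", {
  seg <- tone_segment(450)
  withr::with_seed(31, {
    out <- apply_augmentations(seg, augment_config())
  })
  ops <- attr(out, "operators_applied")
  pars <- attr(out, "draw_parameters")
  expect_gte(length(ops), 1L)
  expect_identical(length(pars), length(ops))
})
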