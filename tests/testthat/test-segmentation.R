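test_that("window counts follow the 6 s / 3 s hop rule", {
  expect_length(window_clip(audio_clip(numeric(6 * 22050) + 0.1, 22050)), 1L)
  expect_length(window_clip(audio_clip(numeric(12 * 22050) + 0.1, 22050)), 3L)
  expect_length(window_clip(audio_clip(numeric(round(5.9 * 22050)) + 0.1, 22050)), 0L)
  segs <- window_clip(audio_clip(numeric(12 * 22050) + 0.1, 22050))
  expect_equal(vapply(segs, `[[`, 0, "start_s"), c(0, 3, 6))
})

test_that("window-count formula matches brute-force enumeration of valid starts", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      dur <- runif(1, 1, 40)
      n <- round(dur * 22050)
      clip <- audio_clip(numeric(n) + 0.1, 22050)
      got <- length(window_clip(clip))
      starts <- seq(0, 1e6, by = 3 * 22050)
      brute <- sum(starts + 132300 <= n)
      expect_identical(got, as.integer(brute))
    }
  })
})

test_that("segments are exactly 132,300 samples and consecutive windows share 66,150", {
  x <- rnorm(round(9.5 * 22050)) * 0.2
  segs <- window_clip(audio_clip(x, 22050))
  expect_length(segs, 2L)
  for (s in segs) expect_length(s$samples, 132300L)
  expect_identical(segs[[1]]$samples[66151:132300], segs[[2]]$samples[1:66150])
})

test_that("window_clip refuses audio at the wrong rate", {
  expect_error(window_clip(audio_clip(numeric(44100 * 7) + 0.1, 44100)), "resample")
})

test_that("70/15/15 split of 20 sources gives 14/3/3 with remainder to train", {
  m <- assign_splits(sprintf("s%02d", 1:20), c(0.7, 0.15, 0.15), seed = 5)
  expect_equal(as.vector(table(m$split)[c("train", "val", "test")]), c(14L, 3L, 3L))
})

test_that("degenerate ratios and determinism behave as declared", {
  ids <- sprintf("s%02d", 1:11)
  all_train <- assign_splits(ids, c(1, 0, 0), seed = 3)
  expect_true(all(all_train$split == "train"))
  a <- assign_splits(ids, seed = 42)
  b <- assign_splits(ids, seed = 42)
  expect_identical(a$split, b$split)
  expect_error(assign_splits(character(0)), "no sources")
})

test_that("split assignment partitions sources for arbitrary corpus sizes", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(3:200, 1)
      ids <- sprintf("src%04d", seq_len(n))
      m <- assign_splits(ids, seed = rep)
      expect_setequal(m$source_id, ids)
      expect_identical(anyDuplicated(m$source_id), 0L)
      expect_true(all(m$split %in% c("train", "val", "test")))
    }
  })
})

test_that("cap_source keeps a temporal prefix and handles edge cases", {
  segs <- window_clip(audio_clip(numeric(30 * 22050) + 0.1, 22050))
  expect_length(segs, 9L)
  capped <- cap_source(segs, 4L)
  expect_length(capped, 4L)
  expect_equal(vapply(capped, `[[`, 0, "start_s"), c(0, 3, 6, 9))
  expect_identical(cap_source(segs, NULL), segs)
  expect_length(cap_source(segs, 0L), 0L)
  expect_error(cap_source(segs, -1L), "non-negative")
})

test_that("check_no_leakage flags hand-built cross-split sources and only those", {
  m <- assign_splits(c("a", "b", "c", "d"), seed = 1)
  segs <- list(
    list(source_id = "a", split = "train"),
    list(source_id = "a", split = "test"), # leaked
    list(source_id = "b", split = "val")
  )
  rep <- check_no_leakage(m, segs)
  expect_equal(rep$source_id, "a")
  expect_match(rep$splits, "test")
  expect_error(check_no_leakage(m, list(list(source_id = "zz", split = "train"))),
               "unknown source_id")
})

test_that("manifests from assign_splits never leak across fuzzed corpora", {
  withr::with_seed(123, {
    for (rep in 1:50) {
      n <- sample(3:60, 1)
      ids <- sprintf("s%03d", seq_len(n))
      m <- assign_splits(ids, seed = rep)
      segs <- lapply(sample(ids, 4 * n, replace = TRUE), function(sid) {
        list(source_id = sid, split = split_of(m, sid))
      })
      expect_identical(nrow(check_no_leakage(m, segs)), 0L)
    }
  })
})
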