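test_that("confusion tallies match a brute-force count and reject bad input", {
  expect_error(confusion(c("humpback"), c("humpback", "no_call")), "length")
  expect_error(confusion("whale", "humpback"), "unknown labels")
  perfect <- confusion(rep(whale_classes(), 5), rep(whale_classes(), 5))
  expect_identical(sum(unclass(perfect)[row(matrix(0, 2, 2)) != col(matrix(0, 2, 2))]), 0L)
  withr::with_seed(4, {
    for (rep in 1:20) {
      n <- sample(5:200, 1)
      truth <- sample(whale_classes(), n, replace = TRUE)
      pred <- sample(whale_classes(), n, replace = TRUE)
      cm <- unclass(confusion(truth, pred))
      for (i in 1:2) for (j in 1:2) {
        expect_identical(cm[i, j],
                         sum(truth == whale_classes()[i] & pred == whale_classes()[j]))
      }
    }
  })
})

test_that("the published worked example reproduces through the evaluation module", {
  # 270 humpback windows with 263 correct; 1207 no-call with 1198 correct
  cm <- confusion_from_counts(rbind(c(263, 7), c(9, 1198)))
  r <- summarize(cm)
  expect_equal(round(100 * r$accuracy, 2), 98.92)
  expect_equal(round(r$mcc, 2), 0.96)
  hp <- r$per_class$humpback
  expect_equal(round(100 * c(hp$precision, hp$recall, hp$f1)), c(97, 97, 97))
  expect_identical(hp$support, 270L)
  nc <- r$per_class$no_call
  expect_equal(round(100 * c(nc$precision, nc$recall, nc$f1)), c(99, 99, 99))
  expect_equal(round(100 * unname(r$error_rates["error_rate_humpback"]), 2), 2.59)
  expect_equal(round(100 * unname(r$error_rates["error_rate_nocall"]), 2), 0.75)
  expect_equal(round(100 * unname(r$macro["f1"])), 98)
  expect_equal(round(100 * unname(r$weighted["f1"])), 99)
})

test_that("perfect and degenerate confusion matrices hit the documented conventions", {
  perfect <- summarize(confusion_from_counts(rbind(c(50, 0), c(0, 70))))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  one_class <- summarize(confusion_from_counts(rbind(c(30, 0), c(20, 0))))
  expect_equal(one_class$mcc, 0) # 0/0 convention
  expect_true(one_class$degenerate)
})

test_that("summarize agrees with an independent per-metric oracle on random matrices", {
  # oracle: precision/recall from raw indicator vectors, MCC as the Pearson
  # correlation of the binary truth/prediction indicators
  withr::with_seed(10, {
    for (rep in 1:200) {
      cm <- matrix(sample(0:60, 4, replace = TRUE), 2, 2)
      if (sum(cm) == 0) next
      r <- summarize(confusion_from_counts(cm))
      truth <- rep(c(1, 1, 0, 0), times = as.vector(t(cm)))
      pred <- rep(c(1, 0, 1, 0), times = as.vector(t(cm)))
      expect_equal(r$accuracy, mean(truth == pred))
      if (sum(pred) > 0) {
        expect_equal(r$per_class$humpback$precision,
                     sum(truth & pred) / sum(pred))
      }
      if (sum(truth) > 0) {
        expect_equal(r$per_class$humpback$recall,
                     sum(truth & pred) / sum(truth))
      }
      if (sd(truth) > 0 && sd(pred) > 0) {
        expect_equal(r$mcc, cor(truth, pred), tolerance = 1e-12)
      }
    }
  })
})

test_that("swapping the class order swaps error-rate orientation but not accuracy or |MCC|", {
  cm <- rbind(c(80, 12), c(5, 40))
  a <- summarize(confusion_from_counts(cm))
  b <- summarize(confusion_from_counts(cm[2:1, 2:1],
                                       classes = rev(whale_classes())))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(abs(a$mcc), abs(b$mcc))
  expect_equal(unname(a$error_rates["error_rate_humpback"]),
               unname(b$error_rates["error_rate_humpback"]))
  expect_equal(unname(a$error_rates["error_rate_nocall"]),
               unname(b$error_rates["error_rate_nocall"]))
})

test_that("weighted F1 equals macro F1 when supports are equal", {
  cm <- rbind(c(40, 10), c(7, 43))
  r <- summarize(confusion_from_counts(cm))
  expect_equal(unname(r$macro["f1"]), unname(r$weighted["f1"]))
})

test_that("perfectly separated scores give ROC area 1; label-free scores give ~0.5", {
  truth <- rep(whale_classes(), each = 50)
  scores <- c(runif(50, 0.8, 1), runif(50, 0, 0.2))
  expect_equal(roc_pr(scores, truth)$auc, 1)
  withr::with_seed(6, {
    n <- 10000
    truth2 <- sample(whale_classes(), n, replace = TRUE)
    scores2 <- runif(n)
    expect_equal(roc_pr(scores2, truth2)$auc, 0.5, tolerance = 0.02)
  })
})

test_that("trapezoidal ROC area equals the pairwise-concordance probability", {
  withr::with_seed(8, {
    for (rep in 1:30) {
      n <- sample(20:80, 1)
      truth <- sample(whale_classes(), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
      auc <- roc_pr(scores, truth)$auc
      pos <- scores[truth == "humpback"]
      neg <- scores[truth == "no_call"]
      conc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
      expect_equal(auc, conc, tolerance = 1e-9)
    }
  })
})

test_that("ROC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    truth <- sample(whale_classes(), 300, replace = TRUE)
    scores <- ifelse(truth == "humpback", rnorm(300, 0.6, 0.2), rnorm(300, 0.4, 0.2))
    scores <- pmin(pmax(scores, 0), 1)
    ours <- roc_pr(scores, truth)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("no_call", "humpback"),
      direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("single-class truth raises an error naming the missing class", {
  expect_error(roc_pr(runif(5), rep("humpback", 5)), "humpback")
  expect_error(roc_pr(runif(5), rep("no_call", 5)), "humpback")
  expect_error(roc_pr(c(0.5, 1.2), whale_classes()), "\\[0, 1\\]")
})

test_that("evaluate_predictions assembles report plus curves from probabilities", {
  withr::with_seed(3, {
    truth <- sample(whale_classes(), 100, replace = TRUE)
    p <- ifelse(truth == "humpback", 0.9, 0.1) + rnorm(100, 0, 0.05)
    p <- pmin(pmax(p, 0), 1)
  })
  r <- evaluate_predictions(truth, p)
  expect_s3_class(r, "eval_report")
  expect_gt(r$accuracy, 0.9)
  expect_gt(r$curves$auc, 0.95)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$accuracy, r$accuracy)
})
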