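# build a pooled-scores data frame directly; calibration only needs
# svm_score and label columns
held <- function(scores, labels) {
  tibble::tibble(
    svm_score = scores,
    label = ifelse(labels == 1, "positive", "negative")
  )
}

test_that("bin lower bounds are one-sided binomial confidence limits", {
  # two clean bins: low scores all negative, high scores all positive
  h <- held(c(seq(0, 1, length.out = 50), seq(2, 3, length.out = 50)),
            rep(c(0, 1), each = 50))
  calib <- build_calibration(h, bins = 2, confidence = 0.95)
  expect_equal(nrow(calib), 2L)
  expect_equal(calib$lower_bound[[1]], 0)          # 0 positives of 50
  # 50 of 50 positive: closed-form Clopper-Pearson limit 0.05^(1/50)
  expect_equal(calib$lower_bound[[2]], 0.05^(1 / 50), tolerance = 1e-12)
  expect_gt(calib$lower_bound[[2]], 0.9)
  expect_lte(calib$lower_bound[[2]], 1.0)
  expect_true(all(calib$lower_bound <= calib$precision))
})

test_that("non-monotone bin precisions are pooled into a non-decreasing table", {
  set.seed(8)
  # middle score band deliberately richer in positives than the top band
  scores <- c(runif(100, 0, 1), runif(100, 1, 2), runif(100, 2, 3))
  labels <- c(
    rbinom(100, 1, 0.05), rbinom(100, 1, 0.9), rbinom(100, 1, 0.4)
  )
  calib <- build_calibration(held(scores, labels), bins = 6)
  expect_true(all(diff(calib$lower_bound) >= 0))
  expect_true(all(diff(calib$precision) >= -1e-12))
  expect_true(all(calib$lower_bound <= calib$precision + 1e-12))
  expect_equal(sum(calib$n), 300L)
})

test_that("score lookup clamps to the outermost bins", {
  h <- held(1:100, rep(c(0, 1), each = 50))
  calib <- build_calibration(h, bins = 4)
  expect_equal(
    estimate_precision(calib, -10),
    calib$lower_bound[[1]]
  )
  expect_equal(
    estimate_precision(calib, 1e6),
    calib$lower_bound[[nrow(calib)]]
  )
})

test_that("lift is the precision ratio over the base rate", {
  expect_equal(lift(0.0123, 0.0123), 1.0)
  expect_equal(lift(0.3910, 0.0123), 31.79, tolerance = 0.01 / 31.79)
  expect_equal(lift(0.1722, 0.0123), 14.0, tolerance = 1e-3)
  expect_error(lift(0.5, 0), class = "og_config_error")
})

test_that("calibration lower bounds cover the true precision at nominal confidence", {
  # synthetic score model: score s ~ U(0,1), P(positive | s) = s, so the
  # true precision of any score bin is the mean score inside it
  set.seed(31)
  hits <- 0L
  total <- 0L
  for (rep in 1:30) {
    s <- runif(1500)
    y <- as.integer(runif(1500) < s)
    calib <- build_calibration(held(s, y), bins = 8, confidence = 0.95)
    truth <- vapply(seq_len(nrow(calib)), function(i) {
      inside <- s >= calib$score_lo[[i]] & s <= calib$score_hi[[i]]
      mean(s[inside])
    }, numeric(1))
    hits <- hits + sum(truth >= calib$lower_bound)
    total <- total + nrow(calib)
  }
  coverage <- hits / total
  expect_gte(coverage, 0.95 - 2 * sqrt(0.05 * 0.95 / total))
})

test_that("ranked reports respect threshold, ordering and secreted flags", {
  sim <- small_corpus()
  d <- assemble_dataset(sim$proteins, sim$annotations)
  cv <- og_grid_cv(d, 1, 2^-6, folds = 5, seed = 2)
  calib <- build_calibration(cv, bins = 10)
  model <- og_calibrate(og_train(d, cv$best_params), calib)

  p1 <- sim$proteins[1, ]
  st_count <- nrow(extract_candidate_sites(p1))
  all_rows <- rank_report(p1, model, threshold = 0)
  expect_equal(nrow(all_rows), st_count)
  expect_true(all(diff(all_rows$svm_score) <= 0))
  expect_equal(all_rows$lift, all_rows$estimated_precision / 0.0123)

  top <- rank_report(p1, model, threshold = 1.0)
  expect_true(all(top$estimated_precision >= 1.0))

  flagged <- rank_report(p1, model, threshold = 0, secreted = p1$id)
  expect_true(all(flagged$flagged))

  # a protein with no Ser/Thr yields an empty report, not an error
  none <- protein("bare", "MAGGAGAGA")
  expect_equal(nrow(rank_report(none, model, threshold = 0)), 0L)

  # an uncalibrated model is refused
  expect_error(
    rank_report(p1, og_train(d, cv$best_params)),
    class = "og_config_error"
  )
})

test_that("a strongly planted site ranks first in its protein", {
  sim <- small_corpus()
  d <- assemble_dataset(sim$proteins, sim$annotations)
  cv <- og_grid_cv(d, 1, 2^-6, folds = 5, seed = 2)
  model <- og_calibrate(og_train(d, cv$best_params), build_calibration(cv))
  # fresh protein: random non-S/T background with one full-strength
  # motif window planted in the middle
  set.seed(12)
  ch <- sample(setdiff(og_alphabet()[1:20], c("S", "T", "P", "V", "A")),
    200,
    replace = TRUE
  )
  ch[100:105] <- c("P", "P", "V", "S", "T", "A")
  fresh <- protein("fresh", paste(ch, collapse = ""))
  rep <- rank_report(fresh, model, threshold = 0)
  expect_equal(rep$position[[1]], 103L)
})
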