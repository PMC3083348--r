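# 20 positive and 20 negative single-site proteins, separable by one
# flank feature: positives carry Pro at -1, negatives Gly
separable_corpus <- function() {
  pos <- purrr::map(1:20, function(i) {
    protein(paste0("pos", i), paste0(random_sequence(4, FALSE), "PS", random_sequence(4, FALSE)))
  })
  neg <- purrr::map(1:20, function(i) {
    protein(paste0("neg", i), paste0(random_sequence(4, FALSE), "GS", random_sequence(4, FALSE)))
  })
  proteins <- dplyr::bind_rows(pos, neg)
  ann <- annotation(paste0("pos", 1:20), 6, "S")
  list(proteins = proteins, annotations = ann)
}

test_that("training on a separable corpus separates the classes", {
  set.seed(1)
  corp <- separable_corpus()
  d <- assemble_dataset(corp$proteins, corp$annotations, window_config(2))
  m <- og_train(d, og_params(cost = 10))
  scored <- og_score(d, m)
  expect_gt(
    min(scored$svm_score[scored$label == "positive"]),
    max(scored$svm_score[scored$label == "negative"])
  )
})

test_that("retraining with identical inputs gives bit-identical scores", {
  set.seed(1)
  corp <- separable_corpus()
  d <- assemble_dataset(corp$proteins, corp$annotations, window_config(2))
  m1 <- og_train(d, og_params(cost = 2), seed = 5)
  m2 <- og_train(d, og_params(cost = 2), seed = 5)
  expect_identical(og_score(d, m1)$svm_score, og_score(d, m2)$svm_score)
})

test_that("single-class input is a training error", {
  p <- protein("p1", "MASTGSAT")
  d <- assemble_dataset(p, NULL, window_config(2))
  expect_error(og_train(d), class = "og_training_error")
})

test_that("model archives round trip to identical scores", {
  sim <- small_corpus()
  d <- assemble_dataset(sim$proteins, sim$annotations)
  m <- og_train(d, og_params(cost = 1, gamma = 2^-6))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(og_score(d, m)$svm_score, og_score(d, m2)$svm_score)
  expect_equal(glance(m2)$n, 5)
})

test_that("scoring refuses a dataset encoded with a different window", {
  sim <- small_corpus()
  d5 <- assemble_dataset(sim$proteins, sim$annotations, window_config(5))
  d3 <- assemble_dataset(sim$proteins, sim$annotations, window_config(3))
  m <- og_train(d3, og_params(cost = 1))
  expect_error(og_score(d5, m), class = "og_config_error")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0)), 1.0) # strict separation
  set.seed(20)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(round(stats::rnorm(n), 1)) # rounding forces ties
    expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels))
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(21)
  scores <- stats::rnorm(100)
  labels <- sample(0:1, 100, replace = TRUE)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(5 * scores + 3, labels), a)
  expect_equal(roc_auc(-scores, labels), 1 - a) # no ties in rnorm draws
  expect_error(roc_auc(scores, rep(1, 100)), class = "og_contract_error")
})

test_that("random scores give AUC near one half", {
  set.seed(22)
  n <- 4000
  a <- roc_auc(stats::rnorm(n), sample(0:1, n, replace = TRUE))
  se <- sqrt((n + 1) / (12 * (n / 2)^2)) # Mann-Whitney null sd, balanced classes
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("grid search equals an exhaustive loop oracle and honours the tie rule", {
  sim <- generate_corpus(sim_config(
    n_proteins = 12, length_meanlog = log(250), length_sdlog = 0.1,
    positive_rate = 0.08, seed = 77
  ))
  d <- assemble_dataset(sim$proteins, sim$annotations, window_config(3))
  cost_grid <- c(1, 4)
  gamma_grid <- c(2^-6, 2^-3)
  cv <- og_grid_cv(d, cost_grid, gamma_grid, folds = 3, seed = 13)

  # independent oracle: same folds, explicit loop over every pair
  fold <- oglcnacr:::cv_folds(d, 3, "by_protein", seed = 13)
  oracle <- tidyr::expand_grid(cost = cost_grid, gamma = gamma_grid)
  oracle$auc <- purrr::pmap_dbl(oracle, function(cost, gamma) {
    held <- purrr::map(1:3, function(k) {
      m <- og_train(oglcnacr:::subset_dataset(d, fold != k), og_params(cost, gamma))
      og_score(oglcnacr:::subset_dataset(d, fold == k), m)
    })
    held <- dplyr::bind_rows(held)
    roc_auc(held$svm_score, held$label)
  })
  grid <- dplyr::arrange(tidy(cv), .data$cost, .data$gamma)
  oracle <- dplyr::arrange(oracle, .data$cost, .data$gamma)
  expect_equal(grid$auc_pooled, oracle$auc)

  # selected pair is the lexicographically smallest among the argmax set
  best <- oracle[oracle$auc == max(oracle$auc), ]
  best <- best[order(best$cost, best$gamma), ][1, ]
  expect_equal(cv$best_params$cost, best$cost)
  expect_equal(cv$best_params$gamma, best$gamma)

  # a one-pair grid returns that pair with its CV AUC
  one <- og_grid_cv(d, 2, 2^-5, folds = 3, seed = 13)
  expect_equal(one$best_params$cost, 2)
  expect_equal(one$best_params$gamma, 2^-5)
  expect_equal(nrow(tidy(one)), 1L)
})

test_that("held-out folds partition the data and protein grouping is respected", {
  sim <- small_corpus()
  d <- assemble_dataset(sim$proteins, sim$annotations)
  cv <- og_grid_cv(d, 1, 2^-6, folds = 5, seed = 4)
  expect_equal(nrow(cv$held_out), nrow(d))
  expect_equal(sort(table(cv$held_out$label)), sort(table(d$label)))
  by_protein <- tapply(cv$fold, d$protein_id, function(f) length(unique(f)))
  expect_true(all(by_protein == 1L))
  expect_error(
    og_grid_cv(d, numeric(), 1, folds = 5),
    class = "og_config_error"
  )
})
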