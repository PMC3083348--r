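#' SVM hyper-parameters
#'
#' @param cost Soft-margin cost `C` (> 0).
#' @param gamma RBF kernel width (> 0); `NULL` defaults at fit time to
#'   1 / (number of features), the usual radial-kernel heuristic.
#' @return An object of class `og_params`.
#' @export
og_params <- function(cost = 1, gamma = NULL) {
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0) {
    rlang::abort("cost must be a single positive number", class = "og_config_error")
  }
  if (!is.null(gamma) && (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)) {
    rlang::abort("gamma must be a single positive number", class = "og_config_error")
  }
  structure(list(cost = cost, gamma = gamma), class = "og_params")
}

#' Train the RBF-kernel site classifier
#'
#' Fits a support vector machine with a radial basis function kernel on the
#' one-hot encoded instances of an [assemble_dataset()] result. Higher decision
#' scores mean more site-like. Training is deterministic given the data, the
#' parameters and the seed recorded in the model metadata.
#'
#' @param dataset An `og_dataset` containing both classes.
#' @param params [og_params()] with `cost` and `gamma`.
#' @param class_weights Optional named vector of class weights
#'   (`c(positive = ..., negative = ...)`) for cost-sensitive training; the
#'   default trains on the raw imbalanced corpus.
#' @param seed Integer seed recorded in the model metadata.
#' @return An object of class `og_model`.
#' @export
og_train <- function(dataset, params = og_params(), class_weights = NULL, seed = 1L) {
  x <- og_features(dataset)
  y <- factor(dataset$label, levels = c("positive", "negative"))
  if (dplyr::n_distinct(dataset$label) < 2L) {
    rlang::abort("training requires both positive and negative instances",
      class = "og_training_error"
    )
  }
  gamma <- params$gamma %||% (1 / ncol(x))
  set.seed(seed)
  fit <- e1071::svm(
    x, y,
    type = "C-classification", kernel = "radial",
    cost = params$cost, gamma = gamma,
    scale = FALSE, cachesize = 256,
    class.weights = class_weights
  )
  structure(
    list(
      fit = fit,
      params = og_params(cost = params$cost, gamma = gamma),
      window = og_window(dataset),
      alphabet = og_alphabet(),
      calibration = NULL,
      meta = list(
        n_instances = nrow(x),
        n_positive = sum(dataset$label == "positive"),
        n_negative = sum(dataset$label == "negative"),
        seed = seed,
        version = as.character(utils::packageVersion("oglcnacr"))
      )
    ),
    class = "og_model"
  )
}

#' @export
print.og_model <- function(x, ...) {
  cat(
    "<og_model> RBF-kernel SVM site classifier\n",
    "  window n = ", x$window$n,
    ", cost = ", format(x$params$cost),
    ", gamma = ", format(x$params$gamma), "\n",
    "  trained on ", x$meta$n_instances, " instances (",
    x$meta$n_positive, " positive)\n",
    "  calibration: ", if (is.null(x$calibration)) "none" else "attached", "\n",
    sep = ""
  )
  invisible(x)
}

# raw decision scores for a 0/1 feature matrix, oriented so that
# higher = more site-like
svm_decision <- function(model, x) {
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv[, 1L])
  # libsvm orients the decision value by the first training label it saw;
  # flip if the column is named "negative/positive"
  if (grepl("^negative", colnames(dv)[[1L]])) s <- -s
  s
}

#' Score Ser/Thr sites with a trained model
#'
#' @param dataset An `og_dataset` (or the result of encoding new proteins with
#'   the model's window configuration via [assemble_dataset()]).
#' @param model An [og_train()] model.
#' @return The dataset tibble with an `svm_score` column appended.
#' @export
og_score <- function(dataset, model) {
  cfg <- og_window(dataset)
  if (!is.null(cfg) && cfg$n != model$window$n) {
    rlang::abort(
      paste0(
        "window mismatch: dataset encoded with n = ", cfg$n,
        " but model expects n = ", model$window$n
      ),
      class = "og_config_error"
    )
  }
  dplyr::mutate(
    tibble::as_tibble(dataset),
    svm_score = svm_decision(model, og_features(dataset))
  )
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly random
#' positive outscores a uniformly random negative, with ties counted 1/2.
#' A perfect ranking gives 1 (100%); random scores give about 0.5.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels: logical, 0/1 numeric, or
#'   `"positive"`/`"negative"` character.
#' @return AUC as a fraction in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
roc_auc <- function(scores, labels) {
  pos <- as_binary_label(labels)
  if (length(scores) != length(pos)) {
    rlang::abort("scores and labels differ in length", class = "og_contract_error")
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    rlang::abort("AUC undefined: both classes must be present",
      class = "og_contract_error"
    )
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) {
    return(labels)
  }
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("positive", "negative")))
    return(labels == "positive")
  }
  rlang::abort("unsupported label type", class = "og_contract_error")
}

# assign proteins (or sites) to cross-validation folds; returns an integer
# fold id per dataset row. Under by_protein grouping all sites of a protein
# share a fold, blocking leakage between homologous windows; folds are
# redrawn (bounded) until every training fold holds both classes.
cv_folds <- function(dataset, folds, grouping, seed, max_redraw = 20L) {
  set.seed(seed)
  for (attempt in seq_len(max_redraw)) {
    if (grouping == "by_protein") {
      ids <- unique(dataset$protein_id)
      if (length(ids) < folds) {
        rlang::abort("fewer proteins than folds under by_protein grouping",
          class = "og_config_error"
        )
      }
      fold_of <- sample(rep_len(seq_len(folds), length(ids)))
      f <- fold_of[match(dataset$protein_id, ids)]
    } else {
      f <- sample(rep_len(seq_len(folds), nrow(dataset)))
    }
    ok <- all(vapply(seq_len(folds), function(k) {
      tr <- dataset$label[f != k]
      any(tr == "positive") && any(tr == "negative")
    }, logical(1)))
    if (ok) {
      return(f)
    }
    if (grouping == "by_site") break
  }
  rlang::abort(
    "could not form folds whose training parts contain both classes",
    class = "og_cv_error"
  )
}

# pooled held-out scores for one (cost, gamma) pair over the given folds
cv_scores <- function(dataset, params, fold, seed) {
  folds <- sort(unique(fold))
  out <- purrr::map(folds, function(k) {
    train <- subset_dataset(dataset, fold != k)
    test <- subset_dataset(dataset, fold == k)
    model <- og_train(train, params, seed = seed)
    tibble::tibble(
      fold = k,
      protein_id = test$protein_id,
      position = test$position,
      label = test$label,
      svm_score = svm_decision(model, og_features(test))
    )
  })
  dplyr::bind_rows(out)
}

#' Cross-validated grid search over SVM hyper-parameters
#'
#' Evaluates every (cost, gamma) pair by k-fold cross-validation — training on
#' four fifths and scoring the held-out fifth under the default `folds = 5` —
#' and selects the pair maximising the pooled held-out AUC. Ties break towards
#' the smaller cost, then the smaller gamma. Folds are drawn once per call
#' (seeded) and shared across the whole grid.
#'
#' @param dataset An `og_dataset`.
#' @param cost_grid,gamma_grid Positive numeric grids. Defaults are the usual
#'   log-spaced RBF search: cost 2^-5..2^5 and gamma 2^-10..2^2 in powers of 4.
#' @param folds Number of folds (default 5).
#' @param grouping `"by_protein"` (default; all sites of a protein share a
#'   fold) or `"by_site"`.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `og_cv` with elements `best_params`, `grid`
#'   (tibble of cost, gamma, pooled and fold-averaged AUC), `held_out`
#'   (pooled held-out scores/labels for the best pair), `fold` assignment,
#'   and `config` metadata.
#' @export
og_grid_cv <- function(dataset,
                       cost_grid = 2^seq(-5, 5, by = 2),
                       gamma_grid = 2^seq(-10, 2, by = 2),
                       folds = 5L,
                       grouping = c("by_protein", "by_site"),
                       seed = 1L) {
  grouping <- rlang::arg_match(grouping)
  if (length(cost_grid) == 0L || length(gamma_grid) == 0L) {
    rlang::abort("parameter grids must be nonempty", class = "og_config_error")
  }
  stopifnot(all(cost_grid > 0), all(gamma_grid > 0), folds >= 2L)
  fold <- cv_folds(dataset, folds, grouping, seed)
  pairs <- tidyr::expand_grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  runs <- purrr::pmap(pairs, function(cost, gamma) {
    held <- cv_scores(dataset, og_params(cost, gamma), fold, seed)
    per_fold <- dplyr::summarise(
      dplyr::group_by(held, .data$fold),
      auc = tryCatch(roc_auc(.data$svm_score, .data$label), error = function(e) NA_real_),
      .groups = "drop"
    )
    list(
      held = held,
      auc_pooled = roc_auc(held$svm_score, held$label),
      auc_fold_mean = mean(per_fold$auc, na.rm = TRUE)
    )
  })
  grid <- dplyr::mutate(
    pairs,
    auc_pooled = purrr::map_dbl(runs, "auc_pooled"),
    auc_fold_mean = purrr::map_dbl(runs, "auc_fold_mean")
  )
  # argmax with deterministic tie-break: smaller cost, then smaller gamma
  ord <- order(-grid$auc_pooled, grid$cost, grid$gamma)
  best_i <- ord[[1L]]
  structure(
    list(
      best_params = og_params(grid$cost[[best_i]], grid$gamma[[best_i]]),
      grid = grid,
      held_out = runs[[best_i]]$held,
      auc = grid$auc_pooled[[best_i]],
      auc_fold_mean = grid$auc_fold_mean[[best_i]],
      fold = fold,
      config = list(
        folds = folds, grouping = grouping, seed = seed,
        n = og_window(dataset)$n
      )
    ),
    class = "og_cv"
  )
}

#' @export
print.og_cv <- function(x, ...) {
  cat(
    "<og_cv> ", x$config$folds, "-fold cross-validation (", x$config$grouping,
    "), ", nrow(x$grid), " (cost, gamma) pairs\n",
    "  best: cost = ", format(x$best_params$cost),
    ", gamma = ", format(x$best_params$gamma),
    ", pooled AUC = ", sprintf("%.3f", x$auc),
    " (fold-mean ", sprintf("%.3f", x$auc_fold_mean), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation grid
#'
#' @param x An `og_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per (cost, gamma) pair and its pooled and
#'   fold-averaged held-out AUC.
#' @export
tidy.og_cv <- function(x, ...) {
  x$grid
}

#' @rdname tidy.og_cv
#' @return `glance()` returns a one-row tibble summarising the selected model.
#' @export
glance.og_cv <- function(x, ...) {
  tibble::tibble(
    cost = x$best_params$cost,
    gamma = x$best_params$gamma,
    auc_pooled = x$auc,
    auc_fold_mean = x$auc_fold_mean,
    folds = x$config$folds,
    grouping = x$config$grouping,
    seed = x$config$seed
  )
}

#' One-row summary of a trained model
#'
#' @param x An `og_model`.
#' @param ... Unused.
#' @export
glance.og_model <- function(x, ...) {
  tibble::tibble(
    n = x$window$n,
    cost = x$params$cost,
    gamma = x$params$gamma,
    n_instances = x$meta$n_instances,
    n_positive = x$meta$n_positive,
    n_negative = x$meta$n_negative,
    calibrated = !is.null(x$calibration),
    seed = x$meta$seed
  )
}

#' Save or load a trained model archive
#'
#' The archive is a single self-describing file holding the fitted decision
#' data, the window configuration, the alphabet order, any calibration table,
#' the seed and the package version. Loading restores a model that produces
#' identical scores.
#'
#' @param model An `og_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "og_model")) {
    rlang::abort("file does not contain a model archive", class = "og_io_error")
  }
  model
}
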