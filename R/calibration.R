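#' Calibrate decision scores into estimated-precision lower bounds
#'
#' Converts pooled held-out cross-validation scores into a score-bin table.
#' Scores are cut into equal-frequency bins; each bin's estimated precision is
#' a one-sided lower binomial (Clopper-Pearson) confidence limit on its
#' held-out positive fraction, so a reported value of 0.391 reads "at least
#' 39.1% of sites with similar classifier scores are true sites" at the
#' configured confidence. Monotonicity in score is enforced by pooling
#' adjacent violating bins (merging their counts and recomputing the limit)
#' from low to high scores, and empty bins are merged with a neighbour.
#'
#' @param cv An [og_grid_cv()] result, or any data frame with columns
#'   `svm_score` and `label`.
#' @param bins Number of equal-frequency score bins (default 20).
#' @param confidence One-sided confidence level of the lower bound
#'   (default 0.95).
#' @param baseline_rate Corpus positive base rate used for lift
#'   (default 0.0123, the observed fraction of annotated O-GlcNAc sites among
#'   all Ser/Thr sites in the motivating corpus).
#' @return An `og_calibration` tibble with one row per bin: score range,
#'   counts, raw precision and `lower_bound`.
#' @export
build_calibration <- function(cv, bins = 20L, confidence = 0.95,
                              baseline_rate = 0.0123) {
  held <- if (inherits(cv, "og_cv")) cv$held_out else cv
  stopifnot(all(c("svm_score", "label") %in% names(held)))
  pos <- as_binary_label(held$label)
  if (!any(pos)) {
    rlang::abort("calibration requires held-out positives",
      class = "og_calibration_error"
    )
  }
  stopifnot(confidence > 0, confidence < 1, baseline_rate > 0)
  scores <- held$svm_score
  breaks <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1L)))
  bin <- cut(scores, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  tab <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, score = scores, pos = pos), .data$bin),
    score_lo = min(.data$score),
    score_hi = max(.data$score),
    n = dplyr::n(),
    positives = sum(.data$pos),
    .groups = "drop"
  ), .data$score_lo)
  tab <- tab[tab$n > 0L, ]
  # pool adjacent violators on the lower bound, merging counts
  lo <- tab$score_lo
  hi <- tab$score_hi
  n <- tab$n
  x <- tab$positives
  repeat {
    lb <- binom_lower(x, n, confidence)
    v <- which(diff(lb) < 0)
    if (length(v) == 0L) break
    i <- v[[1L]]
    n[i] <- n[i] + n[i + 1L]
    x[i] <- x[i] + x[i + 1L]
    hi[i] <- hi[i + 1L]
    n <- n[-(i + 1L)]
    x <- x[-(i + 1L)]
    lo <- lo[-(i + 1L)]
    hi <- hi[-(i + 1L)]
  }
  out <- tibble::tibble(
    bin = seq_along(n),
    score_lo = lo,
    score_hi = hi,
    n = n,
    positives = x,
    precision = x / n,
    lower_bound = binom_lower(x, n, confidence)
  )
  structure(
    tibble::new_tibble(out, class = "og_calibration"),
    confidence = confidence,
    baseline_rate = baseline_rate
  )
}

# one-sided lower Clopper-Pearson limit for x successes of n
binom_lower <- function(x, n, confidence) {
  ifelse(x == 0, 0, stats::qbeta(1 - confidence, x, n - x + 1))
}

#' Look up the estimated precision for raw scores
#'
#' Maps each score to its calibration bin (scores beyond the observed range
#' clamp to the outermost bins) and returns that bin's lower-bound precision.
#'
#' @param calibration An [build_calibration()] table.
#' @param scores Numeric scores.
#' @return Numeric vector of estimated precisions.
#' @export
estimate_precision <- function(calibration, scores) {
  # bins partition the score axis at their lower edges; findInterval clamps
  edges <- calibration$score_lo
  i <- pmax(findInterval(scores, edges), 1L)
  calibration$lower_bound[i]
}

#' Lift over the corpus base rate
#'
#' The relative improvement of the classifier over random selection:
#' estimated precision divided by the corpus positive base rate (~0.0123).
#' An estimated precision of 0.1722 is a lift of 14.
#'
#' @param estimated_precision Estimated precision value(s).
#' @param baseline_rate Positive base rate (> 0).
#' @return `estimated_precision / baseline_rate`.
#' @export
#' @examples
#' lift(0.3910, 0.0123)
lift <- function(estimated_precision, baseline_rate = 0.0123) {
  if (!is.numeric(baseline_rate) || length(baseline_rate) != 1L ||
    is.na(baseline_rate) || baseline_rate <= 0) {
    rlang::abort("baseline_rate must be a single positive number",
      class = "og_config_error"
    )
  }
  estimated_precision / baseline_rate
}

#' Attach a calibration table to a model
#'
#' @param model An `og_model`.
#' @param calibration An `og_calibration` table built with the same window
#'   configuration.
#' @return The model with the calibration attached.
#' @export
og_calibrate <- function(model, calibration) {
  stopifnot(inherits(model, "og_model"), inherits(calibration, "og_calibration"))
  model$calibration <- calibration
  model
}

#' Ranked site prediction report
#'
#' Scores every Ser/Thr site of the given proteins, converts scores to
#' estimated precision and lift through the model's calibration table, and
#' returns the sites whose estimated precision reaches `threshold`, ordered by
#' descending SVM score (ties by ascending position). The default threshold
#' keeps sites whose estimated precision is at least the base rate, i.e.
#' lift >= 1; it can be raised or lowered to shrink or grow the report.
#' Proteins named in `secreted` get `flagged = TRUE` as a caution that a
#' sequence with a secreted form may be predicted spuriously, since the
#' classifier sees only sequence context.
#'
#' @param proteins Protein tibble.
#' @param model A calibrated `og_model` (see [og_calibrate()]), or pass
#'   `calibration` explicitly.
#' @param calibration Optional `og_calibration` overriding the model's.
#' @param threshold Minimum estimated precision to report (default: the
#'   calibration's baseline rate).
#' @param secreted Character vector of protein ids known to have secreted
#'   forms.
#' @return Tibble with columns `protein_id`, `position`, `residue`,
#'   `svm_score`, `estimated_precision`, `lift`, `flagged`.
#' @export
rank_report <- function(proteins, model, calibration = NULL,
                        threshold = NULL, secreted = character()) {
  calibration <- calibration %||% model$calibration
  if (is.null(calibration)) {
    rlang::abort("model carries no calibration table; run og_calibrate() first",
      class = "og_config_error"
    )
  }
  baseline <- attr(calibration, "baseline_rate", exact = TRUE)
  threshold <- threshold %||% baseline
  sites <- extract_candidate_sites(proteins)
  if (nrow(sites) == 0L) {
    return(tibble::tibble(
      protein_id = character(), position = integer(), residue = character(),
      svm_score = numeric(), estimated_precision = numeric(),
      lift = numeric(), flagged = logical()
    ))
  }
  x <- encode_matrix(proteins, sites, model$window)
  scored <- dplyr::mutate(
    sites,
    svm_score = svm_decision(model, x),
    estimated_precision = estimate_precision(calibration, .data$svm_score),
    lift = lift(.data$estimated_precision, baseline),
    flagged = .data$protein_id %in% secreted,
    label = NULL
  )
  dplyr::arrange(
    dplyr::filter(scored, .data$estimated_precision >= threshold),
    dplyr::desc(.data$svm_score), .data$position
  )
}

#' Write a prediction report as TSV
#'
#' @param report A [rank_report()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}

#' Plot a calibration table
#'
#' Bar plot of the estimated-precision lower bound per score bin, with the
#' raw held-out precision overlaid and the base rate as a dashed line.
#'
#' @param object An `og_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.og_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$score_lo + df$score_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$precision),
      fill = "grey80", width = (max(df$score_hi) - min(df$score_lo)) / nrow(df) * 0.9
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$lower_bound), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower_bound), colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = attr(object, "baseline_rate", exact = TRUE),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "SVM decision score (bin midpoint)",
      y = "held-out precision",
      title = "Score calibration",
      subtitle = "bars: raw bin precision; points: lower confidence bound; dashed: base rate"
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of pooled held-out cross-validation scores
#'
#' @param object An `og_cv` result.
#' @param ... Unused.
#' @return A ggplot object showing the ROC curve and the chance diagonal.
#' @export
autoplot.og_cv <- function(object, ...) {
  held <- object$held_out
  pos <- as_binary_label(held$label)
  ord <- order(held$svm_score, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  ggplot2::ggplot(tibble::tibble(fpr = fpr, tpr = tpr), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Cross-validated ROC (pooled AUC = %.1f%%)", 100 * object$auc)
    ) +
    ggplot2::theme_minimal()
}
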