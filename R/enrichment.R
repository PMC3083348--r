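#' Two-sample position-specific residue enrichment
#'
#' Compares residue usage around positive (modified) and negative Ser/Thr
#' windows in the style of a two-sample logo: for each flank position relative
#' to the site (position 0) and each amino acid, the difference between the
#' positive-set and negative-set frequencies, with a two-proportion z-test per
#' (position, residue) cell. End-of-sequence padding symbols are excluded from
#' the denominators, so frequencies at each position are taken over real
#' residues only. Position 0 (the Ser/Thr itself) is reported descriptively
#' but excluded from significance testing. No multiple-testing correction is
#' applied by default; `correction = "bonferroni"` divides alpha by the
#' number of tested cells.
#'
#' @param pos_windows,neg_windows Character matrices of windows (one row per
#'   window, `2n + 1` columns), e.g. built by [site_windows()].
#' @param alpha Significance level (default 0.05); `alpha = 0` flags nothing.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return An `og_enrichment` tibble with columns `position` (`-n..n`),
#'   `residue`, `freq_pos`, `freq_neg`, `difference`, `p_value`,
#'   `significant`.
#' @export
two_sample_enrichment <- function(pos_windows, neg_windows, alpha = 0.05,
                                  correction = c("none", "bonferroni")) {
  correction <- rlang::arg_match(correction)
  if (!is.matrix(pos_windows)) pos_windows <- do.call(rbind, pos_windows)
  if (!is.matrix(neg_windows)) neg_windows <- do.call(rbind, neg_windows)
  if (ncol(pos_windows) != ncol(neg_windows)) {
    rlang::abort("window lengths differ between the two samples",
      class = "og_contract_error"
    )
  }
  if (nrow(pos_windows) == 0L || nrow(neg_windows) == 0L) {
    rlang::abort("both window sets must be nonempty", class = "og_contract_error")
  }
  w <- ncol(pos_windows)
  if (w %% 2L != 1L) {
    rlang::abort("window length must be odd (2n + 1)", class = "og_contract_error")
  }
  n <- (w - 1L) %/% 2L
  rel <- -n:n
  aa <- og_aa()
  cells <- purrr::map(seq_len(w), function(j) {
    p_sym <- pos_windows[, j]
    n_sym <- neg_windows[, j]
    p_sym <- p_sym[p_sym %in% aa]
    n_sym <- n_sym[n_sym %in% aa]
    n1 <- length(p_sym)
    n2 <- length(n_sym)
    x1 <- tabulate(match(p_sym, aa), nbins = 20L)
    x2 <- tabulate(match(n_sym, aa), nbins = 20L)
    f1 <- if (n1 > 0) x1 / n1 else rep(0, 20L)
    f2 <- if (n2 > 0) x2 / n2 else rep(0, 20L)
    tibble::tibble(
      position = rel[[j]],
      residue = aa,
      freq_pos = f1,
      freq_neg = f2,
      difference = f1 - f2,
      p_value = two_prop_p(x1, n1, x2, n2)
    )
  })
  out <- dplyr::bind_rows(cells)
  out$p_value[out$position == 0L] <- NA_real_
  n_tests <- sum(out$position != 0L)
  alpha_eff <- if (correction == "bonferroni") alpha / n_tests else alpha
  out$significant <- !is.na(out$p_value) & alpha > 0 & out$p_value <= alpha_eff
  structure(
    tibble::new_tibble(out, class = "og_enrichment"),
    alpha = alpha, correction = correction, n = n
  )
}

# vectorised two-proportion z-test (pooled variance, two-sided)
two_prop_p <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) {
    return(rep(NA_real_, length(x1)))
  }
  phat <- (x1 + x2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- 1 # pooled frequency 0 or 1: no evidence either way
  p
}

#' Build site windows for enrichment analysis
#'
#' Extracts the `2n + 1` windows around the given annotated sites and around
#' all remaining (unannotated) Ser/Thr sites of the same proteins.
#'
#' @param proteins Protein tibble.
#' @param annotations O-GlcNAc site annotations defining the positive set.
#' @param config A [window_config()].
#' @return List with character matrices `positive` and `negative`.
#' @export
site_windows <- function(proteins, annotations, config = window_config()) {
  dataset <- assemble_dataset(proteins, annotations, config)
  sites <- tibble::as_tibble(dataset)
  parts <- purrr::map(
    split(seq_len(nrow(sites)), sites$protein_id),
    function(i) {
      seq <- proteins$sequence[match(sites$protein_id[i[[1]]], proteins$id)]
      list(win = windows_at(seq, sites$position[i], config$n), label = sites$label[i])
    }
  )
  win <- do.call(rbind, purrr::map(parts, "win"))
  label <- unlist(purrr::map(parts, "label"), use.names = FALSE)
  list(
    positive = win[label == "positive", , drop = FALSE],
    negative = win[label == "negative", , drop = FALSE]
  )
}

#' Position enrichment around annotated sites
#'
#' Convenience wrapper: windows are built with [site_windows()] and compared
#' with [two_sample_enrichment()].
#'
#' @inheritParams site_windows
#' @inheritParams two_sample_enrichment
#' @return An `og_enrichment` tibble.
#' @export
motif_enrichment <- function(proteins, annotations, config = window_config(),
                             alpha = 0.05, correction = c("none", "bonferroni")) {
  w <- site_windows(proteins, annotations, config)
  two_sample_enrichment(w$positive, w$negative,
    alpha = alpha,
    correction = rlang::arg_match(correction)
  )
}

#' Logo-style plot of position enrichment
#'
#' Letters above the axis are enriched in the positive windows, letters below
#' are depleted; only significant cells are drawn, scaled by the frequency
#' difference.
#'
#' @param object An `og_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.og_enrichment <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$difference, label = .data$residue
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(
      size = abs(.data$difference),
      colour = .data$difference > 0
    ), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "steelblue")) +
    ggplot2::scale_x_continuous(breaks = function(l) seq(ceiling(l[1]), floor(l[2]))) +
    ggplot2::labs(
      x = "position relative to the modified Ser/Thr",
      y = "frequency difference (positive - negative)",
      title = "Two-sample position enrichment"
    ) +
    ggplot2::theme_minimal()
}
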