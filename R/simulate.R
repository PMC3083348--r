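#' Background residue frequency presets
#'
#' `"uniform"` gives each of the 20 amino acids probability 0.05.
#' `"swissprot"` is a Swiss-Prot-like composition (the familiar averages:
#' Leu ~9.7%, Ala ~8.3%, Trp ~1.1%, ...), useful when a more protein-like
#' Ser/Thr density is wanted.
#'
#' @param preset `"uniform"` or `"swissprot"`, or a named numeric vector of
#'   20 frequencies which is normalised and returned.
#' @return Named numeric vector over [og_aa()] summing to 1.
#' @export
background_frequencies <- function(preset = c("uniform", "swissprot")) {
  if (is.numeric(preset)) {
    stopifnot(length(preset) == 20L, all(preset >= 0), sum(preset) > 0)
    if (!is.null(names(preset))) preset <- preset[og_aa()]
    return(rlang::set_names(as.numeric(preset) / sum(preset), og_aa()))
  }
  preset <- rlang::arg_match(preset)
  if (preset == "uniform") {
    return(rlang::set_names(rep(0.05, 20L), og_aa()))
  }
  f <- c(
    A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
    G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
    P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
  )
  f / sum(f)
}

#' Default flank motif of the synthetic generator
#'
#' Residue biases at flank positions relative to the modified Ser/Thr,
#' mirroring the qualitative enrichment seen around real O-GlcNAc sites
#' (Pro at -3/-2, Val at -1, Thr at +1, Ala at +2 — a "PPV(S/T)TA"-like
#' pattern). `strength` is the probability that the biased residue is placed
#' at its position in a positive window; with the remaining probability the
#' background is kept. `strength = 0` removes the signal entirely (a null
#' corpus).
#'
#' @param strength Per-position bias probability in `[0, 1]` (default 0.6).
#' @return Tibble with columns `position`, `residue`, `prob`.
#' @export
default_motif <- function(strength = 0.6) {
  stopifnot(strength >= 0, strength <= 1)
  tibble::tibble(
    position = c(-3L, -2L, -1L, 1L, 2L),
    residue = c("P", "P", "V", "T", "A"),
    prob = strength
  )
}

#' Simulation configuration
#'
#' Defaults emulate the shape of the motivating corpus: a few hundred
#' sequences long enough to carry roughly 30,000 Ser/Thr sites in total, of
#' which about 1.23% are positives, with position-specific residue biases in
#' the positive flanks.
#'
#' @param n_proteins Number of sequences (default 300).
#' @param length_meanlog,length_sdlog Log-normal sequence-length parameters
#'   (defaults `log(1000)` and 0.3; lengths are capped below at `2n + 1`).
#' @param background Background preset or 20 frequencies
#'   (see [background_frequencies()]).
#' @param motif Flank bias tibble as in [default_motif()].
#' @param positive_rate Per-site probability that a Ser/Thr is a positive
#'   (default 0.0123).
#' @param n Window half-width the motif refers to (default 5).
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @return An `og_sim_config` list.
#' @export
sim_config <- function(n_proteins = 300L,
                       length_meanlog = log(1000),
                       length_sdlog = 0.3,
                       background = "uniform",
                       motif = default_motif(),
                       positive_rate = 0.0123,
                       n = 5L,
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, positive_rate > 0, positive_rate < 1)
  freqs <- background_frequencies(background)
  if (nrow(motif) > 0) {
    stopifnot(
      all(motif$residue %in% og_aa()),
      all(motif$prob >= 0), all(motif$prob <= 1),
      all(motif$position != 0L)
    )
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      length_meanlog = length_meanlog,
      length_sdlog = length_sdlog,
      background = freqs,
      motif = motif,
      positive_rate = positive_rate,
      n = as.integer(n),
      seed = as.integer(seed)
    ),
    class = "og_sim_config"
  )
}

#' Generate a synthetic proteome with planted O-GlcNAc sites
#'
#' Sequences are drawn i.i.d. from the background frequencies; each Ser/Thr
#' is then independently selected as a positive with probability
#' `positive_rate`, and the flanks of every positive are resampled from the
#' motif model (biased residues planted with their configured probability).
#' Flank positions that are themselves selected positive centres are never
#' overwritten, so every annotated site keeps its Ser/Thr. Resampling can
#' create or destroy other Ser/Thr occurrences; those simply join or leave
#' the negative pool, as in real sequence context.
#'
#' @param config An [sim_config()].
#' @return List with `proteins` (tibble), `annotations` (site-table tibble for
#'   the positives) and `truth` (planted parameters and realised counts).
#' @export
#' @examples
#' sim <- generate_corpus(sim_config(n_proteins = 5, seed = 42))
#' sim$truth$n_sites
generate_corpus <- function(config = sim_config()) {
  set.seed(config$seed)
  aa <- og_aa()
  lens <- pmax(
    2L * config$n + 1L,
    as.integer(round(stats::rlnorm(
      config$n_proteins, config$length_meanlog, config$length_sdlog
    )))
  )
  ids <- sprintf("SYN%04d", seq_len(config$n_proteins))
  chars <- purrr::map(lens, function(L) {
    sample(aa, L, replace = TRUE, prob = config$background)
  })

  annotations <- vector("list", config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    ch <- chars[[i]]
    st <- which(ch %in% c("S", "T"))
    if (length(st) == 0L) next
    is_pos <- stats::runif(length(st)) < config$positive_rate
    pos <- st[is_pos]
    if (length(pos) > 0L && nrow(config$motif) > 0L) {
      for (p in pos) {
        for (j in seq_len(nrow(config$motif))) {
          at <- p + config$motif$position[[j]]
          if (at < 1L || at > length(ch) || at %in% pos) next
          if (stats::runif(1) < config$motif$prob[[j]]) {
            ch[at] <- config$motif$residue[[j]]
          }
        }
      }
      chars[[i]] <- ch
    }
    if (length(pos) > 0L) {
      annotations[[i]] <- tibble::tibble(
        protein_id = ids[[i]],
        position = pos,
        residue = ch[pos],
        ptm_type = "OGlcNAc",
        evidence = "",
        pmids = "",
        source = "experimental"
      )
    }
  }
  proteins <- tibble::tibble(
    id = ids,
    description = "synthetic protein",
    sequence = vapply(chars, paste, character(1), collapse = "")
  )
  annotations <- dplyr::bind_rows(annotations)
  if (nrow(annotations) == 0L) {
    rlang::abort("no positive sites drawn; increase corpus size or rate",
      class = "og_sim_error"
    )
  }
  n_sites <- sum(vapply(
    strsplit(proteins$sequence, ""),
    function(ch) sum(ch %in% c("S", "T")), integer(1)
  ))
  if (n_sites == nrow(annotations)) {
    rlang::abort("positive rate too high: no negative sites remain",
      class = "og_sim_error"
    )
  }
  list(
    proteins = proteins,
    annotations = annotations,
    truth = list(
      config = config,
      n_sites = n_sites,
      n_positive = nrow(annotations),
      realized_rate = nrow(annotations) / n_sites
    )
  )
}

#' Generate a crosstalk fixture with known ground truth
#'
#' Builds random per-protein O-GlcNAc/phospho site sets with exact planted
#' counts: `n_identical` phospho-sites placed on O-GlcNAc positions,
#' `n_adjacent` placed 1..`k` residues away from an O-GlcNAc position, and
#' `n_background` phospho-sites placed farther than `k` from every O-GlcNAc
#' site. Planted relations are spread over the proteins round-robin and
#' spaced widely so the planted relation is the only one each site has.
#'
#' @param n_proteins Number of proteins (default 10).
#' @param n_identical,n_adjacent,n_background Planted counts.
#' @param k Adjacency half-window (default 4).
#' @param seed Integer seed.
#' @return List with `sites` (long tibble: `protein_id`, `position`,
#'   `residue`, `ptm_type`) and `truth` (planted counts).
#' @export
generate_crosstalk_fixture <- function(n_proteins = 10L, n_identical = 5L,
                                       n_adjacent = 7L, n_background = 20L,
                                       k = 4L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_proteins >= 1L, k >= 0L)
  ids <- sprintf("XTK%03d", seq_len(n_proteins))
  # anchors spaced > 4k apart so relations cannot interact
  spacing <- 10L * max(k, 1L) + 20L
  slot <- function(i) (i - 1L) %/% n_proteins + 1L
  rows <- list()
  add <- function(pid, position, ptm, residue = sample(c("S", "T"), 1L)) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      protein_id = pid,
      position = as.integer(position),
      residue = residue,
      ptm_type = ptm
    )
  }
  for (i in seq_len(n_identical)) {
    pid <- ids[[(i - 1L) %% n_proteins + 1L]]
    anchor <- slot(i) * spacing + sample.int(10L, 1L)
    res <- sample(c("S", "T"), 1L)
    add(pid, anchor, "OGlcNAc", res)
    add(pid, anchor, "Phospho", res)
  }
  for (i in seq_len(n_adjacent)) {
    pid <- ids[[(i - 1L) %% n_proteins + 1L]]
    anchor <- (slot(i) + n_identical + 2L) * spacing + sample.int(10L, 1L)
    d <- if (k > 0L) sample.int(k, 1L) else 1L
    add(pid, anchor, "OGlcNAc")
    add(pid, anchor + d * sample(c(-1L, 1L), 1L), "Phospho")
  }
  for (i in seq_len(n_background)) {
    pid <- ids[[(i - 1L) %% n_proteins + 1L]]
    anchor <- (slot(i) + n_identical + n_adjacent + 10L) * spacing +
      sample.int(10L, 1L)
    add(pid, anchor, "Phospho")
  }
  sites <- dplyr::bind_rows(rows)
  list(
    sites = sites,
    truth = list(
      n_identical = n_identical, n_adjacent = n_adjacent,
      n_background = n_background, k = k, seed = seed
    )
  )
}
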