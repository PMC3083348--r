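#' Window configuration for site encoding
#'
#' A candidate Ser/Thr site is represented by its sequence context: `n`
#' residues upstream and `n` downstream of the site, giving a window of
#' `2n + 1` symbols. Positions that fall beyond a sequence terminal are
#' filled with the end-of-sequence symbol so every window has the same
#' length. One-hot encoding over the 21-symbol alphabet then yields a
#' binary feature vector of length `21 * (2n + 1)`.
#'
#' @param n Half-width of the window (default 5, the value found to give the
#'   best cross-validated prediction performance).
#' @return An object of class `og_window_config`.
#' @export
#' @examples
#' window_config(5)
window_config <- function(n = 5L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > 25L) {
    rlang::abort("window half-width n must be a single integer in 1..25",
      class = "og_config_error"
    )
  }
  structure(list(n = n), class = "og_window_config")
}

#' @export
print.og_window_config <- function(x, ...) {
  cat(
    "<og_window_config> n =", x$n, "| window length", 2L * x$n + 1L,
    "| feature length", 21L * (2L * x$n + 1L), "\n"
  )
  invisible(x)
}

#' Enumerate candidate Ser/Thr sites
#'
#' Lists every serine and threonine in each protein as an unlabeled candidate
#' site, in ascending position order within each protein.
#'
#' @param proteins Protein tibble (columns `id`, `sequence`).
#' @return Tibble with columns `protein_id`, `position`, `residue`, `label`.
#' @export
extract_candidate_sites <- function(proteins) {
  res <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    ch <- strsplit(seq, "")[[1]]
    pos <- which(ch %in% c("S", "T"))
    tibble::tibble(
      protein_id = rep(id, length(pos)),
      position = pos,
      residue = ch[pos]
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      protein_id = character(), position = integer(), residue = character()
    )
  }
  dplyr::mutate(out, label = "unlabeled")
}

# windows for several positions of one sequence; rows = sites, 2n+1 columns
windows_at <- function(sequence, positions, n) {
  len <- nchar(sequence)
  stopifnot(all(positions >= 1L), all(positions <= len))
  padded <- c(
    rep(og_eos(), n), strsplit(sequence, "")[[1]], rep(og_eos(), n)
  )
  offs <- -n:n
  idx <- outer(positions + n, offs, `+`) # positions are shifted by the pad
  matrix(padded[idx], nrow = length(positions), ncol = 2L * n + 1L)
}

#' Extract the sequence window around a site
#'
#' Returns the `2n + 1` symbols centred on `position`; overhangs past either
#' terminal are padded with the end-of-sequence symbol (`og_eos()`).
#'
#' @param protein A one-row protein tibble (or any row with a `sequence`).
#' @param position 1-based residue position; must hold Ser or Thr.
#' @param config A [window_config()].
#' @return Character vector of length `2n + 1`.
#' @export
#' @examples
#' p <- tibble::tibble(id = "p", description = "", sequence = "MASTG")
#' extract_window(p, 4, window_config(2))
extract_window <- function(protein, position, config = window_config()) {
  stopifnot(nrow(protein) == 1L)
  seq <- protein$sequence
  position <- as.integer(position)
  if (position < 1L || position > nchar(seq)) {
    rlang::abort("position outside sequence", class = "og_contract_error")
  }
  centre <- substr(seq, position, position)
  if (!centre %in% c("S", "T")) {
    rlang::abort(
      paste0("window centre must be Ser/Thr, got '", centre, "'"),
      class = "og_contract_error"
    )
  }
  windows_at(seq, position, config$n)[1L, ]
}

#' One-hot encode a sequence window
#'
#' Each window symbol is coded as a block of 21 binary values over
#' [og_alphabet()]: `1 0 ... 0` for Ala, `0 1 0 ... 0` for Arg, through
#' `0 ... 0 1` for the end-of-sequence symbol. The full vector has length
#' `21 * (2n + 1)` and carries exactly `2n + 1` ones. The symbol `X`
#' (permissive reading of ambiguity codes) is encoded as an all-zero block,
#' keeping the vector length unchanged.
#'
#' @param window Character vector of `2n + 1` symbols.
#' @param config A [window_config()].
#' @return Integer vector of 0/1 of length `21 * (2n + 1)`.
#' @export
#' @examples
#' sparse_encode(c("-", "A", "S", "T", "G"), window_config(2))
sparse_encode <- function(window, config = window_config()) {
  if (length(window) != 2L * config$n + 1L) {
    rlang::abort("window length does not match the configuration",
      class = "og_contract_error"
    )
  }
  rank <- match(window, og_alphabet())
  unknown <- is.na(rank) & window != "X"
  if (any(unknown)) {
    rlang::abort(
      paste0(
        "symbol(s) outside the 21-symbol alphabet: ",
        paste(unique(window[unknown]), collapse = ", ")
      ),
      class = "og_encoding_error"
    )
  }
  v <- integer(21L * length(window))
  hit <- !is.na(rank)
  v[(which(hit) - 1L) * 21L + rank[hit]] <- 1L
  v
}

#' Decode a one-hot feature vector back to window symbols
#'
#' Inverts [sparse_encode()] by taking the position of the 1 within each
#' 21-slot block; an all-zero block decodes to `X`.
#'
#' @param features 0/1 vector of length `21 * (2n + 1)`.
#' @param config A [window_config()].
#' @return Character vector of `2n + 1` symbols.
#' @export
decode_window <- function(features, config = window_config()) {
  w <- 2L * config$n + 1L
  if (length(features) != 21L * w) {
    rlang::abort("feature length does not match the configuration",
      class = "og_contract_error"
    )
  }
  m <- matrix(features, nrow = 21L, ncol = w)
  apply(m, 2L, function(block) {
    if (sum(block) == 0L) "X" else og_alphabet()[which.max(block)]
  })
}

# encode many sites at once: returns nsites x 21(2n+1) 0/1 matrix
encode_matrix <- function(proteins, sites, config) {
  n <- config$n
  width <- 2L * n + 1L
  alpha <- og_alphabet()
  blocks <- purrr::map(split(seq_len(nrow(sites)), sites$protein_id), function(i) {
    pid <- sites$protein_id[i[[1]]]
    seq <- proteins$sequence[match(pid, proteins$id)]
    win <- windows_at(seq, sites$position[i], n)
    rank <- match(win, alpha) # NA for X -> all-zero block
    x <- matrix(0L, nrow = length(i), ncol = 21L * width)
    row <- rep(seq_along(i), times = width)
    col <- (rep(seq_len(width), each = length(i)) - 1L) * 21L + as.vector(rank)
    keep <- !is.na(col)
    x[cbind(row[keep], col[keep])] <- 1L
    x
  })
  x <- do.call(rbind, blocks)
  # restore the original row order (split() groups by protein)
  x[order(unlist(split(seq_len(nrow(sites)), sites$protein_id))), , drop = FALSE]
}

#' Export encoded instances as a dense text matrix
#'
#' Writes one row per instance: `protein_id`, `position`, `label`, then the
#' `21 * (2n + 1)` binary features, comma-separated.
#'
#' @param dataset An [assemble_dataset()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_instances <- function(dataset, path) {
  x <- og_features(dataset)
  header <- paste(
    c("protein_id", "position", "label", paste0("f", seq_len(ncol(x)))),
    collapse = ","
  )
  rows <- paste(
    dataset$protein_id, dataset$position, dataset$label,
    apply(x, 1L, paste, collapse = ","),
    sep = ","
  )
  writeLines(c(header, rows), path)
  invisible(path)
}
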