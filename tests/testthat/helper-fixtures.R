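# shared builders and independent oracles for the test suite

protein <- function(id, sequence, description = "") {
  tibble::tibble(id = id, description = description, sequence = sequence)
}

annotation <- function(protein_id, position, residue,
                       ptm_type = "OGlcNAc", evidence = "", pmids = "",
                       source = "experimental") {
  tibble::tibble(
    protein_id = protein_id, position = as.integer(position),
    residue = residue, ptm_type = ptm_type, evidence = evidence,
    pmids = pmids, source = source
  )
}

random_sequence <- function(len, include_st = TRUE) {
  pool <- if (include_st) og_alphabet()[1:20] else setdiff(og_alphabet()[1:20], c("S", "T"))
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# brute-force AUC: enumerate every positive-negative pair, ties count 1/2
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# independent Needleman-Wunsch score, linear gap penalty
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n)
  f[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      f[i + 1, j + 1] <- max(f[i, j] + s, f[i, j + 1] + gap, f[i + 1, j] + gap)
    }
  }
  f[n + 1, m + 1]
}

# brute-force adjacent Yin-Yang positions: double loop over (p, g) pairs
adjacent_oracle <- function(g, p, k) {
  hits <- integer()
  for (q in p) {
    for (gg in g) {
      if (abs(q - gg) >= 1 && abs(q - gg) <= k) hits <- c(hits, q)
    }
  }
  sort(unique(hits))
}

# small corpus for model tests; cached per session to keep the suite fast
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(sim_config(
        n_proteins = 30, length_meanlog = log(400), length_sdlog = 0.2,
        positive_rate = 0.05, seed = 101
      ))
    }
    cache
  }
})
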