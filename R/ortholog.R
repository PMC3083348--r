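#' Alignment scoring parameters
#'
#' Two schemes are provided. `"blosum62"` (default) is a global,
#' end-gap-penalised alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1) — appropriate for ortholog pairs, which are near-full-length
#' homologs. `"simple"` is linear-gap match/mismatch scoring, mainly useful
#' for small constructed cases and cross-checking against textbook dynamic
#' programming.
#'
#' @param method `"blosum62"` or `"simple"`.
#' @param match,mismatch Scores for the simple scheme.
#' @param gap Per-residue gap penalty (negative) for the simple scheme.
#' @param gap_open,gap_extend Affine gap penalties (positive costs) for the
#'   BLOSUM62 scheme.
#' @return An `og_align_scoring` list.
#' @export
align_scoring <- function(method = c("blosum62", "simple"),
                          match = 1, mismatch = -1, gap = -2,
                          gap_open = 11, gap_extend = 1) {
  method <- rlang::arg_match(method)
  structure(
    list(
      method = method, match = match, mismatch = mismatch, gap = gap,
      gap_open = gap_open, gap_extend = gap_extend
    ),
    class = "og_align_scoring"
  )
}

#' Global pairwise alignment of two protein records
#'
#' Needleman-Wunsch global alignment computed with Biostrings. The result is
#' a column table pairing source and target positions; gap columns carry `NA`
#' on the gapped side.
#'
#' @param a,b One-row protein tibbles (source and target).
#' @param scoring An [align_scoring()] configuration.
#' @return An `og_alignment`: tibble with columns `column`, `source_pos`,
#'   `source_sym`, `target_pos`, `target_sym`; attributes `score`,
#'   `source_id`, `target_id`.
#' @export
#' @examples
#' a <- tibble::tibble(id = "a", description = "", sequence = "ACGSTA")
#' b <- tibble::tibble(id = "b", description = "", sequence = "ACGTA")
#' align_global(a, b, align_scoring("simple"))
align_global <- function(a, b, scoring = align_scoring()) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (!nzchar(a$sequence) || !nzchar(b$sequence)) {
    rlang::abort("sequences must be non-empty", class = "og_contract_error")
  }
  if (scoring$method == "blosum62") {
    sub <- get_blosum62()
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
      substitutionMatrix = sub,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global"
    )
  } else {
    letters_all <- unique(c(
      og_aa(), "X",
      strsplit(a$sequence, "")[[1]], strsplit(b$sequence, "")[[1]]
    ))
    sub <- matrix(scoring$mismatch,
      nrow = length(letters_all), ncol = length(letters_all),
      dimnames = list(letters_all, letters_all)
    )
    diag(sub) <- scoring$match
    aln <- Biostrings::pairwiseAlignment(
      a$sequence, b$sequence,
      substitutionMatrix = sub,
      gapOpening = 0, gapExtension = -scoring$gap,
      type = "global"
    )
  }
  src <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  tgt <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  source_pos <- ifelse(src == "-", NA_integer_, cumsum(src != "-"))
  target_pos <- ifelse(tgt == "-", NA_integer_, cumsum(tgt != "-"))
  out <- tibble::tibble(
    column = seq_along(src),
    source_pos = as.integer(source_pos),
    source_sym = ifelse(src == "-", NA_character_, src),
    target_pos = as.integer(target_pos),
    target_sym = ifelse(tgt == "-", NA_character_, tgt)
  )
  structure(
    tibble::new_tibble(out, class = "og_alignment"),
    score = Biostrings::score(aln),
    source_id = a$id,
    target_id = b$id
  )
}

# BLOSUM62 without triggering a data() load into the caller's environment
get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Alignment score accessor
#'
#' @param alignment An `og_alignment`.
#' @return The numeric alignment score.
#' @export
alignment_score <- function(alignment) {
  attr(alignment, "score", exact = TRUE)
}

#' Transfer known O-GlcNAc sites onto an ortholog
#'
#' Maps each experimentally known site of the source protein through the
#' alignment. A site transfers iff its column pairs it with a non-gap target
#' position whose residue is Ser or Thr ("conserved Ser/Thr"): S aligned to T
#' still transfers, with `conserved_identity = FALSE` recording that the
#' letter differed. Sites falling on gap columns or on non-S/T target
#' residues are dropped and counted in the `skipped` attribute.
#'
#' @param alignment An [align_global()] result whose source is the annotated
#'   protein.
#' @param source_sites Site annotation tibble for the source protein
#'   (experimental O-GlcNAc rows).
#' @return Tibble of inferred sites in the standard site-table schema
#'   (`source = "inferred"`) plus `conserved_identity`, `source_protein`,
#'   `source_position`; attribute `skipped` counts non-transferred sites.
#' @export
transfer_sites <- function(alignment, source_sites) {
  src_id <- attr(alignment, "source_id", exact = TRUE)
  tgt_id <- attr(alignment, "target_id", exact = TRUE)
  if (nrow(source_sites) > 0) {
    if (!all(source_sites$protein_id == src_id)) {
      rlang::abort("source_sites must all lie on the alignment's source protein",
        class = "og_contract_error"
      )
    }
    if (!all(source_sites$residue %in% c("S", "T"))) {
      rlang::abort("source sites must be Ser/Thr", class = "og_contract_error")
    }
  }
  col <- match(source_sites$position, alignment$source_pos)
  tgt_pos <- alignment$target_pos[col]
  tgt_sym <- alignment$target_sym[col]
  ok <- !is.na(tgt_pos) & tgt_sym %in% c("S", "T")
  out <- tibble::tibble(
    protein_id = rep(tgt_id, sum(ok)),
    position = tgt_pos[ok],
    residue = tgt_sym[ok],
    ptm_type = "OGlcNAc",
    evidence = "",
    pmids = source_sites$pmids[ok],
    source = "inferred",
    conserved_identity = source_sites$residue[ok] == tgt_sym[ok],
    source_protein = src_id,
    source_position = source_sites$position[ok]
  )
  if (nrow(out) == 0L) {
    out$pmids <- character()
  }
  structure(out, skipped = sum(!ok))
}
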