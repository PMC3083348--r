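#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file into a tibble of protein records. Multi-line
#' sequence bodies are concatenated and letters are uppercased. Record order
#' follows file order. The record id is the first whitespace-delimited token of
#' the header; the remainder becomes the description.
#'
#' Sequences must use the 20 standard amino-acid letters. Ambiguity and
#' nonstandard codes (B, Z, X, U, O, J, `*`) are rejected by default because
#' the 21-symbol encoding alphabet has no slot for them; with
#' `permissive = TRUE` they are mapped to `X`, which downstream encoding
#' represents as an all-zero block.
#'
#' @param path Path to a FASTA file.
#' @param permissive Map nonstandard letters to `X` instead of failing.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @seealso [write_fasta()], [read_site_table()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo protein", "MAS", "TG"), fa)
#' read_fasta(fa)
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path), class = "og_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      id = character(), description = character(), sequence = character()
    ))
  }
  if (!startsWith(lines[[1]], ">")) {
    rlang::abort(
      "malformed FASTA: sequence data before the first '>' header",
      class = "og_format_error"
    )
  }
  # delegate the actual parsing to Biostrings, which handles FASTA edge cases
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  seqs <- toupper(as.character(set))
  proteins <- tibble::tibble(id = ids, description = desc, sequence = unname(seqs))
  validate_proteins(proteins, permissive = permissive)
}

# check sequence letters; under permissive = TRUE map nonstandard codes to X
validate_proteins <- function(proteins, permissive = FALSE) {
  if (any(!nzchar(proteins$sequence))) {
    rlang::abort("empty sequence in FASTA record", class = "og_format_error")
  }
  if (anyDuplicated(proteins$id)) {
    dup <- unique(proteins$id[duplicated(proteins$id)])
    rlang::abort(
      paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")),
      class = "og_format_error"
    )
  }
  if (permissive) {
    pat <- paste0("[", paste(setdiff(og_nonstandard(), "*"), collapse = ""), "*]")
    proteins$sequence <- gsub("\\*", "X", proteins$sequence)
    proteins$sequence <- gsub(pat, "X", proteins$sequence)
  }
  allowed <- if (permissive) c(og_aa(), "X") else og_aa()
  bad <- vapply(
    strsplit(proteins$sequence, ""),
    function(ch) paste(sort(unique(ch[!ch %in% allowed])), collapse = ""),
    character(1)
  )
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[[1]]
    rlang::abort(
      paste0(
        "record '", proteins$id[[i]], "' contains letters outside the ",
        "20-letter amino-acid alphabet: ", bad[[i]],
        if (!permissive) " (use permissive = TRUE to map them to X)" else ""
      ),
      class = "og_format_error"
    )
  }
  proteins
}

#' Write protein records to a FASTA file
#'
#' @param proteins Tibble with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  header <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  body <- vapply(proteins$sequence, function(s) {
    starts <- seq(1L, nchar(s), by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
      collapse = "\n"
    )
  }, character(1))
  writeLines(paste0(">", header, "\n", body), path)
  invisible(path)
}

site_table_cols <- function() {
  c("protein_id", "position", "residue", "ptm_type", "evidence", "pmids", "source")
}

#' Read a PTM site annotation table
#'
#' Reads a tab-delimited site table with columns `protein_id`, `position`
#' (1-based), `residue`, `ptm_type` (`OGlcNAc` or `Phospho`), `evidence`
#' (free-text tag, e.g. `"LS: MALDI-TOF-MS"`, kept verbatim), `pmids`
#' (comma-separated PubMed ids, may be empty) and `source` (`experimental` or
#' `inferred`). Lines starting with `#` are ignored. Extra columns are kept.
#'
#' When `proteins` is supplied every row is validated against the sequences:
#' the protein id must be known, the position must lie inside the sequence,
#' and the residue must equal the sequence letter at that (1-based) position
#' and be Ser or Thr. Validation failures are reported with their row numbers.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional protein tibble from [read_fasta()] to validate
#'   against.
#' @return A tibble of site annotations.
#' @export
read_site_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("site table not found: ", path), class = "og_io_error")
  }
  sites <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      position = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  missing <- setdiff(site_table_cols(), names(sites))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("site table lacks column(s): ", paste(missing, collapse = ", ")),
      class = "og_format_error"
    )
  }
  sites <- dplyr::mutate(
    sites,
    evidence = dplyr::coalesce(.data$evidence, ""),
    pmids = dplyr::coalesce(.data$pmids, "")
  )
  validate_sites(sites, proteins)
}

#' Validate site annotations against protein sequences
#'
#' @param sites Site annotation tibble (see [read_site_table()] for the schema).
#' @param proteins Optional protein tibble; sequence-level checks are skipped
#'   when `NULL`.
#' @return `sites`, invisibly validated (returned unchanged on success).
#' @export
validate_sites <- function(sites, proteins = NULL) {
  problems <- character()
  # note: paste0() recycles zero-length args to "", so guard on length
  note <- function(idx, ...) {
    if (length(idx) > 0L) {
      problems <<- c(problems, paste0("row ", idx, ": ", ...))
    }
  }
  bad_type <- which(!sites$ptm_type %in% c("OGlcNAc", "Phospho"))
  note(bad_type, "unknown ptm_type '", sites$ptm_type[bad_type], "'")
  bad_src <- which(!sites$source %in% c("experimental", "inferred"))
  note(bad_src, "unknown source '", sites$source[bad_src], "'")
  bad_res <- which(!sites$residue %in% c("S", "T"))
  note(bad_res, "residue '", sites$residue[bad_res], "' is not Ser/Thr")
  bad_pos <- which(is.na(sites$position) | sites$position < 1L)
  note(bad_pos, "position is not a positive integer")

  if (!is.null(proteins)) {
    idx <- match(sites$protein_id, proteins$id)
    unknown <- which(is.na(idx))
    note(unknown, "unknown protein_id '", sites$protein_id[unknown], "'")
    ok <- !is.na(idx) & !is.na(sites$position) & sites$position >= 1L
    len <- nchar(proteins$sequence)[idx]
    oor <- which(ok & sites$position > len)
    note(
      oor, "position ", sites$position[oor],
      " outside sequence of length ", len[oor]
    )
    inr <- ok & sites$position <= len
    actual <- substr(
      proteins$sequence[idx], sites$position, sites$position
    )
    mism <- which(inr & actual != sites$residue)
    note(
      mism, "residue '", sites$residue[mism],
      "' does not match sequence letter '", actual[mism],
      "' at position ", sites$position[mism]
    )
  }
  if (length(problems) > 0) {
    rlang::abort(
      paste0(
        "invalid site annotation(s):\n",
        paste(" -", problems, collapse = "\n")
      ),
      class = "og_validation_error"
    )
  }
  sites
}

#' Write a PTM site annotation table
#'
#' @param sites Site annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file Name of a file under the package's `extdata` directory;
#'   with no argument, lists the available files. `"yin_yang_table1.tsv"`
#'   is a transcription of the published table of O-GlcNAc/phospho sites
#'   occurring at identical or adjacent (+/- 4 aa) Ser/Thr positions.
#' @return A file path, or a character vector of file names.
#' @export
og_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "oglcnacr")))
  }
  system.file("extdata", file, package = "oglcnacr", mustWork = TRUE)
}
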