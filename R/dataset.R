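#' Assemble a labeled, encoded training dataset
#'
#' Every Ser/Thr in every protein becomes exactly one instance. Sites carrying
#' an `OGlcNAc` annotation are the positives; all remaining Ser/Thr sites in
#' the same sequences are the negatives — the corpus is left at its natural
#' class balance (about 1.2% positives in the motivating corpus) rather than
#' resampled.
#'
#' @param proteins Protein tibble from [read_fasta()].
#' @param annotations Site annotation tibble; only `ptm_type == "OGlcNAc"`
#'   rows define positives. May be empty.
#' @param config A [window_config()].
#' @return An `og_dataset`: a tibble with columns `protein_id`, `position`,
#'   `residue`, `label` (`"positive"`/`"negative"`) and the one-hot feature
#'   matrix in attribute `"features"` (retrieve with [og_features()]).
#' @export
#' @examples
#' p <- tibble::tibble(id = "p1", description = "", sequence = "MASTGSAT")
#' a <- tibble::tibble(
#'   protein_id = "p1", position = 3L, residue = "S", ptm_type = "OGlcNAc",
#'   evidence = "", pmids = "", source = "experimental"
#' )
#' d <- assemble_dataset(p, a, window_config(2))
#' table(d$label)
assemble_dataset <- function(proteins, annotations = NULL, config = window_config()) {
  sites <- extract_candidate_sites(proteins)
  if (nrow(sites) == 0L) {
    rlang::abort("no Ser/Thr sites in the supplied proteins",
      class = "og_contract_error"
    )
  }
  label <- rep("negative", nrow(sites))
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    ann <- dplyr::filter(annotations, .data$ptm_type == "OGlcNAc")
    if (nrow(ann) > 0L) {
      validate_sites(ann, proteins)
      key <- paste(sites$protein_id, sites$position)
      label[key %in% paste(ann$protein_id, ann$position)] <- "positive"
    }
  }
  sites$label <- label
  x <- encode_matrix(proteins, sites, config)
  structure(
    tibble::new_tibble(sites, class = "og_dataset"),
    features = x,
    window = config
  )
}

#' Feature matrix of an encoded dataset
#'
#' @param dataset An `og_dataset` from [assemble_dataset()].
#' @return The 0/1 feature matrix (instances by `21 * (2n + 1)` columns).
#' @export
og_features <- function(dataset) {
  x <- attr(dataset, "features", exact = TRUE)
  if (is.null(x)) {
    rlang::abort("not an encoded dataset (no feature matrix attached)",
      class = "og_contract_error"
    )
  }
  x
}

og_window <- function(dataset) attr(dataset, "window", exact = TRUE)

#' @export
print.og_dataset <- function(x, ...) {
  cfg <- og_window(x)
  cat(
    "<og_dataset> ", nrow(x), " Ser/Thr instances (",
    sum(x$label == "positive"), " positive, ",
    sum(x$label == "negative"), " negative), window n = ", cfg$n,
    ", ", ncol(og_features(x)), " binary features\n",
    sep = ""
  )
  NextMethod()
}

# subsetting an og_dataset keeps the feature rows aligned
subset_dataset <- function(dataset, i) {
  out <- dataset[i, , drop = FALSE]
  structure(
    tibble::new_tibble(out, class = "og_dataset"),
    features = og_features(dataset)[i, , drop = FALSE],
    window = og_window(dataset)
  )
}
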