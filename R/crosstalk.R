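#' Identical Yin-Yang positions
#'
#' Positions carrying both an O-GlcNAc and a phospho annotation in the same
#' protein: the intersection of the two position sets.
#'
#' @param g_sites Integer vector of O-GlcNAc positions (1-based).
#' @param p_sites Integer vector of phospho positions (1-based).
#' @return Sorted integer vector of identical positions.
#' @export
#' @examples
#' find_identical(c(308, 473), c(308, 473))
find_identical <- function(g_sites, p_sites) {
  sort(intersect(as.integer(p_sites), as.integer(g_sites)))
}

#' Adjacent Yin-Yang positions
#'
#' Phospho positions within `k` residues (1 <= |p - g| <= k) of some O-GlcNAc
#' position. "Adjacent" is judged per (p, g) pair, so a phospho-site identical
#' to one O-GlcNAc site still qualifies when it lies within `k` of a
#' *different* O-GlcNAc site.
#'
#' @param g_sites,p_sites Integer position vectors as in [find_identical()].
#' @param k Adjacency half-window in residues (default 4).
#' @return Sorted integer vector of adjacent phospho positions.
#' @export
#' @examples
#' find_adjacent(g_sites = c(13, 15), p_sites = c(9, 13, 14), k = 4)
find_adjacent <- function(g_sites, p_sites, k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  p <- as.integer(p_sites)
  g <- as.integer(g_sites)
  if (k == 0L || length(p) == 0L || length(g) == 0L) {
    return(integer())
  }
  d <- abs(outer(p, g, `-`))
  sort(unique(p[apply(d >= 1L & d <= k, 1L, any)]))
}

# split a long site tibble into per-protein g/p position sets
site_sets <- function(sites) {
  stopifnot(all(c("protein_id", "position", "ptm_type") %in% names(sites)))
  bad <- setdiff(unique(sites$ptm_type), c("OGlcNAc", "Phospho"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown ptm_type: ", paste(bad, collapse = ", ")),
      class = "og_validation_error"
    )
  }
  ids <- unique(sites$protein_id)
  purrr::map(rlang::set_names(ids), function(id) {
    d <- sites[sites$protein_id == id, ]
    list(
      g = sort(unique(d$position[d$ptm_type == "OGlcNAc"])),
      p = sort(unique(d$position[d$ptm_type == "Phospho"]))
    )
  })
}

#' Per-site Yin-Yang crosstalk classification
#'
#' Classifies every phospho-site of every protein against the protein's
#' O-GlcNAc sites: `identical` relations (same position) and `adjacent`
#' relations (within `k` residues of some O-GlcNAc site). A site may appear
#' with both relations. The reported partner is the nearest qualifying
#' O-GlcNAc site (ties towards the smaller position).
#'
#' @param sites Tibble with columns `protein_id`, `position`, `ptm_type`
#'   (`OGlcNAc` / `Phospho`), e.g. from [read_site_table()].
#' @param k Adjacency half-window in residues (default 4).
#' @return Tibble with columns `protein_id`, `position`, `relation`,
#'   `partner_g_site`, `distance`.
#' @export
crosstalk_sites <- function(sites, k = 4L) {
  sets <- site_sets(sites)
  rows <- purrr::imap(sets, function(s, id) {
    ident <- find_identical(s$g, s$p)
    adj <- find_adjacent(s$g, s$p, k)
    out <- list()
    if (length(ident) > 0) {
      out$identical <- tibble::tibble(
        protein_id = id, position = ident, relation = "identical",
        partner_g_site = ident, distance = 0L
      )
    }
    if (length(adj) > 0) {
      partner <- vapply(adj, function(q) {
        cand <- s$g[abs(s$g - q) >= 1L & abs(s$g - q) <= k]
        cand[order(abs(cand - q), cand)][[1L]]
      }, integer(1))
      out$adjacent <- tibble::tibble(
        protein_id = id, position = adj, relation = "adjacent",
        partner_g_site = partner, distance = abs(adj - partner)
      )
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      protein_id = character(), position = integer(), relation = character(),
      partner_g_site = integer(), distance = integer()
    )
  }
  out
}

#' Corpus-wide Yin-Yang crosstalk summary
#'
#' Aggregates [crosstalk_sites()] over all proteins: per-protein counts of
#' identical and adjacent phospho-sites (each counted once per distinct
#' position) and corpus totals, including the number of proteins with at
#' least one identical-or-adjacent relation.
#'
#' @inheritParams crosstalk_sites
#' @return An `og_crosstalk` object: list with `sites` (the per-site
#'   classification), `per_protein` (tibble of per-protein counts) and
#'   `totals` (tibble with `proteins_with_any`, `identical_count`,
#'   `adjacent_count`).
#' @export
#' @examples
#' tab <- read_site_table(og_example("yin_yang_table1.tsv"))
#' crosstalk_summary(tab)$totals
crosstalk_summary <- function(sites, k = 4L) {
  detail <- crosstalk_sites(sites, k = k)
  per_protein <- dplyr::summarise(
    dplyr::group_by(detail, .data$protein_id),
    identical = sum(.data$relation == "identical"),
    adjacent = sum(.data$relation == "adjacent"),
    .groups = "drop"
  )
  totals <- tibble::tibble(
    proteins_with_any = nrow(per_protein),
    identical_count = sum(per_protein$identical),
    adjacent_count = sum(per_protein$adjacent)
  )
  structure(
    list(sites = detail, per_protein = per_protein, totals = totals, k = k),
    class = "og_crosstalk"
  )
}

#' @export
print.og_crosstalk <- function(x, ...) {
  cat(
    "<og_crosstalk> k = ", x$k, "\n",
    "  proteins with identical-or-adjacent sites: ", x$totals$proteins_with_any, "\n",
    "  identical phospho/O-GlcNAc positions:      ", x$totals$identical_count, "\n",
    "  adjacent phospho positions (<= k away):    ", x$totals$adjacent_count, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a crosstalk report
#'
#' @param x An `og_crosstalk` object.
#' @param ... Unused.
#' @return The per-site relation tibble (`glance()` returns the totals).
#' @export
tidy.og_crosstalk <- function(x, ...) x$sites

#' @rdname tidy.og_crosstalk
#' @export
glance.og_crosstalk <- function(x, ...) x$totals
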