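# Annotation transfer from tabular homology searches and domain assignment.

#' Transfer annotation from the best homology hit per query
#'
#' For each query, selects the most similar subject: smallest E-value, ties
#' broken by larger bit score, then lexicographically smallest subject id.
#'
#' @param hits A tibble of homology hits as returned by [read_blast_hits()]
#'   (columns `query_id`, `subject_id`, `evalue`, `bitscore`, optionally
#'   `subject_description`).
#' @param source_db Optional database label stored with every annotation
#'   (e.g. `"Nr"`, `"SwissProt"`, `"KEGG"`, `"COG"`).
#' @return A tibble with one row per distinct query: `gene_id`,
#'   `best_subject`, `description`, `evalue`, `bitscore`, `source_db`.
#' @export
transfer_best_hit <- function(hits, source_db = NA_character_) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    return(tibble::tibble(gene_id = character(), best_subject = character(),
                          description = character(), evalue = double(),
                          bitscore = double(), source_db = character()))
  }
  desc <- if ("subject_description" %in% names(hits)) {
    hits$subject_description
  } else {
    rep(NA_character_, nrow(hits))
  }
  tibble::tibble(gene_id = hits$query_id, best_subject = hits$subject_id,
                 description = desc, evalue = hits$evalue,
                 bitscore = hits$bitscore) |>
    dplyr::arrange(.data$gene_id, .data$evalue, dplyr::desc(.data$bitscore),
                   .data$best_subject) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::mutate(source_db = source_db)
}

#' Assign Pfam domains to proteins
#'
#' Collapses per-domain hits into one set of distinct, unversioned domain
#' accessions per protein. Hits at or above `evalue_cutoff` are discarded
#' (readers usually pre-filter; the filter here is idempotent). Proteins
#' with no surviving hit are absent from the output.
#'
#' @param hits A tibble of domain hits as returned by [read_domain_hits()].
#' @param evalue_cutoff Reliable-hit threshold (default `1e-5`).
#' @return A tibble with columns `protein_id`, `domain_acc` (one row per
#'   protein-domain pair).
#' @export
assign_domains <- function(hits, evalue_cutoff = 1e-5) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    return(tibble::tibble(protein_id = character(), domain_acc = character()))
  }
  hits |>
    dplyr::filter(.data$evalue < evalue_cutoff) |>
    dplyr::mutate(domain_acc = strip_pfam_version(.data$domain_acc)) |>
    dplyr::distinct(.data$protein_id, .data$domain_acc) |>
    dplyr::arrange(.data$protein_id, .data$domain_acc)
}

#' Rank the most abundant domains
#'
#' Counts, for each domain, the number of distinct proteins carrying it,
#' and returns the top `n` domains, descending by count with ties broken by
#' ascending accession. Domain display names are taken from the hit table.
#'
#' @param assignments A tibble from [assign_domains()].
#' @param hits The domain-hit tibble the assignments came from (used to
#'   recover `domain_name` for each accession).
#' @param n Number of top domains to report (default 20).
#' @return A tibble with columns `domain_name`, `domain_acc`, `n_proteins`.
#' @export
top_domain_summary <- function(assignments, hits, n = 20) {
  if (n < 1) stop_validation("top_domain_summary: n must be >= 1")
  names_map <- hits |>
    dplyr::mutate(domain_acc = strip_pfam_version(.data$domain_acc)) |>
    dplyr::distinct(.data$domain_acc, .keep_all = TRUE) |>
    dplyr::select("domain_acc", "domain_name")
  assignments |>
    dplyr::count(.data$domain_acc, name = "n_proteins") |>
    dplyr::left_join(names_map, by = "domain_acc") |>
    dplyr::arrange(dplyr::desc(.data$n_proteins), .data$domain_acc) |>
    dplyr::select("domain_name", "domain_acc", "n_proteins") |>
    head(n) |>
    tibble::as_tibble()
}

#' Attach functional terms to annotated genes
#'
#' Joins best-hit annotations against a subject-to-term map, yielding a
#' gene-to-term table suitable for [term_enrichment()].
#'
#' @param annotations A tibble from [transfer_best_hit()].
#' @param term_map A tibble with columns `subject_id`, `term_id`,
#'   `term_name` (see [read_term_map()]).
#' @return A tibble with columns `gene_id`, `term_id`, `term_name`.
#' @export
attach_terms <- function(annotations, term_map) {
  stopifnot(all(c("subject_id", "term_id") %in% names(term_map)))
  annotations |>
    dplyr::inner_join(term_map, by = c(best_subject = "subject_id"),
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", "term_id", "term_name")
}

#' Read a subject-to-term map
#'
#' TSV with columns `subject_id`, `term_id`, `term_name` (header required).
#'
#' @param path Path to the map file.
#' @return A tibble with those three character columns.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("subject_id", "term_id", "term_name")
  if (!all(need %in% names(out))) {
    stop_parse("term map must have columns subject_id, term_id, term_name")
  }
  out
}
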