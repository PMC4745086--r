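# Fisher-exact term enrichment with Benjamini-Hochberg correction, and a
# two-set term-frequency comparison. All tail sums are accumulated in log
# space so that p-values far below the double underflow of naive products
# (e.g. 1e-206 for genome-scale tables) remain representable.

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test on the table `rbind(c(a, b), c(c, d))`. The
#' two-sided p-value is the sum of the probabilities of all tables (with
#' the same margins) no more probable than the observed one; `"greater"`
#' is the upper tail of the first cell. Probabilities are evaluated with
#' log-space gamma arithmetic, so tables with totals in the hundreds of
#' thousands are handled without underflow.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise).
#' @param sided `"two.sided"` (default) or `"greater"`.
#' @return A p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(1, 1, 1, 1)  # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  if (any(c(a, b, c, d) < 0)) {
    stop_validation("fisher_exact_2x2: counts must be non-negative")
  }
  if (a + b + c + d < 1) stop_validation("fisher_exact_2x2: empty table")
  m <- a + b         # row 1 total (white balls)
  n2 <- c + d        # row 2 total (black balls)
  k <- a + c         # column 1 total (drawn)
  if (sided == "greater") {
    p <- phyper(a - 1, m, n2, k, lower.tail = FALSE)
    return(min(max(p, .Machine$double.xmin), 1))
  }
  support <- max(0, k - n2):min(k, m)
  logd <- dhyper(support, m, n2, k, log = TRUE)
  obs <- logd[match(a, support)]
  # relative tolerance guards against ties broken by rounding
  keep <- logd <= obs + log(1 + 1e-7)
  p <- exp(logsumexp(logd[keep]) - logsumexp(logd))
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j >= i}
#' p_(j) * m / j`, clipped at 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_validation("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Term over-representation analysis of a gene set
#'
#' For every functional term annotated to at least one background gene, a
#' one-sided (over-representation) Fisher exact test compares the term's
#' frequency inside the gene set against the rest of the background, with
#' Benjamini-Hochberg correction across all tested terms.
#'
#' @param gene_set Character vector of genes of interest; must be a subset
#'   of `background`.
#' @param background Character vector of all eligible genes.
#' @param term_map A data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name` (e.g. from [attach_terms()]). Genes outside the
#'   background are ignored.
#' @param sided Passed to [fisher_exact_2x2()]; default `"greater"`.
#' @return A tibble with one row per tested term: `term_id`, `term_name`,
#'   `k` (term genes in set), `n` (set size), `K` (term genes in
#'   background), `N` (background size), `pvalue`, `qvalue`, `flagged`
#'   (`qvalue < 0.05`), sorted by `pvalue`.
#' @export
term_enrichment <- function(gene_set, background, term_map,
                            sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (!all(gene_set %in% background)) {
    stop_validation("term_enrichment: gene_set must be a subset of background")
  }
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  if (!"term_name" %in% names(term_map)) term_map$term_name <- NA_character_
  N <- length(background)
  n <- length(gene_set)
  tm <- term_map |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  if (!nrow(tm)) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), pvalue = double(), qvalue = double(),
                          flagged = logical()))
  }
  per_term <- tm |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(term_name = .data$term_name[1],
                     K = dplyr::n(),
                     k = sum(.data$gene_id %in% gene_set),
                     .groups = "drop")
  pv <- purrr::map2_dbl(per_term$k, per_term$K, function(k, K) {
    fisher_exact_2x2(k, n - k, K - k, N - n - (K - k), sided = sided)
  })
  per_term |>
    dplyr::mutate(n = n, N = N, pvalue = pv,
                  qvalue = benjamini_hochberg(pv),
                  flagged = .data$qvalue < 0.05) |>
    dplyr::select("term_id", "term_name", "k", "n", "K", "N",
                  "pvalue", "qvalue", "flagged") |>
    dplyr::arrange(.data$pvalue, .data$term_id)
}

#' Compare a term's frequency between two gene sets
#'
#' Two-sided Fisher exact test of `kA` term-positive genes out of `nA`
#' against `kB` out of `nB` — e.g. contrasting how often an ontology term
#' appears in two differentially-expressed gene sets.
#'
#' @param kA,nA Term-positive count and size of set A (`kA <= nA`).
#' @param kB,nB Term-positive count and size of set B (`kB <= nB`).
#' @return A two-sided p-value in (0, 1].
#' @export
compare_two_sets <- function(kA, nA, kB, nB) {
  if (kA > nA || kB > nB) {
    stop_validation("compare_two_sets: k must not exceed n")
  }
  fisher_exact_2x2(kA, nA - kA, kB, nB - kB, sided = "two.sided")
}

#' Write an enrichment table as TSV
#'
#' @param enrichment A tibble from [term_enrichment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  readr::write_tsv(enrichment, path)
  invisible(path)
}
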