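#' Read a nucleotide FASTA file into a tibble
#'
#' Parses a FASTA file of unigene (assembled transcript) sequences. Sequence
#' identifiers are the first whitespace-delimited token of each header line.
#' Sequences are upper-cased and must use the alphabet `A`, `C`, `G`, `T`,
#' `N`; anything else is a validation error, as is a duplicated identifier.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   uppercase), one row per record, input order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">u1", "acgtACGT", ">u2", "NNAC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && !startsWith(first, ">")) {
    stop_parse("malformed FASTA header at line 1: expected '>'")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_parse(paste0("malformed FASTA: ",
                                          conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop_parse(paste0("empty FASTA header (record ",
                      which(!nzchar(ids))[1], ")"))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_validation(paste0("duplicate sequence id: ", dup[1]))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_validation(paste0("sequence '", ids[which(bad)[1]],
                           "' contains characters outside {A,C,G,T,N}"))
  }
  if (any(nchar(seqs) < 1L)) {
    stop_validation(paste0("empty sequence for id '",
                           ids[which(nchar(seqs) < 1L)[1]], "'"))
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param records A data frame with columns `id` and `seq`. An optional
#'   `desc` column is appended to the header after a space.
#' @param path Output file path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  hdr <- records$id
  if ("desc" %in% names(records)) {
    hdr <- ifelse(nzchar(records$desc), paste(hdr, records$desc), hdr)
  }
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(records$seq)
  } else {
    Biostrings::AAStringSet(records$seq)
  }
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-domain HMM search hits (domtblout-style)
#'
#' Reads a whitespace-delimited table of protein-vs-Pfam domain hits in the
#' column layout of HMMER's per-domain tabular output: target (protein) name
#' in column 1, query (domain) name in column 4, domain accession in column
#' 5, full-sequence E-value in column 7 and bit score in column 8. Comment
#' lines starting with `#` are skipped. Pfam accession version suffixes
#' (`PF13465.1` -> `PF13465`) are stripped so accessions join cleanly
#' against unversioned domain-interaction tables.
#'
#' @param path Path to the hits table.
#' @param evalue_cutoff Retain only hits with E-value strictly below this
#'   cutoff (default `1e-5`, the conventional reliable-hit threshold).
#' @return A tibble with columns `protein_id`, `domain_name`, `domain_acc`
#'   (unversioned), `evalue`, `bitscore`.
#' @export
read_domain_hits <- function(path, evalue_cutoff = 1e-5) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(protein_id = character(), domain_name = character(),
                          domain_acc = character(), evalue = double(),
                          bitscore = double()))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop_parse(paste0("line ", idx[which(nf < 8L)[1]],
                      ": expected >= 8 whitespace-delimited columns"))
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  if (anyNA(ev)) {
    stop_parse(paste0("line ", idx[which(is.na(ev))[1]],
                      ": non-numeric E-value"))
  }
  if (any(ev < 0)) {
    stop_validation(paste0("line ", idx[which(ev < 0)[1]],
                           ": negative E-value"))
  }
  bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 8L)))
  if (anyNA(bs)) {
    stop_parse(paste0("line ", idx[which(is.na(bs))[1]],
                      ": non-numeric bit score"))
  }
  out <- tibble::tibble(
    protein_id = vapply(fields, `[[`, "", 1L),
    domain_name = vapply(fields, `[[`, "", 4L),
    domain_acc = strip_pfam_version(vapply(fields, `[[`, "", 5L)),
    evalue = ev,
    bitscore = bs
  )
  dplyr::filter(out, .data$evalue < evalue_cutoff)
}

#' Read tabular homology (BLAST outfmt-6 style) hits
#'
#' Reads a 12-column tab-delimited alignment table (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, E-value, bit score); a 13th column, if present, is kept as the
#' subject description.
#'
#' @param path Path to the hits table.
#' @param evalue_cutoff Retain only rows with E-value strictly below this
#'   cutoff (default `1e-5`).
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `bitscore`, `subject_description`.
#' @export
read_blast_hits <- function(path, evalue_cutoff = 1e-5) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(lines)
  idx <- which(keep)
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          percent_identity = double(), evalue = double(),
                          bitscore = double(), subject_description = character())
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L | nf > 13L)) {
    bad <- which(nf < 12L | nf > 13L)[1]
    stop_parse(paste0("line ", idx[bad], ": expected 12 or 13 tab-delimited ",
                      "columns, found ", nf[bad]))
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(ev)) {
    stop_parse(paste0("line ", idx[which(is.na(ev))[1]],
                      ": non-numeric E-value"))
  }
  pid <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(pid) || any(pid < 0 | pid > 100)) {
    stop_validation(paste0("line ",
                           idx[which(is.na(pid) | pid < 0 | pid > 100)[1]],
                           ": percent identity outside [0,100]"))
  }
  if (any(ev < 0)) {
    stop_validation(paste0("line ", idx[which(ev < 0)[1]],
                           ": negative E-value"))
  }
  desc <- vapply(fields, function(f) if (length(f) >= 13L) f[[13L]] else "", "")
  out <- tibble::tibble(
    query_id = vapply(fields, `[[`, "", 1L),
    subject_id = vapply(fields, `[[`, "", 2L),
    percent_identity = pid,
    evalue = ev,
    bitscore = as.numeric(vapply(fields, `[[`, "", 12L)),
    subject_description = desc
  )
  dplyr::filter(out, .data$evalue < evalue_cutoff)
}

#' Read a domain-domain interaction table
#'
#' Reads a flat file of interacting Pfam domain pairs, one interaction per
#' line, pipe- or tab-delimited: accession, accession, confidence class
#' (e.g. `HC`/`MC`/`LC`/`NA` in DOMINE-style compendia). Pairs are unordered
#' — `(a,b)` and `(b,a)` are the same interaction and are deduplicated; a
#' domain may interact with itself. Accession version suffixes are stripped.
#'
#' @param path Path to the interaction table.
#' @param accepted_confidences Character vector of confidence classes to
#'   retain, or `NULL` (default) to accept every class.
#' @return A tibble with columns `domain_a`, `domain_b` (canonical order,
#'   `domain_a <= domain_b`) and `confidence`.
#' @export
read_ddi_table <- function(path, accepted_confidences = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- tibble::tibble(domain_a = character(), domain_b = character(),
                          confidence = character())
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(trimws(lines[idx]), "[|\t]")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_parse(paste0("line ", idx[which(nf < 3L)[1]],
                      ": expected 3 columns (domain, domain, confidence)"))
  }
  a <- strip_pfam_version(trimws(vapply(fields, `[[`, "", 1L)))
  b <- strip_pfam_version(trimws(vapply(fields, `[[`, "", 2L)))
  conf <- trimws(vapply(fields, `[[`, "", 3L))
  cp <- canonical_pair(a, b)
  out <- tibble::tibble(domain_a = cp$a, domain_b = cp$b, confidence = conf)
  if (!is.null(accepted_confidences)) {
    out <- dplyr::filter(out, .data$confidence %in% accepted_confidences)
  }
  dplyr::distinct(out, .data$domain_a, .data$domain_b, .keep_all = TRUE)
}

#' Assembly summary statistics
#'
#' Computes the count, total length, mean length and N50 of an assembly.
#' N50 is the length for which sequences of that length or longer contain at
#' least half of the summed length of all sequences: lengths are sorted in
#' decreasing order and the first length at which the cumulative sum reaches
#' `total/2` (inclusive) is returned. The mean is rounded to the nearest
#' integer, ties away from zero.
#'
#' @param records A data frame of sequences as returned by [read_fasta()]
#'   (columns `id`, `seq`), or any data frame with a `seq` column.
#' @return A one-row tibble with columns `n_sequences`, `total_length`,
#'   `mean_length`, `n50`.
#' @examples
#' recs <- tibble::tibble(id = paste0("u", 1:5),
#'                        seq = strrep("A", 1:5))
#' assembly_stats(recs)  # n50 = 4
#' @export
assembly_stats <- function(records) {
  stopifnot(is.data.frame(records), "seq" %in% names(records))
  if (nrow(records) < 1L) stop_validation("assembly_stats: no sequences")
  len <- nchar(records$seq)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  tibble::tibble(
    n_sequences = length(len),
    total_length = total,
    mean_length = as.integer(round_half_away(total / length(len))),
    n50 = as.integer(n50)
  )
}
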