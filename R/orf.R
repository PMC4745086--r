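# Six-frame ORF scanning and longest-ORF protein prediction.
#
# ORFs are stop-to-stop: a maximal run of non-stop codons in one of the six
# reading frames, with no start-codon requirement (assembled transcripts are
# frequently 5'-truncated). Coordinates are always reported on the forward
# strand, 0-based half-open, and (end - start) is a multiple of 3.

# translate a vector of DNA codons; codons not in the standard table
# (anything containing N) become 'X', stops become '*'
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# stop-free codon runs in a single frame of strand-sequence s.
# offset: 0,1,2. Returns data frame with codon-index bounds (1-based,
# inclusive) and protein strings.
frame_runs <- function(s, offset) {
  n <- nchar(s)
  ncod <- (n - offset) %/% 3L
  if (ncod < 1L) {
    return(data.frame(i1 = integer(), i2 = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  starts <- offset + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- translate_codons(codons)
  open <- aa != "*"
  r <- rle(open)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  sel <- which(r$values)
  if (!length(sel)) {
    return(data.frame(i1 = integer(), i2 = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  i1 <- begins[sel]
  i2 <- ends[sel]
  protein <- vapply(seq_along(i1), function(j) {
    paste(aa[i1[j]:i2[j]], collapse = "")
  }, "")
  data.frame(i1 = i1, i2 = i2, protein = protein, stringsAsFactors = FALSE)
}

#' Enumerate candidate ORFs in all six reading frames
#'
#' Scans the three forward and three reverse frames of a nucleotide sequence
#' and reports every maximal stop-free codon run (stop-to-stop ORF, no start
#' codon required). Ambiguous codons (containing `N`) translate to `X` and
#' do not terminate a run; trailing partial codons are ignored; terminal
#' runs without a closing stop are reported (open 3' end).
#'
#' @param seq A single nucleotide string over `A`,`C`,`G`,`T`,`N`
#'   (case-insensitive).
#' @return A tibble with columns `frame` (one of `1,2,3,-1,-2,-3`), `start`,
#'   `end` (0-based half-open interval on the forward strand) and `protein`
#'   (amino-acid string, length >= 1). Sequences shorter than 3 nt yield an
#'   empty tibble.
#' @examples
#' six_frame_orfs("ATGGCCTAA")  # frame +1 candidate "MA"
#' @export
six_frame_orfs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    stop_validation("sequence contains characters outside {A,C,G,T,N}")
  }
  L <- nchar(s)
  empty <- tibble::tibble(frame = integer(), start = integer(),
                          end = integer(), protein = character())
  if (L < 3L) return(empty)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  out <- vector("list", 6L)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (k in seq_along(frames)) {
    f <- frames[k]
    offset <- abs(f) - 1L
    runs <- frame_runs(if (f > 0) s else rc, offset)
    if (!nrow(runs)) next
    # strand coordinates, 0-based half-open
    st <- offset + 3L * (runs$i1 - 1L)
    en <- offset + 3L * runs$i2
    if (f < 0) {  # map reverse-strand interval back to forward strand
      tmp <- L - en
      en <- L - st
      st <- tmp
    }
    out[[k]] <- tibble::tibble(frame = f, start = st, end = en,
                               protein = runs$protein)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) empty else res
}

#' Select the longest-ORF protein of a sequence
#'
#' Returns the single longest six-frame candidate ORF if its protein is at
#' least `min_aa` residues, otherwise no row. Equal-length candidates are
#' broken deterministically by frame order `+1, +2, +3, -1, -2, -3`, then by
#' smallest forward-strand start.
#'
#' @inheritParams six_frame_orfs
#' @param min_aa Minimum retained protein length in amino acids (default 30).
#' @return A tibble with zero or one row and columns `frame`, `start`,
#'   `end`, `protein`.
#' @export
select_protein <- function(seq, min_aa = 30) {
  cands <- six_frame_orfs(seq)
  if (!nrow(cands)) return(cands)
  rank <- match(cands$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  ord <- order(-nchar(cands$protein), rank, cands$start)
  best <- cands[ord[1], ]
  if (nchar(best$protein) < min_aa) return(cands[0, ])
  best
}

#' Predict proteins for a table of unigene sequences
#'
#' Applies [select_protein()] to every record; unigenes whose longest ORF is
#' shorter than `min_aa` amino acids are dropped.
#'
#' @param records A data frame with columns `id` and `seq`
#'   (see [read_fasta()]).
#' @param min_aa Minimum retained protein length (default 30).
#' @return A tibble with columns `unigene_id`, `frame`, `start`, `end`,
#'   `protein`.
#' @export
predict_proteins <- function(records, min_aa = 30) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  picks <- purrr::map2(records$id, records$seq, function(id, s) {
    hit <- select_protein(s, min_aa = min_aa)
    if (nrow(hit)) dplyr::mutate(hit, unigene_id = id) else NULL
  })
  out <- dplyr::bind_rows(picks)
  if (!nrow(out)) {
    return(tibble::tibble(unigene_id = character(), frame = integer(),
                          start = integer(), end = integer(),
                          protein = character()))
  }
  dplyr::select(out, "unigene_id", "frame", "start", "end", "protein")
}

#' Write predicted proteins as amino-acid FASTA
#'
#' Headers have the form `<unigene_id> frame=<f> coords=<start>-<end>`.
#'
#' @param proteins A tibble as returned by [predict_proteins()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  recs <- tibble::tibble(
    id = proteins$unigene_id,
    seq = proteins$protein,
    desc = sprintf("frame=%+d coords=%d-%d", proteins$frame,
                   proteins$start, proteins$end)
  )
  write_fasta(recs, path, type = "protein")
}
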