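# Seeded synthetic-data generators with known ground truth.
#
# The bundle emulates the tabular landscape of a post-assembly transcriptome
# project: unigene FASTA with planted ORFs, domain and homology hit tables,
# a domain-interaction table implying a known protein network, a two-sample
# count matrix with planted differential expression, a term map and a seed
# gene list. Each section draws from its own sub-stream (a fixed offset on
# the bundle seed) so adding a generator never perturbs existing outputs.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# the 61 sense codons
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all64, STOP_CODONS)
}

# generator-internal scanner: lengths of all maximal stop-free codon runs
# across the six frames (independent of the orf module's implementation)
stopfree_run_lengths <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- integer(0)
  for (s in c(seq, rc)) {
    for (offset in 0:2) {
      ncod <- (nchar(s) - offset) %/% 3L
      if (ncod < 1L) next
      starts <- offset + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      open <- !(codons %in% STOP_CODONS)
      r <- rle(open)
      out <- c(out, r$lengths[r$values])
    }
  }
  out
}

# stop-dense padding: every frame of (TTAA)* hits a stop within 4 codons,
# on both strands (TTAA is its own reverse complement)
pad_seq <- function(n) {
  if (n == 0L) return("")
  substring(strrep("TTAA", ceiling(n / 4) + 1L), 1L, n)
}

# one unigene with a planted ORF of orf_aa codons in the requested frame.
# Returns list(seq, start, end, protein); the planted run is the strict
# six-frame maximum (or, for sub-threshold ORFs, all runs are < min_aa).
plant_orf <- function(orf_aa, frame, min_aa = 30, max_tries = 200) {
  codons61 <- sense_codons()
  code <- Biostrings::GENETIC_CODE
  fpos <- abs(frame)
  for (try in seq_len(max_tries)) {
    lp <- sample(8:40, 1)
    lp <- lp + ((fpos - 1L) - lp %% 3L) %% 3L  # align ORF start to frame
    rp <- sample(8:40, 1)
    orf_codons <- sample(codons61, orf_aa, replace = TRUE)
    core <- paste0(pad_seq(lp), "TAA", paste(orf_codons, collapse = ""),
                   "TAA", pad_seq(rp))
    s <- lp + 3L                      # 0-based ORF start in core
    e <- s + 3L * orf_aa
    L <- nchar(core)
    runs <- stopfree_run_lengths(core)
    ok <- if (orf_aa >= min_aa) {
      max(runs) == orf_aa && sum(runs == orf_aa) == 1L
    } else {
      max(runs) < min_aa
    }
    if (!ok) next
    if (frame > 0) {
      return(list(seq = core, start = s, end = e,
                  protein = paste(unname(code[orf_codons]), collapse = "")))
    }
    rcseq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(core)))
    return(list(seq = rcseq, start = L - e, end = L - s,
                protein = paste(unname(code[orf_codons]), collapse = "")))
  }
  stop_validation("plant_orf: failed to construct an unambiguous planted ORF")
}

#' Simulate a two-sample negative-binomial count matrix with planted DE
#'
#' Non-differential genes share their mean across the two samples;
#' differential genes differ by a factor of `2^lfc` (half up, half down).
#' Counts are drawn NB with dispersion `alpha` (variance `mu + alpha*mu^2`).
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param mean_range Range of baseline means, sampled log-uniformly
#'   (default `c(50, 1000)`).
#' @param alpha NB dispersion, strictly positive (a Poisson limit is
#'   approximated by a tiny alpha, never by 0).
#' @param n_de Number of planted differential genes (default 0).
#' @param lfc Absolute planted log2 fold change (default 2).
#' @return A list with `counts` (tibble `gene_id`, `sampleA`, `sampleB`)
#'   and `truth` (tibble `gene_id`, `is_de`, `direction`, `true_lfc`).
#' @export
simulate_nb_counts <- function(n_genes, seed, mean_range = c(50, 1000),
                               alpha = 0.05, n_de = 0, lfc = 2) {
  if (n_genes < 1) stop_validation("simulate_nb_counts: n_genes must be >= 1")
  if (alpha <= 0) {
    stop_validation("simulate_nb_counts: alpha must be > 0 (approximate Poisson with a tiny alpha)")
  }
  if (n_de > n_genes || n_de < 0) {
    stop_validation("simulate_nb_counts: need 0 <= n_de <= n_genes")
  }
  set.seed(seed)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  direction <- rep(0L, n_genes)
  if (n_de > 0) {
    direction[de_idx] <- rep_len(c(1L, -1L), n_de)
  }
  muB <- mu * 2^(lfc * direction)
  counts <- tibble::tibble(
    gene_id = gene_id,
    sampleA = rnbinom(n_genes, mu = mu, size = 1 / alpha),
    sampleB = rnbinom(n_genes, mu = muB, size = 1 / alpha)
  )
  truth <- tibble::tibble(
    gene_id = gene_id,
    is_de = direction != 0L,
    direction = direction,
    true_lfc = lfc * direction
  )
  list(counts = counts, truth = truth)
}

#' Exact power-law degree histogram
#'
#' Counts exactly proportional to `k^-b` (scaled to large integers so that
#' rounding error is negligible); useful for validating exponent recovery.
#'
#' @param b Exponent, >= 0.
#' @param kmax Largest degree, >= 2.
#' @return A tibble with columns `k` (1..kmax) and `count`.
#' @export
simulate_powerlaw_histogram <- function(b, kmax) {
  if (b < 0) stop_validation("simulate_powerlaw_histogram: b must be >= 0")
  if (kmax < 2) stop_validation("simulate_powerlaw_histogram: kmax must be >= 2")
  k <- seq_len(kmax)
  tibble::tibble(k = k, count = round(1e12 * k^(-b)))
}

# small pool of common protein domains used by the generator
domain_pool <- function() {
  tibble::tibble(
    domain_acc = c("PF00069", "PF07714", "PF00096", "PF13465", "PF00023",
                   "PF12796", "PF00076", "PF00400", "PF00001", "PF00071",
                   "PF07679", "PF00036"),
    domain_name = c("Pkinase", "Pkinase_Tyr", "zf-C2H2", "zf-H2C2_2", "Ank",
                    "Ank_2", "RRM_1", "WD40", "7tm_1", "Ras",
                    "I-set", "EF-hand_1")
  )
}

#' Simulate a complete synthetic input bundle with known truth
#'
#' Generates every input the pipeline consumes — unigene FASTA with planted
#' ORFs (30% below the 30-aa retention threshold), a domtblout-style domain
#' hit table (with above-cutoff decoy rows), a tabular homology hit table,
#' a domain-interaction table, a two-sample count matrix with planted
#' differential genes at `|log2fc| = 2`, a subject-to-term map and a
#' terminal list — together with a `truth` record sufficient to score every
#' stage. Regenerating with the same seed is byte-identical.
#'
#' @param n_genes Number of unigenes (>= 20).
#' @param seed Integer bundle seed.
#' @param dir Optional directory; when given, all files plus `truth.json`
#'   are written there.
#' @return A list with tibbles `unigenes`, `domain_hits` (raw lines in
#'   `domain_hits_lines`), `blast_hits`, `ddi_table`, `counts`,
#'   `term_map`, `terminals`, the `truth` list, and (if `dir` was given)
#'   a named vector `paths`.
#' @examples
#' b <- simulate_bundle(n_genes = 25, seed = 1)
#' names(b$truth)
#' @export
simulate_bundle <- function(n_genes, seed, dir = NULL) {
  if (n_genes < 20) stop_validation("simulate_bundle: n_genes must be >= 20")

  ## --- unigenes with planted ORFs (sub-stream 101) ---
  set.seed(seed + 101L)
  ids <- ifelse(seq_len(n_genes) %% 5L == 0L,
                sprintf("CL%04d.Contig1", seq_len(n_genes)),
                sprintf("Unigene%05d", seq_len(n_genes)))
  short <- runif(n_genes) < 0.3
  orf_aa <- ifelse(short, sample(4:24, n_genes, replace = TRUE),
                   sample(30:80, n_genes, replace = TRUE))
  frames <- sample(c(1L, 2L, 3L, -1L, -2L, -3L), n_genes, replace = TRUE)
  planted <- purrr::map(seq_len(n_genes), function(i) {
    plant_orf(orf_aa[i], frames[i])
  })
  unigenes <- tibble::tibble(id = ids,
                             seq = purrr::map_chr(planted, "seq"))
  truth_orfs <- tibble::tibble(
    unigene_id = ids,
    frame = frames,
    start = purrr::map_int(planted, ~ as.integer(.x$start)),
    end = purrr::map_int(planted, ~ as.integer(.x$end)),
    protein = purrr::map_chr(planted, "protein"),
    expected = orf_aa >= 30L
  )

  ## --- domain hits (sub-stream 102) ---
  set.seed(seed + 102L)
  pool <- domain_pool()
  has_dom <- runif(n_genes) < 0.7
  assign_list <- purrr::map(seq_len(n_genes), function(i) {
    if (!has_dom[i]) return(character(0))
    sample(pool$domain_acc, sample(1:3, 1))
  })
  truth_assignments <- tibble::tibble(
    protein_id = rep(ids, lengths(assign_list)),
    domain_acc = unlist(assign_list) %||% character(0)
  ) |> dplyr::arrange(.data$protein_id, .data$domain_acc)
  mk_dom_line <- function(pid, acc, name, ev, score) {
    # domtblout column layout: target, acc, tlen, query, qacc, qlen, E, score
    sprintf("%-20s -       400 %-12s %-12s 200 %9.2g %6.1f  0.1 ... domain",
            pid, name, acc, ev, score)
  }
  dom_lines <- c("# target name  tacc tlen query name  acc  qlen  E-value  score  bias")
  for (i in which(lengths(assign_list) > 0)) {
    for (acc in assign_list[[i]]) {
      nm <- pool$domain_name[pool$domain_acc == acc]
      ver <- paste0(acc, ".", sample(1:25, 1))  # versioned accession on disk
      dom_lines <- c(dom_lines, mk_dom_line(
        ids[i], ver, nm, 10^(-runif(1, 6, 20)), runif(1, 40, 300)))
    }
  }
  # decoys above the reliable-hit cutoff; must not enter any assignment
  decoy_idx <- sample(seq_len(n_genes), max(2L, n_genes %/% 10L))
  for (i in decoy_idx) {
    acc <- sample(pool$domain_acc, 1)
    nm <- pool$domain_name[pool$domain_acc == acc]
    dom_lines <- c(dom_lines, mk_dom_line(ids[i], paste0(acc, ".3"), nm,
                                          10^(-runif(1, 1, 4)), runif(1, 5, 15)))
  }

  ## --- domain-domain interactions and true network (sub-stream 103) ---
  set.seed(seed + 103L)
  accs <- pool$domain_acc
  all_pairs <- t(utils::combn(accs, 2))
  pick <- sample(nrow(all_pairs), 10)
  self_dom <- sample(accs, 1)            # one self-interacting domain
  ddi <- tibble::tibble(
    domain_a = c(all_pairs[pick, 1], self_dom),
    domain_b = c(all_pairs[pick, 2], self_dom)
  )
  ddi$confidence <- sample(c("HC", "MC", "LC"), nrow(ddi), replace = TRUE)
  cpd <- canonical_pair(ddi$domain_a, ddi$domain_b)
  ddi$domain_a <- cpd$a
  ddi$domain_b <- cpd$b
  ddi <- dplyr::distinct(ddi, .data$domain_a, .data$domain_b, .keep_all = TRUE)
  # truth edges by explicit all-pairs scan (independent of build_network)
  dom_of <- split(truth_assignments$domain_acc, truth_assignments$protein_id)
  prots <- names(dom_of)
  ddi_key <- paste(ddi$domain_a, ddi$domain_b)
  true_edges <- list()
  if (length(prots) >= 2) {
    for (i in seq_len(length(prots) - 1)) {
      for (j in (i + 1):length(prots)) {
        hit <- FALSE
        for (a in dom_of[[i]]) {
          for (b in dom_of[[j]]) {
            if (paste(min(a, b), max(a, b)) %in% ddi_key) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) {
          true_edges[[length(true_edges) + 1L]] <-
            c(min(prots[i], prots[j]), max(prots[i], prots[j]))
        }
      }
    }
  }
  truth_edges <- if (length(true_edges)) {
    tibble::as_tibble(do.call(rbind, true_edges), .name_repair = ~ c("from", "to")) |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    tibble::tibble(from = character(), to = character())
  }

  ## --- homology hits and term map (sub-stream 104) ---
  set.seed(seed + 104L)
  subjects <- sprintf("SP%04d", 1:30)
  n_hits <- sample(0:3, n_genes, replace = TRUE)
  nb <- sum(n_hits)
  blast <- tibble::tibble(
    query_id = rep(ids, n_hits),
    subject_id = sample(subjects, nb, replace = TRUE),
    percent_identity = round(runif(nb, 30, 95), 1),
    aln_len = sample(50:400, nb, replace = TRUE),
    mismatch = sample(0:40, nb, replace = TRUE),
    gapopen = sample(0:5, nb, replace = TRUE),
    qstart = sample(1:50, nb, replace = TRUE),
    qend = sample(200:500, nb, replace = TRUE),
    sstart = sample(1:50, nb, replace = TRUE),
    send = sample(200:500, nb, replace = TRUE),
    evalue = signif(10^(-runif(nb, 3, 30)), 4),  # some rows exceed 1e-5
    bitscore = round(runif(nb, 40, 500), 1),
    subject_description = paste("hypothetical protein",
                                sample(subjects, nb, replace = TRUE))
  )
  go_terms <- tibble::tibble(
    term_id = sprintf("GO:%07d", c(8152, 5515, 46872, 6468, 7264, 5509, 3723, 16020)),
    term_name = c("metabolic process", "protein binding", "metal ion binding",
                  "protein phosphorylation", "small GTPase signaling",
                  "calcium ion binding", "RNA binding", "membrane")
  )
  term_map <- tibble::tibble(
    subject_id = rep(subjects, each = 2),
    term_id = sample(go_terms$term_id, 2 * length(subjects), replace = TRUE)
  ) |>
    dplyr::left_join(go_terms, by = "term_id") |>
    dplyr::distinct(.data$subject_id, .data$term_id, .keep_all = TRUE)

  ## --- counts with planted DE (sub-stream 105) ---
  sim <- simulate_nb_counts(n_genes, seed = seed + 105L, n_de = max(4L, n_genes %/% 10L),
                            lfc = 2, alpha = 0.05)
  counts <- sim$counts
  counts$gene_id <- ids

  ## --- terminals (sub-stream 106) ---
  set.seed(seed + 106L)
  net_nodes <- sort(unique(c(truth_edges$from, truth_edges$to)))
  terminals <- if (length(net_nodes) >= 2) {
    sort(sample(net_nodes, min(5L, length(net_nodes))))
  } else {
    character(0)
  }

  truth <- list(
    seed = seed, n_genes = n_genes,
    orfs = truth_orfs,
    assignments = truth_assignments,
    network_edges = truth_edges,
    de = dplyr::mutate(sim$truth, gene_id = ids),
    powerlaw_b = 0.872
  )
  bundle <- list(
    unigenes = unigenes,
    domain_hits_lines = dom_lines,
    blast_hits = blast,
    ddi_table = ddi,
    counts = counts,
    term_map = term_map,
    terminals = terminals,
    truth = truth
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      unigenes = file.path(dir, "unigenes.fasta"),
      domain_hits = file.path(dir, "domain_hits.domtbl"),
      blast_hits = file.path(dir, "blast_hits.tsv"),
      ddi_table = file.path(dir, "ddi.tsv"),
      counts = file.path(dir, "counts.tsv"),
      term_map = file.path(dir, "term_map.tsv"),
      terminals = file.path(dir, "terminals.txt"),
      truth = file.path(dir, "truth.json")
    )
    write_fasta(unigenes, paths[["unigenes"]])
    writeLines(dom_lines, paths[["domain_hits"]])
    readr::write_tsv(blast, paths[["blast_hits"]], col_names = FALSE)
    writeLines(paste(ddi$domain_a, ddi$domain_b, ddi$confidence, sep = "|"),
               paths[["ddi_table"]])
    readr::write_tsv(counts, paths[["counts"]])
    readr::write_tsv(term_map, paths[["term_map"]])
    writeLines(terminals, paths[["terminals"]])
    jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                         digits = NA, pretty = TRUE)
    bundle$paths <- paths
  }
  bundle
}
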