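test_that("read_fasta parses records, normalizes case, preserves order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">u1 some description", "acgt", ">u2", "NNAC", "GT"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("u1", "u2"))
  expect_equal(recs$seq, c("ACGT", "NNACGT"))
})

test_that("read_fasta rejects duplicate ids, bad alphabet, bad header", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">u1", "ACGT", ">u1", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate", class = "unitome_validation_error")
  writeLines(c(">u1", "ACGU"), fa)
  expect_error(read_fasta(fa), "alphabet|outside",
               class = "unitome_validation_error")
  writeLines(c("u1", "ACGT"), fa)
  expect_error(read_fasta(fa), "line 1", class = "unitome_parse_error")
})

test_that("FASTA writer round-trips through the reader", {
  recs <- tibble::tibble(id = c("a", "b"), seq = c("ACGTN", "GGGCCC"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  expect_equal(read_fasta(fa), recs)
})

test_that("read_domain_hits filters at the cutoff and strips versions", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# comment line",
    "prot1 -  400 Pkinase  PF00069.20 200 1e-6  55.0 0.1",
    "prot1 -  400 zf-H2C2_2 PF13465.1 200 1e-4  10.0 0.1",
    "prot2 -  400 Ank      PF00023    200 1e-10 99.0 0.1"
  ), f)
  hits <- read_domain_hits(f, evalue_cutoff = 1e-5)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$domain_acc, c("PF00069", "PF00023"))
  expect_true(all(hits$evalue < 1e-5))
})

test_that("read_domain_hits reports parse errors with line numbers", {
  f <- withr::local_tempfile()
  writeLines("prot1 - 400 Pkinase PF00069 200 not_a_number 55 0.1", f)
  expect_error(read_domain_hits(f), "line 1.*non-numeric",
               class = "unitome_parse_error")
  writeLines("prot1 only four fields x", f)
  expect_error(read_domain_hits(f), "line 1", class = "unitome_parse_error")
})

test_that("filtering at two cutoffs equals filtering at the minimum", {
  f <- withr::local_tempfile()
  set.seed(42)
  lines <- sprintf("p%02d - 400 dom PF%05d 200 %g %g 0.1",
                   1:50, sample(1:20, 50, TRUE), 10^-runif(50, 2, 12),
                   runif(50, 10, 200))
  writeLines(lines, f)
  c1 <- 1e-4; c2 <- 1e-7
  two_step <- dplyr::filter(read_domain_hits(f, c1), evalue < c2)
  one_step <- read_domain_hits(f, min(c1, c2))
  expect_equal(two_step, one_step)
})

test_that("read_blast_hits enforces the 12/13-column contract", {
  f <- withr::local_tempfile()
  row12 <- paste(c("q1", "s1", "80.5", "100", "10", "1", "1", "100",
                   "1", "100", "1e-15", "200"), collapse = "\t")
  row13 <- paste(c("q2", "s2", "60.0", "90", "20", "2", "1", "90",
                   "5", "94", "1e-3", "80", "some protein"), collapse = "\t")
  writeLines(c(row12, row13), f)
  hits <- read_blast_hits(f, evalue_cutoff = 1e-5)
  expect_equal(nrow(hits), 1L)           # the 1e-3 row is dropped
  expect_equal(hits$query_id, "q1")
  hits_all <- read_blast_hits(f, evalue_cutoff = 1)
  expect_equal(hits_all$subject_description[2], "some protein")
  writeLines("q1\ts1\tonly-three-cols", f)
  expect_error(read_blast_hits(f), "line 1", class = "unitome_parse_error")
})

test_that("empty blast file yields an empty tibble, not an error", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(read_blast_hits(f)), 0L)
})

test_that("read_ddi_table deduplicates unordered pairs and keeps self-pairs", {
  f <- withr::local_tempfile()
  writeLines(c("PF1|PF2|HC", "PF2|PF1|HC", "PF1|PF1|HC", "PF3|PF4|LC"), f)
  ddi <- read_ddi_table(f)
  expect_equal(nrow(ddi), 3L)
  expect_true(any(ddi$domain_a == "PF1" & ddi$domain_b == "PF1"))
  ddi_hc <- read_ddi_table(f, accepted_confidences = c("HC", "MC"))
  expect_equal(nrow(ddi_hc), 2L)
  writeLines("PF1|PF2", f)
  expect_error(read_ddi_table(f), "line 1", class = "unitome_parse_error")
})

test_that("assembly_stats matches the inclusive-half N50 definition", {
  recs <- tibble::tibble(id = paste0("u", 1:5), seq = strrep("A", 1:5))
  st <- assembly_stats(recs)
  expect_equal(st$n50, 4L)
  expect_equal(st$mean_length, 3L)
  expect_equal(st$total_length, 15L)
  one <- assembly_stats(tibble::tibble(id = "u", seq = strrep("G", 7)))
  expect_equal(one$n50, 7L)
  expect_equal(one$mean_length, 7L)
  expect_error(assembly_stats(tibble::tibble(id = character(), seq = character())),
               class = "unitome_validation_error")
})

test_that("at least half the total length lies in sequences >= n50", {
  # exhaustive over all length multisets of size <= 4 with lengths <= 8
  for (sz in 1:4) {
    grids <- do.call(expand.grid, rep(list(1:8), sz))
    # multisets: keep non-decreasing rows only
    keep <- apply(grids, 1, function(r) all(diff(as.numeric(r)) >= 0))
    grids <- grids[keep, , drop = FALSE]
    for (i in seq_len(nrow(grids))) {
      lens <- as.numeric(grids[i, ])
      recs <- tibble::tibble(id = paste0("s", seq_along(lens)),
                             seq = strrep("A", lens))
      n50 <- assembly_stats(recs)$n50
      expect_gte(sum(lens[lens >= n50]), sum(lens) / 2)
      expect_true(n50 %in% lens)
    }
  }
})

test_that("network writers round-trip node and edge sets in every format", {
  set.seed(7)
  g <- random_connected_graph(20, p = 0.2)
  for (fmt in c("sif", "graphml", "tsv")) {
    f <- withr::local_tempfile()
    write_network(g, f, format = fmt)
    g2 <- read_network(f, format = fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(edge_set(g2), edge_set(g))
  }
  # graph with an isolated node survives SIF and TSV
  gi <- igraph::make_empty_graph(directed = FALSE)
  gi <- igraph::add_vertices(gi, 3, name = c("A", "B", "Z"))
  gi <- igraph::add_edges(gi, c(1, 2))
  for (fmt in c("sif", "tsv", "graphml")) {
    f <- withr::local_tempfile()
    write_network(gi, f, format = fmt)
    g2 <- read_network(f, format = fmt)
    expect_setequal(igraph::V(g2)$name, c("A", "B", "Z"))
    expect_equal(edge_set(g2), edge_set(gi))
  }
  expect_error(write_network(g, tempfile(), format = "dot"),
               "unknown", class = "unitome_validation_error")
})

test_that("SIF output uses the 'interacts' relation", {
  g <- igraph::make_graph(~ A - B)
  f <- withr::local_tempfile()
  write_network(g, f, format = "sif")
  expect_equal(readLines(f), "A interacts B")
})
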