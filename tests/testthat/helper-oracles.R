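# Independent oracles used across the suite. Each takes a deliberately
# different computational route from the implementation it checks.

# random nucleotide sequence
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- ORF oracle: Biostrings translation + regex run extraction -------------
oracle_six_frame <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  res <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      src <- if (strand == 1L) s else rc
      ncod <- (L - (f - 1L)) %/% 3L
      if (ncod < 1L) next
      sub <- substr(src, f, f - 1L + 3L * ncod)
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)))
      runs <- gregexpr("[^*]+", aa)[[1]]
      if (runs[1] == -1L) next
      lens <- attr(runs, "match.length")
      for (i in seq_along(runs)) {
        c1 <- as.integer(runs[i])           # 1-based codon index
        start <- (f - 1L) + 3L * (c1 - 1L)  # 0-based on strand
        end <- start + 3L * lens[i]
        if (strand == -1L) {
          tmp <- L - end; end <- L - start; start <- tmp
        }
        res[[length(res) + 1L]] <- tibble::tibble(
          frame = strand * f, start = start, end = end,
          protein = substr(aa, c1, c1 + lens[i] - 1L))
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble::tibble(frame = integer(), start = integer(),
                          end = integer(), protein = character())
  }
  dplyr::arrange(out, frame, start)
}

# --- Fisher oracle: explicit binomial-coefficient enumeration --------------
oracle_fisher <- function(a, b, c, d, sided = "two.sided") {
  m <- a + b; n2 <- c + d; k <- a + c
  x <- max(0, k - n2):min(k, m)
  prob <- choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  obs <- prob[match(a, x)]
  if (sided == "greater") sum(prob[x >= a]) else sum(prob[prob <= obs * (1 + 1e-7)])
}

# --- BH oracle: literal step-up rule ---------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# --- BFS oracle: hand-rolled queue over an edge list -----------------------
oracle_bfs_distances <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dmat <- matrix(NA_integer_, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (src in nodes) {
    dist <- setNames(rep(NA_integer_, length(nodes)), nodes)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          queue <- c(queue, v)
        }
      }
    }
    dmat[src, ] <- dist
  }
  dmat
}

# unordered-pair shortest-path histogram from the BFS oracle
oracle_path_histogram <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  dmat <- oracle_bfs_distances(nodes, el)
  d <- dmat[upper.tri(dmat)]
  d <- d[!is.na(d) & d > 0]
  tibble::tibble(distance = as.integer(names(table(d))),
                 count = as.numeric(table(d)))
}

# --- all-pairs DDI network oracle ------------------------------------------
oracle_network_edges <- function(assignments, ddis) {
  dom_of <- split(assignments$domain_acc, assignments$protein_id)
  prots <- sort(names(dom_of))
  key <- paste(pmin(ddis$domain_a, ddis$domain_b),
               pmax(ddis$domain_a, ddis$domain_b))
  out <- list()
  if (length(prots) >= 2) {
    for (i in seq_len(length(prots) - 1)) {
      for (j in (i + 1):length(prots)) {
        pairs <- expand.grid(a = dom_of[[prots[i]]], b = dom_of[[prots[j]]],
                             stringsAsFactors = FALSE)
        if (any(paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b)) %in% key)) {
          out[[length(out) + 1L]] <- c(prots[i], prots[j])
        }
      }
    }
  }
  if (!length(out)) return(tibble::tibble(from = character(), to = character()))
  el <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(from = pmin(el[, 1], el[, 2]),
                                to = pmax(el[, 1], el[, 2])), from, to)
}

# canonical sorted edge tibble of an igraph, for set comparison
edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(el)) return(tibble::tibble(from = character(), to = character()))
  dplyr::arrange(tibble::tibble(from = pmin(el[, 1], el[, 2]),
                                to = pmax(el[, 1], el[, 2])), from, to)
}

# --- exhaustive Steiner minimal tree oracle --------------------------------
# minimum number of edges of any connected subgraph spanning the terminals
oracle_steiner_edges <- function(g, terminals) {
  nodes <- igraph::V(g)$name
  others <- setdiff(nodes, terminals)
  for (extra in 0:length(others)) {
    size <- length(terminals) + extra
    combos <- if (extra == 0) {
      matrix(character(0), nrow = 0, ncol = 0)
    } else {
      utils::combn(others, extra)
    }
    n_combo <- if (extra == 0) 1L else ncol(combos)
    for (ci in seq_len(n_combo)) {
      subset <- if (extra == 0) terminals else c(terminals, combos[, ci])
      sub <- igraph::induced_subgraph(g, subset)
      if (igraph::is_connected(sub)) return(size - 1L)
    }
  }
  Inf  # terminals not connectable
}

# random connected named graph on n nodes
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(n)))
}
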