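asn_tbl <- function(...) {
  x <- list(...)
  tibble::tibble(protein_id = rep(names(x), lengths(x)),
                 domain_acc = unlist(x, use.names = FALSE))
}

ddi_tbl <- function(pairs) {
  tibble::tibble(domain_a = vapply(pairs, `[[`, "", 1),
                 domain_b = vapply(pairs, `[[`, "", 2),
                 confidence = "HC")
}

test_that("build_network connects proteins through interacting domains", {
  net <- build_network(asn_tbl(p = "PF1", q = "PF2"),
                       ddi_tbl(list(c("PF1", "PF2"))))
  expect_equal(edge_set(net), tibble::tibble(from = "p", to = "q"))
  # self-interacting domain connects two proteins but adds no self-loop
  net2 <- build_network(asn_tbl(p = "PF1", q = "PF1"),
                        ddi_tbl(list(c("PF1", "PF1"))))
  expect_equal(edge_set(net2), tibble::tibble(from = "p", to = "q"))
  expect_equal(sum(igraph::which_loop(net2)), 0L)
  # a protein alone with a self-interacting domain yields no node
  net3 <- build_network(asn_tbl(p = "PF1"), ddi_tbl(list(c("PF1", "PF1"))))
  expect_equal(igraph::vcount(net3), 0L)
})

test_that("build_network equals the all-pairs oracle on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    doms <- sprintf("PF%03d", 1:10)
    asn <- tibble::tibble(
      protein_id = rep(sprintf("p%02d", 1:30), each = 2),
      domain_acc = sample(doms, 60, replace = TRUE)
    ) |> dplyr::distinct()
    pair_idx <- t(utils::combn(length(doms), 2))
    sel <- pair_idx[sample(nrow(pair_idx), 12), ]
    ddis <- tibble::tibble(domain_a = doms[sel[, 1]], domain_b = doms[sel[, 2]],
                           confidence = "HC")
    got <- edge_set(build_network(asn, ddis))
    want <- oracle_network_edges(asn, ddis)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("edge set grows monotonically as DDIs are added", {
  set.seed(42)
  doms <- sprintf("PF%03d", 1:8)
  asn <- tibble::tibble(protein_id = rep(sprintf("p%02d", 1:15), each = 2),
                        domain_acc = sample(doms, 30, replace = TRUE))
  pair_idx <- t(utils::combn(8, 2))
  ddis <- tibble::tibble(domain_a = doms[pair_idx[, 1]],
                         domain_b = doms[pair_idx[, 2]], confidence = "HC")
  prev <- tibble::tibble(from = character(), to = character())
  for (k in c(3, 8, 14, 20, 28)) {
    cur <- edge_set(build_network(asn, ddis[seq_len(k), ]))
    expect_true(all(paste(prev$from, prev$to) %in% paste(cur$from, cur$to)))
    prev <- cur
  }
})

test_that("topology of a 4-cycle matches hand evaluation", {
  g <- igraph::make_ring(4)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:4])
  # regular graph: degree distribution has one support point, so no
  # power-law exponent can be fitted
  expect_warning(rep <- topology_report(g), "support points")
  expect_true(is.na(rep$powerlaw_b))
  expect_equal(rep$nodes$degree, rep(2L, 4))
  expect_equal(as.data.frame(rep$shortest_path_histogram),
               data.frame(distance = c(1L, 2L), count = c(4, 2)))
  expect_equal(rep$nodes$topological_coefficient, rep(1, 4))
  expect_equal(rep$mean_degree, 2)
})

test_that("betweenness on a 3-node path puts all load on the middle", {
  g <- igraph::make_graph(~ a - b, b - c)
  rep <- topology_report(g)
  btw <- setNames(rep$nodes$betweenness, rep$nodes$node)
  expect_equal(unname(btw["b"]), 1)
  expect_equal(unname(btw["a"]), 0)
  expect_equal(unname(btw["c"]), 0)
  # normalization flag divides by (n-1)(n-2)/2
  repn <- topology_report(g, normalized_betweenness = TRUE)
  expect_equal(max(repn$nodes$betweenness), 1)
})

test_that("degree histogram satisfies the handshake lemma and node count", {
  set.seed(43)
  for (rep_i in 1:5) {
    g <- random_connected_graph(sample(10:40, 1), p = 0.2)
    tr <- topology_report(g)
    expect_equal(sum(tr$degree_histogram$count), igraph::vcount(g))
    expect_equal(sum(tr$degree_histogram$k * tr$degree_histogram$count),
                 2 * igraph::ecount(g))
  }
  expect_error(topology_report(igraph::make_empty_graph(directed = FALSE)),
               class = "unitome_validation_error")
})

test_that("shortest-path histogram equals an all-pairs BFS oracle", {
  set.seed(44)
  for (rep_i in 1:8) {
    g <- random_connected_graph(sample(10:50, 1), p = 0.15)
    tr <- topology_report(g)
    expect_equal(as.data.frame(tr$shortest_path_histogram),
                 as.data.frame(oracle_path_histogram(g)))
  }
})

test_that("power-law fit recovers generating exponents exactly", {
  h2 <- simulate_powerlaw_histogram(b = 2, kmax = 50)
  expect_equal(fit_power_law(h2)$b, 2, tolerance = 1e-9)
  h <- simulate_powerlaw_histogram(b = 0.872, kmax = 100)
  expect_equal(fit_power_law(h)$b, 0.872, tolerance = 1e-6)
  flat <- tibble::tibble(k = 1:20, count = 1000)
  expect_equal(fit_power_law(flat)$b, 0, tolerance = 1e-12)
  expect_error(fit_power_law(tibble::tibble(k = 3, count = 10)),
               class = "unitome_validation_error")
  expect_error(fit_power_law(tibble::tibble(k = c(0, 1), count = 10)),
               class = "unitome_validation_error")
  # MLE variant lands near the same exponent on exact input
  expect_equal(fit_power_law(h, method = "mle")$b, 0.872, tolerance = 1e-2)
})

test_that("hub ranking is by degree with id tie-breaks", {
  g <- igraph::make_star(6, mode = "undirected", center = 1)
  g <- igraph::set_vertex_attr(g, "name", value = c("hub", letters[1:5]))
  expect_equal(find_hubs(g, 1)$node, "hub")
  expect_equal(nrow(find_hubs(g, 5)), 5L)
  set.seed(45)
  for (rep_i in 1:5) {
    gr <- random_connected_graph(sample(8:20, 1), p = 0.3)
    hubs <- find_hubs(gr, 4)
    deg <- igraph::degree(gr)
    ord <- order(-deg, igraph::V(gr)$name)
    expect_equal(hubs$node, igraph::V(gr)$name[ord][1:4])
  }
})

test_that("steiner extraction on hand-built graphs", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  res <- steiner_subnetwork(path3, c("a", "c"))
  expect_equal(sort(res$steiner_nodes), "b")
  expect_equal(igraph::ecount(res$tree), 2)
  star <- igraph::make_graph(~ h - x, h - y, h - z)
  res2 <- steiner_subnetwork(star, c("x", "y"))
  expect_equal(edge_set(res2$tree),
               tibble::tibble(from = c("h", "h"), to = c("x", "y")))
  # a tree input with all nodes terminal is returned whole
  tr <- igraph::make_tree(7, children = 2, mode = "undirected")
  tr <- igraph::set_vertex_attr(tr, "name", value = paste0("n", 1:7))
  res3 <- steiner_subnetwork(tr, paste0("n", 1:7))
  expect_equal(edge_set(res3$tree), edge_set(tr))
  # missing terminals are dropped with a warning; all-missing errors
  expect_warning(steiner_subnetwork(path3, c("a", "c", "zz")), "absent")
  expect_error(suppressWarnings(steiner_subnetwork(path3, "zz")),
               class = "unitome_validation_error")
})

test_that("disconnected terminal groups yield a forest with a warning", {
  g <- igraph::make_graph(~ a - b, c - d)
  expect_warning(res <- steiner_subnetwork(g, c("a", "b", "c", "d")),
                 "components")
  expect_equal(res$n_trees, 2L)
  expect_equal(igraph::ecount(res$tree), 2)
})

test_that("heuristic Steiner cost stays within 2x the exhaustive optimum", {
  set.seed(46)
  for (rep_i in 1:40) {
    n <- sample(5:7, 1)
    g <- random_connected_graph(n, p = runif(1, 0.3, 0.7))
    terms <- sample(igraph::V(g)$name, 3)
    res <- suppressWarnings(steiner_subnetwork(g, terms))
    opt <- oracle_steiner_edges(g, terms)
    expect_lte(igraph::ecount(res$tree), 2 * opt)
    # result spans all terminals
    expect_true(all(terms %in% igraph::V(res$tree)$name))
    expect_equal(igraph::ecount(res$tree),
                 igraph::vcount(res$tree) - res$n_trees)  # acyclic forest
  }
})
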