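# Domain-interaction-based protein-protein network inference and topology.
#
# Two proteins are connected when at least one of the first protein's
# domains is known to interact with one of the second's. The resulting
# graph is simple: self-loops are excluded (a self-interacting domain does
# not connect a protein to itself) and multiple supporting domain pairs
# collapse into one edge carrying all of them as evidence.

#' Build a protein-protein interaction network from domain interactions
#'
#' An edge `p -- q` (with `p != q`) exists iff some domain of `p` interacts
#' with some domain of `q` according to the supplied domain-domain
#' interaction table (unordered pairs; self-interacting domains connect two
#' *different* proteins that both carry the domain). Nodes are the proteins
#' participating in at least one edge.
#'
#' @param assignments A tibble of protein-domain assignments from
#'   [assign_domains()] (columns `protein_id`, `domain_acc`, unversioned).
#' @param ddis A tibble of domain interactions from [read_ddi_table()]
#'   (columns `domain_a`, `domain_b`).
#' @return An undirected [igraph::igraph] with vertex attribute `name` and
#'   edge attribute `evidence` (comma-separated `PFa:PFb` domain pairs).
#' @export
build_network <- function(assignments, ddis) {
  stopifnot(is.data.frame(assignments), is.data.frame(ddis))
  pd <- dplyr::distinct(assignments, .data$protein_id, .data$domain_acc)
  cp <- canonical_pair(ddis$domain_a, ddis$domain_b)
  dd <- dplyr::distinct(tibble::tibble(domain_a = cp$a, domain_b = cp$b))
  if (!nrow(pd) || !nrow(dd)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  half1 <- dd |>
    dplyr::inner_join(pd, by = c(domain_a = "domain_acc"),
                      relationship = "many-to-many") |>
    dplyr::rename(p = "protein_id") |>
    dplyr::inner_join(pd, by = c(domain_b = "domain_acc"),
                      relationship = "many-to-many") |>
    dplyr::rename(q = "protein_id")
  pairs <- half1 |>
    dplyr::filter(.data$p != .data$q) |>
    dplyr::mutate(from = pmin(.data$p, .data$q), to = pmax(.data$p, .data$q),
                  pair = paste0(.data$domain_a, ":", .data$domain_b)) |>
    dplyr::distinct(.data$from, .data$to, .data$pair)
  if (!nrow(pairs)) return(igraph::make_empty_graph(directed = FALSE))
  edges <- pairs |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(evidence = paste(sort(unique(.data$pair)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Topological analysis of an interaction network
#'
#' Computes the degree histogram, mean degree, a log-log least-squares
#' power-law exponent for the degree distribution, the unordered
#' shortest-path length histogram (unweighted breadth-first distances,
#' reachable pairs only), per-node topological coefficients, and
#' (unnormalized by default) shortest-path betweenness.
#'
#' The topological coefficient of node `n` with degree `k_n` is the mean,
#' over all nodes `m` sharing at least one neighbor with `n`, of
#' `J(n,m)/k_n`, where `J(n,m)` is the number of shared neighbors plus one
#' if `n` and `m` are adjacent. Nodes sharing neighbors with no other node
#' get coefficient 0.
#'
#' @param network An [igraph::igraph], e.g. from [build_network()].
#' @param normalized_betweenness If `TRUE`, betweenness is divided by
#'   `(n-1)(n-2)/2`; default `FALSE` (raw pair counts).
#' @return An object of class `topology_report`: a list with tibbles
#'   `nodes` (`node`, `degree`, `topological_coefficient`, `betweenness`),
#'   `degree_histogram` (`k`, `count`), `shortest_path_histogram`
#'   (`distance`, `count`), and scalars `mean_degree`, `powerlaw_b`,
#'   `n_nodes`, `n_edges`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
topology_report <- function(network, normalized_betweenness = FALSE) {
  stopifnot(igraph::is_igraph(network))
  nv <- igraph::vcount(network)
  if (nv < 2L) stop_validation("topology_report: need at least 2 nodes")
  deg <- igraph::degree(network)
  dh <- tibble::tibble(k = as.integer(names(table(deg))),
                       count = as.integer(table(deg)))
  # handshake lemma sanity check
  stopifnot(sum(dh$k * dh$count) == 2L * igraph::ecount(network))
  b <- tryCatch(
    fit_power_law(dplyr::filter(dh, .data$k >= 1L))$b,
    error = function(e) {
      warn("degree distribution has < 2 support points; powerlaw_b is NA")
      NA_real_
    }
  )
  dt <- igraph::distance_table(network, directed = FALSE)$res
  sph <- tibble::tibble(distance = seq_along(dt), count = dt) |>
    dplyr::filter(.data$count > 0)
  btw <- igraph::betweenness(network, directed = FALSE,
                             normalized = normalized_betweenness)
  tc <- topological_coefficients(network)
  nodes <- tibble::tibble(
    node = igraph::V(network)$name %||% as.character(seq_len(nv)),
    degree = as.integer(deg),
    topological_coefficient = tc,
    betweenness = unname(btw)
  )
  structure(
    list(nodes = nodes, degree_histogram = dh,
         shortest_path_histogram = sph,
         mean_degree = mean(deg), powerlaw_b = b,
         n_nodes = nv, n_edges = igraph::ecount(network)),
    class = "topology_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

topological_coefficients <- function(network) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A@x[] <- 1
  shared <- A %*% A            # shared[n,m] = number of common neighbors
  J <- shared + A              # +1 when adjacent
  nv <- nrow(A)
  deg <- Matrix::rowSums(A)
  vapply(seq_len(nv), function(i) {
    s <- shared[i, ]
    m <- which(s >= 1)
    m <- m[m != i]
    if (!length(m) || deg[i] == 0) return(0)
    mean(J[i, m]) / deg[i]
  }, 1.0)
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("Topology report: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  mean degree %.3f; power-law exponent b = %.4g\n",
              x$mean_degree, x$powerlaw_b))
  cat(sprintf("  shortest-path mode at distance %d\n",
              x$shortest_path_histogram$distance[
                which.max(x$shortest_path_histogram$count)]))
  invisible(x)
}

#' @export
tidy.topology_report <- function(x, ...) x$nodes

#' @export
glance.topology_report <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
                 mean_degree = x$mean_degree, powerlaw_b = x$powerlaw_b)
}

#' Fit a power-law exponent to a degree histogram
#'
#' The degree distribution `P(k) = count(k) / sum(count)` is modelled as
#' `P(k) ~ k^-b`. The default estimator is the negated slope of the
#' least-squares line of `log10 P(k)` on `log10 k` over degrees with
#' nonzero count (the estimator used by common network-analysis GUI
#' plugins); `method = "mle"` instead maximizes the discrete power-law
#' likelihood over the observed support.
#'
#' @param degree_histogram A data frame with columns `k` (>= 1) and
#'   `count`.
#' @param method `"ls"` (default) or `"mle"`.
#' @return A list with elements `b` (exponent, >= 0 data permitting),
#'   `method`, and for `"ls"` the `intercept` of the log-log fit.
#' @examples
#' h <- simulate_powerlaw_histogram(b = 2, kmax = 50)
#' fit_power_law(h)$b  # 2
#' @export
fit_power_law <- function(degree_histogram, method = c("ls", "mle")) {
  method <- match.arg(method)
  h <- dplyr::filter(tibble::as_tibble(degree_histogram), .data$count > 0)
  if (any(h$k < 1)) stop_validation("fit_power_law: degrees must be >= 1")
  if (length(unique(h$k)) < 2L) {
    stop_validation("fit_power_law: need >= 2 distinct degrees with nonzero count")
  }
  if (method == "ls") {
    P <- h$count / sum(h$count)
    fit <- lm(log10(P) ~ log10(h$k))
    list(b = -unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         method = "ls")
  } else {
    ks <- h$k
    n <- h$count
    support <- seq(min(ks), max(ks))
    nll <- function(b) {
      b * sum(n * log(ks)) + sum(n) * log(sum(support^(-b)))
    }
    opt <- optimize(nll, interval = c(0, 20))
    list(b = opt$minimum, method = "mle")
  }
}

#' Highest-degree (hub) nodes
#'
#' @param network An [igraph::igraph].
#' @param n Number of hubs to return (default 5); fewer if the network is
#'   smaller.
#' @return A tibble with columns `node`, `degree`, descending by degree
#'   with ties broken by ascending node id.
#' @export
find_hubs <- function(network, n = 5) {
  stopifnot(igraph::is_igraph(network))
  if (n < 1) stop_validation("find_hubs: n must be >= 1")
  deg <- igraph::degree(network)
  tb <- tibble::tibble(
    node = igraph::V(network)$name %||% as.character(seq_along(deg)),
    degree = as.integer(deg)
  )
  tb |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node) |>
    head(min(n, nrow(tb)))
}
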