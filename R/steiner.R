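# Steiner-tree subnetwork extraction by the shortest-path heuristic
# (Takahashi-Matsuyama): grow a tree from the smallest-id terminal,
# repeatedly attaching the closest remaining terminal via one of its
# shortest paths to the current tree. Unit edge weights; deterministic
# tie-breaking by node id. The heuristic is a 2(1 - 1/|T|)-approximation
# of the NP-hard Steiner minimal tree.

#' Extract a minimal subnetwork connecting a set of seed genes
#'
#' Maps the terminals onto the network (absent ids are dropped with a
#' warning), then grows, per connected component holding at least one found
#' terminal, a Steiner tree by the shortest-path heuristic. Disconnected
#' terminal groups yield a forest, one tree per component.
#'
#' @param network An [igraph::igraph] with named vertices.
#' @param terminals Character vector of seed node ids (non-empty).
#' @return An object of class `steiner_subnetwork`: a list with
#'   `terminals_found`, `terminals_missing`, `tree` (an igraph forest),
#'   `steiner_nodes` (non-terminal nodes recruited), `hubs` (top-degree
#'   nodes of the subnetwork, from [find_hubs()]), and `n_trees`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' res <- steiner_subnetwork(g, c("a", "c"))
#' res$steiner_nodes  # "b"
#' @export
steiner_subnetwork <- function(network, terminals) {
  stopifnot(igraph::is_igraph(network))
  if (length(terminals) == 0L) {
    stop_validation("steiner_subnetwork: terminals must be non-empty")
  }
  terminals <- unique(as.character(terminals))
  nodes <- igraph::V(network)$name
  missing <- setdiff(terminals, nodes)
  found <- intersect(terminals, nodes)
  if (!length(found)) {
    stop_validation(paste0("no terminal present in network; missing: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    warn(paste0("dropping ", length(missing),
                " terminal(s) absent from the network: ",
                paste(missing, collapse = ", ")))
  }
  comp <- igraph::components(network)
  memb <- comp$membership[found]
  groups <- split(found, memb)
  if (length(groups) > 1L) {
    warn(paste0("terminals span ", length(groups),
                " components; returning a forest"))
  }
  tree_edges <- matrix(character(0), ncol = 2)
  for (grp in groups) {
    tree_edges <- rbind(tree_edges, grow_tree(network, sort(grp)))
  }
  tree <- igraph::make_empty_graph(directed = FALSE)
  tree_nodes <- sort(unique(c(as.vector(tree_edges), found)))
  tree <- igraph::add_vertices(tree, length(tree_nodes), name = tree_nodes)
  if (nrow(tree_edges)) {
    idx <- matrix(match(tree_edges, tree_nodes), ncol = 2)
    tree <- igraph::add_edges(tree, as.vector(t(idx)))
  }
  structure(
    list(terminals_found = sort(found), terminals_missing = sort(missing),
         tree = tree,
         steiner_nodes = sort(setdiff(tree_nodes, found)),
         hubs = find_hubs(tree, 5),
         n_trees = length(groups)),
    class = "steiner_subnetwork"
  )
}

# grow one Takahashi-Matsuyama tree over terminals `grp` (all in one
# component); returns a 2-column character matrix of edges
grow_tree <- function(network, grp) {
  in_tree <- grp[1]                      # seed: smallest terminal id
  remaining <- setdiff(grp, in_tree)
  edges <- matrix(character(0), ncol = 2)
  while (length(remaining)) {
    d <- igraph::distances(network, v = remaining, to = in_tree)
    # closest remaining terminal; ties by terminal id (rows are sorted)
    best_t <- remaining[order(apply(d, 1, min), remaining)][1]
    dt <- d[match(best_t, remaining), , drop = TRUE]
    # nearest tree node; ties by node id
    targets <- in_tree[dt == min(dt)]
    target <- sort(targets)[1]
    path <- igraph::shortest_paths(network, from = best_t, to = target,
                                   output = "vpath")$vpath[[1]]
    pnames <- igraph::as_ids(path)
    if (length(pnames) > 1L) {
      edges <- rbind(edges, cbind(pnames[-length(pnames)], pnames[-1]))
    }
    in_tree <- unique(c(in_tree, pnames))
    remaining <- setdiff(remaining, pnames)
  }
  edges
}

#' @export
print.steiner_subnetwork <- function(x, ...) {
  cat(sprintf(
    "Steiner subnetwork: %d terminals spanned (+%d Steiner nodes), %d edges in %d tree(s)\n",
    length(x$terminals_found), length(x$steiner_nodes),
    igraph::ecount(x$tree), x$n_trees))
  if (length(x$terminals_missing)) {
    cat(sprintf("  %d terminal(s) not in network\n", length(x$terminals_missing)))
  }
  invisible(x)
}

#' @export
tidy.steiner_subnetwork <- function(x, ...) {
  el <- igraph::as_edgelist(x$tree, names = TRUE)
  tibble::tibble(from = el[, 1], to = el[, 2])
}

#' @export
glance.steiner_subnetwork <- function(x, ...) {
  tibble::tibble(n_terminals = length(x$terminals_found),
                 n_steiner_nodes = length(x$steiner_nodes),
                 n_edges = igraph::ecount(x$tree),
                 n_trees = x$n_trees,
                 n_missing = length(x$terminals_missing))
}

#' Read a terminal (seed gene) list
#'
#' Plain text, one node id per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of node ids.
#' @export
read_terminals <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
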