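#' Write an interaction network to an interchange format
#'
#' Supported formats: `"sif"` (Cytoscape simple interaction format, one
#' `A interacts B` line per edge, isolated nodes as bare-name lines),
#' `"graphml"`, and `"tsv"` (two-column `from`/`to` edge list with header;
#' isolated nodes are written with an empty `to` field so that the node set
#' round-trips).
#'
#' @param network An [igraph::igraph] object, e.g. from [build_network()].
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_network()] for the inverse operation.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(igraph::is_igraph(network))
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("sif", "graphml", "tsv")) {
    stop_validation(paste0("unknown network format: '", format, "'"))
  }
  format <- match.arg(format)
  nodes <- igraph::V(network)$name
  el <- igraph::as_edgelist(network, names = TRUE)
  if (format == "sif") {
    edge_lines <- if (nrow(el)) paste(el[, 1], "interacts", el[, 2]) else character()
    isolated <- setdiff(nodes, unique(c(el[, 1], el[, 2])))
    writeLines(c(edge_lines, isolated), path)
  } else if (format == "tsv") {
    isolated <- setdiff(nodes, unique(c(el[, 1], el[, 2])))
    lines <- c("from\tto",
               if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(),
               if (length(isolated)) paste0(isolated, "\t") else character())
    writeLines(lines, path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' Read an interaction network written by [write_network()]
#'
#' @param path Input file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return An [igraph::igraph] object with vertex attribute `name`.
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("sif", "graphml", "tsv")) {
    stop_validation(paste0("unknown network format: '", format, "'"))
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::simplify(igraph::as_undirected(g, mode = "collapse")))
  }
  lines <- readLines(path)
  if (format == "tsv" && length(lines)) lines <- lines[-1]  # header
  lines <- lines[nzchar(trimws(lines))]
  split_re <- if (format == "sif") "\\s+" else "\t"
  fields <- strsplit(lines, split_re)
  edges <- character(0)
  singles <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]][nzchar(fields[[i]])]
    if (length(f) == 1L) {
      singles <- c(singles, f)
    } else if (format == "sif") {
      if (length(f) < 3L) stop_parse(paste0("line ", i, ": malformed SIF line"))
      edges <- c(edges, f[1], f[3])
    } else {
      edges <- c(edges, f[1], f[2])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  all_nodes <- unique(c(edges, singles))
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (length(edges)) g <- igraph::add_edges(g, match(edges, all_nodes))
  igraph::simplify(g)
}
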