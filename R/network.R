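#' Social network of community members
#'
#' A `social_network` is a simple undirected graph over a fixed set of
#' individuals, stored as an [igraph][igraph::igraph-package] graph together
#' with generation provenance: the community-structure label (degree-skew
#' preset) and the generator seed, when known.
#'
#' Invariants enforced at construction: no self-loops, no duplicate edges,
#' every degree in `[0, n - 1]`.
#'
#' @param edges two-column integer matrix of 1-based node indices, one row per
#'   undirected edge. May have zero rows.
#' @param n_nodes number of individuals in the community.
#' @param structure_label one of `"light"`, `"moderate"`, `"high"` for the
#'   degree-skew presets, or `"custom"`.
#' @param generator_seed integer seed the network was generated from, or `NA`.
#'
#' @return an object of class `social_network`.
#' @examples
#' net <- social_network(rbind(c(1, 2), c(2, 3)), n_nodes = 3)
#' degree_sequence(net)
#' @export
social_network <- function(edges, n_nodes,
                           structure_label = "custom",
                           generator_seed = NA_integer_) {
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop("'n_nodes' must be a single positive integer")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints must be node indices in [1, n_nodes]")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed in a social_network")
    key <- edge_key(edges, n_nodes)
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed in a social_network")
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  structure(
    list(graph = g,
         structure_label = as.character(structure_label),
         generator_seed = generator_seed),
    class = "social_network"
  )
}

# canonical key of an undirected edge, used for duplicate detection
edge_key <- function(edges, n) {
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  (a - 1) * n + (b - 1)
}

#' @rdname social_network
#' @param x,net a `social_network`.
#' @export
is_social_network <- function(x) inherits(x, "social_network")

#' @rdname social_network
#' @export
node_count <- function(net) {
  stopifnot(is_social_network(net))
  as.integer(igraph::vcount(net$graph))
}

#' @rdname social_network
#' @export
edge_count <- function(net) {
  stopifnot(is_social_network(net))
  as.integer(igraph::ecount(net$graph))
}

#' @rdname social_network
#' @return `degree_sequence()`: integer vector of per-node degrees (numbers of
#'   direct social contacts).
#' @export
degree_sequence <- function(net) {
  stopifnot(is_social_network(net))
  as.integer(igraph::degree(net$graph))
}

#' @rdname social_network
#' @export
edge_matrix <- function(net) {
  stopifnot(is_social_network(net))
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

#' @rdname social_network
#' @return `adjacency_matrix()`: dense numeric 0/1 adjacency matrix.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(is_social_network(net))
  as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = FALSE))
}

#' @rdname social_network
#' @export
as_igraph <- function(net) {
  stopifnot(is_social_network(net))
  net$graph
}

#' @rdname social_network
#' @export
is_connected_network <- function(net) {
  stopifnot(is_social_network(net))
  igraph::is_connected(net$graph)
}

#' @export
print.social_network <- function(x, ...) {
  deg <- degree_sequence(x)
  cat(sprintf("<social_network> %d individuals, %d ties (structure: %s)\n",
              node_count(x), edge_count(x), x$structure_label))
  if (!is.na(x$generator_seed))
    cat(sprintf("  generator seed: %d\n", as.integer(x$generator_seed)))
  if (length(deg) > 0)
    cat(sprintf("  degree range: [%d, %d], mean %.2f\n",
                min(deg), max(deg), mean(deg)))
  invisible(x)
}

#' Read and write social networks
#'
#' Networks are serialised either as a plain edge list (two whitespace-
#' separated integer columns of 0-based node indices, preceded by a
#' `# nodes: <n>` comment line so that isolated nodes survive the round trip)
#' or as GraphML. Both round-trips are lossless for node count and edge set.
#'
#' @param net a [social_network].
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`; inferred from the file extension
#'   (`.graphml` vs anything else) when missing.
#' @return `write_network()` returns `path` invisibly; `read_network()` returns
#'   a [social_network].
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(is_social_network(net))
  format <- resolve_format(path, format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    el <- edge_matrix(net)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes: %d", node_count(net)), con)
    if (nrow(el) > 0)
      writeLines(sprintf("%d %d", el[, 1] - 1L, el[, 2] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @param structure_label,generator_seed provenance attached to the
#'   reconstructed network (the edge-list format does not carry them).
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         structure_label = "custom",
                         generator_seed = NA_integer_) {
  format <- resolve_format(path, format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = FALSE)
    storage.mode(el) <- "integer"
    return(social_network(el, igraph::vcount(g),
                          structure_label = structure_label,
                          generator_seed = generator_seed))
  }
  lines <- readLines(path)
  header <- grep("^#\\s*nodes:", lines, value = TRUE)
  if (length(header) != 1L)
    stop("malformed edge-list file: missing '# nodes: <n>' header in ", path)
  n <- as.integer(sub("^#\\s*nodes:\\s*", "", header[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0)
      stop(sprintf("malformed edge-list line %d in %s: '%s'",
                   bad[1], path, body[bad[1]]))
    edges <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE) + 1L
    if (anyNA(edges))
      stop("malformed edge-list file: non-integer endpoint in ", path)
  }
  social_network(edges, n, structure_label = structure_label,
                 generator_seed = generator_seed)
}

resolve_format <- function(path, format) {
  if (length(format) > 1L)
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  match.arg(format, c("edgelist", "graphml"))
}
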