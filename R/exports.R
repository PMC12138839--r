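#' Write a distance matrix as CSV
#'
#' Square CSV with attributes as both header row and first column.
#'
#' @param m symmetric matrix (or `warpnet_distances`, whose group matrix is
#'   written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(m, path) {
  if (inherits(m, "warpnet_distances")) m <- dist_matrix(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_csv()]
#'
#' @param path CSV file path.
#' @return A symmetric numeric matrix.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write the dendrogram as Newick text
#'
#' Merge heights become branch lengths, so the tree can be rendered by any
#' phylogenetics viewer.
#'
#' @param clusters a `warpnet_clusters` object (or an `hclust`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  tree <- if (inherits(clusters, "warpnet_clusters")) clusters$hclust else clusters
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Undirected edge tables (from [undirected_network()]) become an
#' undirected graph with `weight`, `sign`, and `edge_color` attributes and
#' node-level `cluster`; directed edge tables (from
#' [test_directed_edges()], significant rows only) become a directed graph
#' with `weight` (mean delta) and `p_value`.
#'
#' @param edges an edge tibble with `from`, `to` columns.
#' @param path output file path.
#' @param directed write a directed graph.
#' @param nodes optional tibble of node metadata (column `attribute` or
#'   `node` plus annotation columns).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(edges, path, directed = FALSE,
                                  nodes = NULL) {
  g <- edges_to_igraph(edges, directed = directed, nodes = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

edges_to_igraph <- function(edges, directed = FALSE, nodes = NULL) {
  edf <- as.data.frame(edges)
  if (!is.null(nodes)) {
    ndf <- as.data.frame(nodes)
    names(ndf)[1] <- "name"
    extra <- setdiff(unique(c(edf$from, edf$to)), ndf$name)
    if (length(extra) > 0) {
      ndf <- dplyr::bind_rows(ndf, data.frame(name = extra))
    }
    # igraph vertex attributes cannot hold factors cleanly
    ndf[] <- lapply(ndf, function(col) if (is.factor(col)) as.character(col) else col)
  } else {
    ndf <- data.frame(name = unique(c(edf$from, edf$to)))
  }
  edf[] <- lapply(edf, function(col) if (is.factor(col)) as.character(col) else col)
  igraph::graph_from_data_frame(edf, directed = directed, vertices = ndf)
}

#' Export a network as a JSON edge list
#'
#' Writes `{"directed": ..., "nodes": [...], "edges": [...]}` with every
#' edge and node attribute column preserved; [read_network_json()] reads it
#' back.
#'
#' @inheritParams write_network_graphml
#' @return `path`, invisibly.
#' @export
write_network_json <- function(edges, path, directed = FALSE, nodes = NULL) {
  payload <- list(
    directed = directed,
    nodes = if (is.null(nodes))
      data.frame(name = unique(c(edges$from, edges$to))) else
      as.data.frame(nodes),
    edges = as.data.frame(edges)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a JSON network written by [write_network_json()]
#'
#' @param path JSON file path.
#' @return A list with `directed` flag, `nodes` tibble, `edges` tibble.
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  list(
    directed = isTRUE(raw$directed),
    nodes = tibble::as_tibble(raw$nodes),
    edges = tibble::as_tibble(raw$edges)
  )
}

#' Write the strength forest-plot table as CSV
#'
#' @param strengths output of [strength_centrality()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_strengths_csv <- function(strengths, path) {
  df <- as.data.frame(strengths)
  df$kind <- as.character(df$kind)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the directed edge table as CSV
#'
#' @param directed_edges output of [test_directed_edges()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_directed_edges_csv <- function(directed_edges, path) {
  utils::write.csv(as.data.frame(directed_edges), path, row.names = FALSE)
  invisible(path)
}
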