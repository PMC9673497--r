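# Confidence-filtered PPI graph and the eight per-node centrality metrics.

#' Build a confidence-filtered undirected interaction graph
#'
#' Edges with confidence strictly greater than `min_confidence` are kept;
#' duplicates (either orientation) collapse to the maximum confidence and
#' self-loops are dropped. Only proteins incident to a retained edge become
#' nodes (isolated proteins are treated as absent, per the zero-metrics
#' rule).
#'
#' @param edge_list Data frame with columns `id_a`, `id_b`, `confidence`.
#' @param min_confidence Strict lower bound on confidence.
#' @return An [igraph::graph] with edge attribute `confidence`.
#' @export
build_graph <- function(edge_list, min_confidence = 0.63) {
  stopifnot(all(c("id_a", "id_b", "confidence") %in% names(edge_list)))
  if (any(is.na(edge_list$confidence)))
    stop("malformed edge row: missing confidence")
  el <- edge_list[edge_list$confidence > min_confidence &
                    edge_list$id_a != edge_list$id_b, , drop = FALSE]
  if (!nrow(el))
    return(igraph::make_empty_graph(0, directed = FALSE))
  key <- ifelse(el$id_a < el$id_b,
                paste(el$id_a, el$id_b, sep = "\r"),
                paste(el$id_b, el$id_a, sep = "\r"))
  conf <- tapply(el$confidence, key, max)
  ends <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L],
               confidence = as.numeric(conf)),
    directed = FALSE)
  g
}

#' The eight per-node network metrics
#'
#' For every node: average shortest path to its reachable nodes; closeness
#' (its reciprocal); betweenness normalised by `(N-1)(N-2)/2` over the whole
#' graph; stress (raw count of shortest paths through the node); degree;
#' neighbourhood connectivity (mean degree of neighbours); local clustering
#' coefficient; and topological coefficient (mean shared-neighbour overlap
#' `J(v,m)/degree(v)` over partners `m` sharing at least one neighbour,
#' where `J` counts shared neighbours plus 1 if `v` and `m` are adjacent;
#' 0 for degree < 2).
#'
#' @param graph An [igraph::graph] from [build_graph()].
#' @return Data frame, one row per node (rownames = node ids), columns
#'   `avg_shortest_path`, `closeness`, `betweenness`, `stress`, `degree`,
#'   `neighbourhood_connectivity`, `clustering_coefficient`,
#'   `topological_coefficient`.
#' @export
node_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, 8))
    names(out) <- c("avg_shortest_path", "closeness", "betweenness",
                    "stress", "degree", "neighbourhood_connectivity",
                    "clustering_coefficient", "topological_coefficient")
    return(out)
  }
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- igraph::distances(graph)
  diag(d) <- Inf
  reach <- is.finite(d)
  asp <- ifelse(rowSums(reach) > 0,
                rowSums(ifelse(reach, d, 0)) / pmax(rowSums(reach), 1L), 0)
  clo <- ifelse(asp > 0, 1 / asp, 0)
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  br <- brandes_cpp(n, as.integer(el[, 1L]) - 1L, as.integer(el[, 2L]) - 1L)
  denom <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  btw <- br$betweenness / denom
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  S <- A %*% A                       # shared-neighbour counts
  J <- S + A
  nc <- as.numeric(A %*% deg) / pmax(deg, 1L)
  nc[deg == 0L] <- 0
  tc <- numeric(n)
  Sm <- as(S, "TsparseMatrix")
  keep <- Sm@i != Sm@j & Sm@x > 0
  if (any(keep)) {
    i <- Sm@i[keep] + 1L
    j <- Sm@j[keep] + 1L
    jv <- J[cbind(i, j)]
    sums <- tapply(jv, i, sum)
    cnts <- tapply(rep(1L, length(i)), i, sum)
    rows <- as.integer(names(sums))
    tc[rows] <- (sums / cnts) / deg[rows]
  }
  tc[deg < 2L] <- 0
  out <- data.frame(avg_shortest_path = asp, closeness = clo,
                    betweenness = btw, stress = br$stress, degree = deg,
                    neighbourhood_connectivity = nc,
                    clustering_coefficient = cc,
                    topological_coefficient = tc)
  rownames(out) <- ids
  out
}

#' Metrics for one node
#' @param graph An [igraph::graph].
#' @param node Node id.
#' @return One-row data frame (see [node_metrics()]).
#' @export
compute_metrics <- function(graph, node) {
  m <- node_metrics(graph)
  if (!node %in% rownames(m)) stop("node not in graph: ", node)
  m[node, , drop = FALSE]
}

#' Per-gene network metrics with the all-zero rule
#'
#' Genes that are unmapped, or whose protein is absent from the graph
#' (including isolated proteins), receive zeros for all eight metrics.
#'
#' @param graph An [igraph::graph].
#' @param gene_map Data frame with columns `gene_id`, `protein_id`
#'   (possibly partial).
#' @param gene_ids Genes to report (default: all in `gene_map`).
#' @return Data frame, one row per gene (rownames = gene ids).
#' @export
metrics_for_genes <- function(graph, gene_map, gene_ids = NULL) {
  stopifnot(all(c("gene_id", "protein_id") %in% names(gene_map)))
  if (is.null(gene_ids)) gene_ids <- gene_map$gene_id
  m <- node_metrics(graph)
  prot <- gene_map$protein_id[match(gene_ids, gene_map$gene_id)]
  idx <- match(prot, rownames(m))
  out <- as.data.frame(matrix(0, length(gene_ids), ncol(m)))
  names(out) <- names(m)
  hit <- !is.na(idx)
  out[hit, ] <- m[idx[hit], ]
  rownames(out) <- gene_ids
  out
}
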