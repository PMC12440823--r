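#' Build a protein co-membership network from a complex table
#'
#' Every complex contributes a clique over its members; edges are undirected,
#' unweighted, deduplicated, and self-loops are removed. Optional extra edges
#' (e.g. cross-complex interactions) can be supplied.
#'
#' @param complex_table data frame `complex_id`, `complex_name`,
#'   `protein_id`.
#' @param extra_edges optional data frame `from`, `to`.
#' @return A `flip_network`: list with `graph` (igraph), `complexes` (named
#'   list of member vectors) and `complex_names` (named character vector).
#' @export
build_network <- function(complex_table, extra_edges = NULL) {
  if (nrow(complex_table) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, complexes = list(),
                          complex_names = character(0)),
                     class = "flip_network"))
  }
  complex_table <- unique(complex_table)
  members <- split(complex_table$protein_id, complex_table$complex_id)
  cnames <- complex_table$complex_name[
    match(names(members), complex_table$complex_id)]
  names(cnames) <- names(members)
  edges <- do.call(rbind, lapply(members, function(m) {
    m <- unique(m)
    if (length(m) < 2) return(NULL)
    t(utils::combn(m, 2))
  }))
  nodes <- unique(complex_table$protein_id)
  if (!is.null(extra_edges)) {
    edges <- rbind(edges, as.matrix(extra_edges[, c("from", "to")]))
    nodes <- unique(c(nodes, extra_edges$from, extra_edges$to))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, complexes = members, complex_names = cnames),
            class = "flip_network")
}

#' Personalized PageRank by power iteration
#'
#' Random walk with restart: at each step the walker follows a uniformly
#' chosen edge with probability `damping` and restarts with probability
#' `1 - damping` into the uniform distribution over the seed proteins.
#' Walkers on dangling (degree-zero) nodes are redistributed to the restart
#' distribution, so the scores stay a probability distribution.
#'
#' @param network a `flip_network` or an igraph graph.
#' @param seed_proteins restart node names; must intersect the network.
#' @param damping probability of following an edge (default 0.9).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return Named numeric vector of scores summing to 1.
#' @export
personalized_pagerank <- function(network, seed_proteins, damping = 0.9,
                                  tol = 1e-12, max_iter = 10000L) {
  g <- if (inherits(network, "flip_network")) network$graph else network
  nodes <- igraph::V(g)$name
  seeds <- intersect(seed_proteins, nodes)
  if (length(seeds) == 0)
    stop("none of the seed proteins is present in the network")
  n <- length(nodes)
  r <- stats::setNames(rep(0, n), nodes)
  r[seeds] <- 1 / length(seeds)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  deg <- rowSums(adj)
  x <- r
  for (it in seq_len(max_iter)) {
    walk <- as.vector((x / pmax(deg, 1)) %*% adj)
    dangle <- sum(x[deg == 0])
    x_new <- (1 - damping) * r + damping * (walk + dangle * r)
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  stats::setNames(as.vector(x) / sum(x), nodes)
}

#' Induced subnetwork of the top-scoring nodes
#'
#' Keeps the nodes whose score is at or above the score of the
#' `ceiling(keep_fraction * n)`-th ranked node; ties at the threshold are
#' retained (inclusive), so all-equal scores keep the whole network.
#'
#' @param network a `flip_network` or igraph graph.
#' @param scores named scores covering all nodes.
#' @param keep_fraction fraction of nodes to keep (default 0.40).
#' @return An igraph subgraph.
#' @export
top_quantile_subnetwork <- function(network, scores, keep_fraction = 0.40) {
  g <- if (inherits(network, "flip_network")) network$graph else network
  nodes <- igraph::V(g)$name
  s <- scores[nodes]
  k <- ceiling(keep_fraction * length(nodes))
  thr <- sort(s, decreasing = TRUE)[k]
  igraph::induced_subgraph(g, nodes[s >= thr])
}

#' Walktrap communities
#'
#' Random-walk based community detection (Pons-Latapy) with the given walk
#' length, cut at maximal modularity. Isolated nodes form singletons.
#'
#' @param subgraph igraph graph.
#' @param steps walk length (default 4).
#' @return Named integer membership vector.
#' @export
walktrap_clusters <- function(subgraph, steps = 4L) {
  if (igraph::vcount(subgraph) == 0) return(stats::setNames(integer(0),
                                                            character(0)))
  wt <- igraph::cluster_walktrap(subgraph, steps = steps)
  stats::setNames(igraph::membership(wt), igraph::V(subgraph)$name)
}

#' Filter clusters by size and name them by complex overlap
#'
#' Clusters below `min_size` members are dropped (dimers are typically
#' poorly annotated). Each kept cluster is named after the complex holding
#' the most proteins with changing markers in the cluster; complexes tied at
#' that maximum all contribute their name (joined by "/"). A cluster
#' overlapping no catalogued complex is named "unassigned".
#'
#' @param membership named membership vector from [walktrap_clusters()].
#' @param network the `flip_network` the clusters came from.
#' @param changed_proteins proteins with changing markers.
#' @param min_size minimum cluster size (default 4).
#' @return Data frame `cluster_id`, `name`, `size`, `n_changing`, `members`,
#'   `changing_members` (semicolon-separated).
#' @export
filter_and_name <- function(membership, network, changed_proteins,
                            min_size = 4L) {
  stopifnot(inherits(network, "flip_network"))
  rows <- list()
  for (cl in sort(unique(membership))) {
    mem <- names(membership)[membership == cl]
    if (length(mem) < min_size) next
    changing <- intersect(mem, changed_proteins)
    counts <- vapply(network$complexes, function(cm)
      length(intersect(cm, changing)), integer(1))
    name <- if (length(counts) == 0 || max(counts) == 0) {
      overlap <- vapply(network$complexes, function(cm)
        length(intersect(cm, mem)), integer(1))
      if (length(overlap) == 0 || max(overlap) == 0) "unassigned"
      else paste(sort(unique(
        network$complex_names[names(overlap)[overlap == max(overlap)]])),
        collapse = "/")
    } else {
      best <- names(counts)[counts == max(counts)]
      paste(sort(unique(network$complex_names[best])), collapse = "/")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl, name = name, size = length(mem),
      n_changing = length(changing),
      members = paste(sort(mem), collapse = ";"),
      changing_members = paste(sort(changing), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = integer(0), name = character(0),
                      size = integer(0), n_changing = integer(0),
                      members = character(0), changing_members = character(0))
  rownames(out) <- NULL
  out
}

#' Compare changing-marker sets between two conditions, per cluster
#'
#' For each cluster, the changing markers of the two conditions (restricted
#' beforehand to regions detected in both datasets) are compared as sets:
#' equal non-empty sets are `shared`; a strict superset in one condition is a
#' `gain` for that condition; overlapping-but-different or disjoint non-empty
#' sets are `divergent`; two empty sets are `none`.
#'
#' @param clusters cluster table from [filter_and_name()] (the `members`
#'   column defines each cluster).
#' @param markers1,markers2 data frames with `protein_id` and a region key
#'   column `region_id` giving the changing markers per condition.
#' @return `clusters` with columns `delta`, `n_markers_1`, `n_markers_2`.
#' @export
compare_conditions <- function(clusters, markers1, markers2) {
  delta <- character(nrow(clusters))
  n1 <- integer(nrow(clusters)); n2 <- integer(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    mem <- strsplit(clusters$members[i], ";", fixed = TRUE)[[1]]
    m1 <- unique(markers1$region_id[markers1$protein_id %in% mem])
    m2 <- unique(markers2$region_id[markers2$protein_id %in% mem])
    n1[i] <- length(m1); n2[i] <- length(m2)
    delta[i] <- if (length(m1) == 0 && length(m2) == 0) "none"
      else if (setequal(m1, m2)) "shared"
      else if (all(m2 %in% m1)) "gain_c1"
      else if (all(m1 %in% m2)) "gain_c2"
      else "divergent"
  }
  clusters$delta <- delta
  clusters$n_markers_1 <- n1
  clusters$n_markers_2 <- n2
  clusters
}
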