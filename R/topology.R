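#' Node degree
#'
#' Number of edges incident to each node.
#'
#' @param net typed network.
#' @return named integer vector over all nodes.
#' @export
node_degree <- function(net) {
  validate_typed_network(net)
  d <- igraph::degree(net, mode = "all", loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Pair-normalized shortest-path betweenness
#'
#' Fraction of shortest paths between node pairs passing through each node
#' (endpoints excluded, fractional credit over equally short paths),
#' normalized by the number of pairs not involving the node,
#' (N-1)(N-2)/2. Graphs with fewer than three nodes have no interior pairs
#' and get all-zero betweenness.
#'
#' @param net typed network (treated as unweighted, undirected).
#' @return named numeric vector in \[0, 1\] over all nodes.
#' @export
node_betweenness <- function(net) {
  validate_typed_network(net)
  n <- igraph::vcount(net)
  if (n < 3L) {
    b <- rep(0, n)
    names(b) <- igraph::V(net)$name
    return(b)
  }
  igraph::betweenness(net, directed = FALSE, weights = NA, normalized = TRUE)
}

#' Component-scaled closeness centrality
#'
#' Wasserman-Faust closeness: for a node v in a connected component of size
#' n_v inside a graph of N nodes,
#' `((n_v - 1) / (N - 1)) * ((n_v - 1) / sum of distances within the
#' component)`. On a connected graph this reduces to the familiar
#' `(N - 1) / sum(d)`; on a disconnected graph each component's values are
#' scaled down by its relative size, and isolated nodes score 0. Values lie
#' in \[0, 1\] with 1 attained exactly by nodes adjacent to everything.
#'
#' @param net typed network (unweighted, undirected).
#' @return named numeric vector over all nodes.
#' @export
node_closeness <- function(net) {
  validate_typed_network(net)
  n <- igraph::vcount(net)
  out <- numeric(n)
  names(out) <- igraph::V(net)$name
  if (n <= 1L) return(out)
  comp <- igraph::components(net)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nv <- length(idx)
    if (nv < 2L) next  # isolated node: closeness 0
    d <- igraph::distances(net, v = idx, to = idx, weights = NA)
    sums <- rowSums(d)
    out[idx] <- ((nv - 1) / (n - 1)) * ((nv - 1) / sums)
  }
  out
}

#' Full centrality table for a network
#'
#' One row per node with the three topological indices and (optionally) the
#' main-node flag from [select_main_nodes()].
#'
#' @param net typed network.
#' @param flag_main when `TRUE` (default) compute the above-mean main-node
#'   flag; `FALSE` leaves `is_main` all-`FALSE`.
#' @return data.frame with columns `node`, `role`, `degree`, `betweenness`,
#'   `closeness`, `is_main`, one row per node in graph order.
#' @export
centrality_records <- function(net, flag_main = TRUE) {
  validate_typed_network(net)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  rec <- data.frame(
    node = igraph::V(net)$name,
    role = igraph::V(net)$role,
    degree = unname(node_degree(net)),
    betweenness = unname(node_betweenness(net)),
    closeness = unname(node_closeness(net)),
    is_main = FALSE,
    stringsAsFactors = FALSE
  )
  if (flag_main) {
    sel <- select_main_nodes(rec)
    rec$is_main <- rec$node %in% sel$main_nodes
  }
  rec
}

#' Select main nodes by the above-mean three-index rule
#'
#' A node is a main node (hub) when its degree, betweenness and closeness
#' are each at or above the arithmetic mean of that index over all nodes of
#' the analyzed network. The comparison is inclusive (`>=`), so on a
#' vertex-transitive graph every node qualifies.
#'
#' @param records centrality data.frame covering all nodes of one network
#'   (see [centrality_records()]).
#' @return list with `thresholds` (named numeric: `mean_degree`,
#'   `mean_betweenness`, `mean_closeness`) and `main_nodes` (character
#'   vector of selected node ids, in record order).
#' @export
select_main_nodes <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no centrality records", call. = FALSE)
  }
  thr <- c(
    mean_degree = mean(records$degree),
    mean_betweenness = mean(records$betweenness),
    mean_closeness = mean(records$closeness)
  )
  keep <- records$degree >= thr[["mean_degree"]] &
    records$betweenness >= thr[["mean_betweenness"]] &
    records$closeness >= thr[["mean_closeness"]]
  list(thresholds = thr, main_nodes = records$node[keep])
}
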