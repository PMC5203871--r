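#' Node roles used across all networks
#'
#' Closed set of role labels a node of a typed network may carry.
#'
#' @format Character vector of the eight admissible roles.
#' @export
NODE_ROLES <- c(
  "herb", "compound", "compound_target", "infertility_target",
  "shared_target", "other_protein", "pharmacology", "effect"
)

#' Construct a typed network
#'
#' A typed network is an undirected simple [igraph::graph] whose vertices
#' carry a `role` attribute drawn from [NODE_ROLES] and whose edges may carry
#' a `relation` label (defaults to `"pp"`, the generic protein-protein
#' relation used in SIF exports).
#'
#' @param nodes character vector of node ids (unique, non-empty).
#' @param roles character vector of roles, parallel to `nodes`.
#' @param edges two-column character matrix or data.frame of endpoint ids;
#'   may have a third column `relation`.
#' @param name graph-level name.
#' @return an igraph object with vertex attributes `name`, `role`, edge
#'   attribute `relation` and graph attribute `name`.
#' @export
typed_network <- function(nodes, roles, edges = NULL, name = "network") {
  stopifnot(length(nodes) == length(roles))
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  if (any(!nzchar(nodes))) stop("empty node id", call. = FALSE)
  bad <- setdiff(unique(roles), NODE_ROLES)
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes, role = roles)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    rel <- if (ncol(edges) >= 3L) as.character(edges[[3L]]) else rep("pp", length(a))
    missing <- setdiff(unique(c(a, b)), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(a == b)) stop("self-loop edge not allowed", call. = FALSE)
    # canonical unordered storage; parallel edges collapse to one
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    keep <- !duplicated(key)
    g <- igraph::add_edges(g, rbind(lo[keep], hi[keep]), relation = rel[keep])
  }
  g$name <- name
  validate_typed_network(g)
}

#' Validate a typed network
#'
#' Checks the simple-graph invariant and the closed role set; returns the
#' graph invisibly-unchanged so it can be used in pipelines.
#'
#' @param g igraph object.
#' @return `g`, invisibly unchanged.
#' @export
validate_typed_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("typed network must be undirected", call. = FALSE)
  if (!igraph::is_simple(g)) stop("typed network must be a simple graph", call. = FALSE)
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0) {
    stop("nodes must be named", call. = FALSE)
  }
  roles <- igraph::V(g)$role
  if (igraph::vcount(g) > 0) {
    if (is.null(roles)) stop("nodes must carry a role attribute", call. = FALSE)
    bad <- setdiff(unique(roles), NODE_ROLES)
    if (length(bad)) {
      stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  g
}

#' Tabulate node roles
#'
#' @param g typed network.
#' @return named integer vector, one entry per role present, sorted by role.
#' @export
role_census <- function(g) {
  validate_typed_network(g)
  if (igraph::vcount(g) == 0) return(integer(0))
  tab <- table(igraph::V(g)$role)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' Nodes of a given role
#'
#' @param g typed network.
#' @param role one or more role labels.
#' @return character vector of node ids.
#' @export
nodes_with_role <- function(g, role) {
  validate_typed_network(g)
  igraph::V(g)$name[igraph::V(g)$role %in% role]
}
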