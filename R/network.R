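#' Directed social network from nomination edges
#'
#' A light container for a directed friendship graph: nodes are people,
#' an edge `source -> target` records that `source` nominated `target` as a
#' social tie. Self-loops are rejected; duplicate edges are collapsed.
#'
#' @param edges data.frame with columns `source`, `target` (and optionally
#'   `weight`, default 1).
#' @param nodes optional full node set (isolates allowed); defaults to the
#'   nodes appearing in `edges`.
#' @return object of class `social_network`.
#' @export
#' @examples
#' net <- social_network(data.frame(source = c("a", "b"), target = c("b", "a")))
#' centrality_table(net)
social_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (is.null(edges[["weight"]])) edges$weight <- rep(1, nrow(edges))
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  nodes <- as.character(nodes %||% unique(c(edges$source, edges$target)))
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown)) stop("edge endpoints not in nodes: ",
                            paste(unknown, collapse = ", "))
  structure(list(nodes = nodes, edges = edges[c("source", "target", "weight")]),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat("social_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  invisible(x)
}

as_igraph <- function(net, mode = c("directed", "union")) {
  mode <- match.arg(mode)
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  if (mode == "union")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "max"))
  g
}

#' Eigenvector centrality of a social network
#'
#' Principal-eigenvector scores of the adjacency structure: a node is
#' central when it is connected to other well-connected nodes. Scores are
#' non-negative and max-normalized to 1. By default the nomination digraph
#' is symmetrized by union first, because directed eigenvector centrality is
#' unstable for sink nodes in nomination data; `mode = "directed"` uses the
#' digraph as-is.
#'
#' @param net a [social_network()].
#' @param mode `"union"` (symmetrize, default) or `"directed"`.
#' @return named numeric vector of scores.
#' @export
eigenvector_centrality <- function(net, mode = c("union", "directed")) {
  stopifnot(inherits(net, "social_network"))
  if (!length(net$nodes)) stop("empty graph")
  mode <- match.arg(mode)
  g <- as_igraph(net, if (mode == "union") "union" else "directed")
  ec <- igraph::eigen_centrality(g, directed = mode == "directed")$vector
  ec[net$nodes]
}

#' Burt constraint and brokerage
#'
#' Burt's constraint of node i is `sum_j (p_ij + sum_q p_iq p_qj)^2` over
#' proportional tie strengths `p`; low constraint marks brokers bridging
#' otherwise disconnected contacts. Brokerage is defined as
#' `constraint^(-0.5)`. By default the directed nomination graph is
#' symmetrized by union before computing proportional strengths
#' (`ties = "mutual"`); `ties = "directed"` uses the directed proportional
#' treatment instead. Isolated nodes have undefined constraint (`NA`).
#'
#' @param net a [social_network()].
#' @param ties `"mutual"` (default) or `"directed"`.
#' @return data.frame with `node`, `constraint`, `brokerage`.
#' @export
#' @examples
#' tri <- social_network(data.frame(source = c("a", "b", "c"),
#'                                  target = c("b", "c", "a")))
#' burt_constraint(tri)   # constraint 1.125, brokerage 1.125^-0.5
burt_constraint <- function(net, ties = c("mutual", "directed")) {
  stopifnot(inherits(net, "social_network"))
  ties <- match.arg(ties)
  g <- as_igraph(net, if (ties == "mutual") "union" else "directed")
  cons <- igraph::constraint(g, weights = igraph::E(g)$weight)
  cons <- cons[net$nodes]
  cons[is.nan(cons)] <- NA_real_
  data.frame(node = net$nodes, constraint = unname(cons),
             brokerage = unname(cons^(-0.5)))
}

#' PCA composite of eigenvector centrality and brokerage
#'
#' Eigenvector centrality and brokerage are often highly correlated; the
#' composite captures their shared variance. Both metrics are z-scored over
#' the supplied nodes and projected onto the first principal component, with
#' the sign oriented so the loading on eigenvector centrality is positive.
#' The composite has zero mean over included nodes. The PCA is fitted over
#' whichever node set is passed, so the caller chooses the reference
#' population (full cohort vs study participants).
#'
#' @param eigen,brokerage numeric vectors over the same nodes (>= 3 defined
#'   values; neither may be constant).
#' @return numeric vector of composite scores (`NA` where either input is
#'   `NA`).
#' @export
pca_centrality <- function(eigen, brokerage) {
  if (length(eigen) != length(brokerage)) stop("metric lengths differ")
  ok <- !is.na(eigen) & !is.na(brokerage)
  if (sum(ok) < 3) stop("need at least 3 nodes with defined metrics")
  if (sd(eigen[ok]) == 0 || sd(brokerage[ok]) == 0)
    stop("degenerate PCA: a metric is constant over included nodes")
  z <- scale(cbind(eigen = eigen[ok], brokerage = brokerage[ok]))
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1["eigen"] < 0) load1 <- -load1
  out <- rep(NA_real_, length(eigen))
  out[ok] <- as.numeric(z %*% load1)
  out
}

#' Per-node centrality table
#'
#' Convenience wrapper computing eigenvector centrality, Burt constraint,
#' brokerage, and the PCA composite for every node of a network.
#'
#' @param net a [social_network()].
#' @param nodes node subset to fit the PCA over (default all); metrics are
#'   still reported for every node in the subset.
#' @inheritParams eigenvector_centrality
#' @inheritParams burt_constraint
#' @return data.frame `node`, `eigenvector`, `constraint`, `brokerage`,
#'   `pca_centrality`.
#' @export
centrality_table <- function(net, nodes = NULL, mode = "union",
                             ties = "mutual") {
  ec <- eigenvector_centrality(net, mode = mode)
  bc <- burt_constraint(net, ties = ties)
  tab <- data.frame(node = net$nodes, eigenvector = unname(ec),
                    constraint = bc$constraint, brokerage = bc$brokerage)
  if (!is.null(nodes)) tab <- tab[tab$node %in% nodes, , drop = FALSE]
  tab$pca_centrality <- pca_centrality(tab$eigenvector, tab$brokerage)
  rownames(tab) <- NULL
  tab
}
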