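#' Build the ingredients-candidate targets-proteins network
#'
#' Nodes are the ingredients with at least one candidate target, the
#' candidate targets, and the interacting proteins. Edges connect each such
#' ingredient to every candidate it targets, plus the kept high-confidence
#' PPI edges. The result is a simple undirected graph: duplicates collapsed,
#' self-loops forbidden. Ingredients with no candidate target are excluded
#' (they would sit isolated and depress the mean degree).
#'
#' @param cands A `candidate_set` (after [expand_interactors()], or before,
#'   for an ingredient-candidate bipartite view).
#' @param c The `compendium` the candidates came from.
#' @return A `tripartite_network`.
#' @export
build_network <- function(cands, c) {
  assoc <- c$associations
  hit <- assoc[assoc$gene %in% cands$candidates, , drop = FALSE]
  ings <- sort(unique(hit$ingredient))
  nodes <- c(
    stats::setNames(rep("ingredient", length(ings)), ings),
    stats::setNames(rep("candidate_target", length(cands$candidates)),
                    cands$candidates),
    stats::setNames(rep("protein", length(cands$interactors)),
                    cands$interactors)
  )
  edges <- rbind(
    as.matrix(hit[, c("ingredient", "gene")]),
    as.matrix(cands$kept_edges[, c("a", "b")])
  )
  tripartite_network(nodes, edges)
}

#' Per-node degree of a tripartite network
#'
#' @param net A `tripartite_network`.
#' @return Named integer vector, one entry per node (isolated nodes 0).
#' @export
node_degrees <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), names(net$nodes))
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges[, 1], net$edges[, 2]))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Degree statistics and the key-node threshold of a network
#'
#' For a simple graph the mean degree is `sum(degrees)/n_nodes =
#' 2*n_edges/n_nodes`; the key-node threshold is exactly twice the mean.
#' Degrees are computed with igraph and asserted against the handshake
#' lemma.
#'
#' @param net A `tripartite_network`.
#' @return A `network_stats` list: n_nodes, n_edges, degrees (named int
#'   vector), mean_degree, key_threshold.
#' @export
network_stats <- function(net) {
  stopifnot(length(net$nodes) >= 1)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  stopifnot(sum(deg) == 2 * nrow(net$edges))  # handshake lemma
  mean_degree <- sum(deg) / length(deg)
  structure(list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    degrees = stats::setNames(as.integer(deg), names(deg)),
    mean_degree = mean_degree,
    key_threshold = 2 * mean_degree
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network_stats: %d nodes, %d edges, mean degree %.3f, key threshold %.3f\n",
              x$n_nodes, x$n_edges, x$mean_degree, x$key_threshold))
  invisible(x)
}

#' Select key nodes by the degree > 2 x mean rule
#'
#' A node is key when its degree strictly exceeds twice the network's mean
#' degree. Results are partitioned by layer and each list is sorted by
#' degree descending with lexicographic tie-break. A pooled view
#' (`key_targets_pooled`) merges candidate targets and interacting proteins,
#' the combination conventionally reported as "key targets".
#'
#' @param net A `tripartite_network`.
#' @param stats A `network_stats` computed on `net` (defaults to computing
#'   it).
#' @return List with key_ingredients, key_targets, key_proteins,
#'   key_targets_pooled (character vectors of node ids).
#' @export
select_key_nodes <- function(net, stats = network_stats(net)) {
  deg <- stats$degrees
  key <- names(deg)[deg > stats$key_threshold]
  ord <- function(ids) ids[order(-deg[ids], ids)]
  by_layer <- function(layer) ord(key[net$nodes[key] == layer])
  ki <- by_layer("ingredient")
  kt <- by_layer("candidate_target")
  kp <- by_layer("protein")
  list(key_ingredients = ki, key_targets = kt, key_proteins = kp,
       key_targets_pooled = ord(c(kt, kp)))
}
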