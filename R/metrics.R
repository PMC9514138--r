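check_adjacency <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square", call. = FALSE)
  if (any(adjacency != 0 & adjacency != 1))
    stop("adjacency must be binary", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency must be symmetric", call. = FALSE)
  storage.mode(adjacency) <- "integer"
  adjacency
}

#' Global efficiency of a binary undirected graph
#'
#' The mean over all node pairs of the inverse shortest-path length
#' (edge count), with disconnected pairs contributing 0. A network
#' integration measure in `[0, 1]`; 1 for a complete graph.
#'
#' @param adjacency binary symmetric matrix, zero diagonal, at least 2
#'   nodes.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  if (nrow(adjacency) < 2L) stop("need at least 2 nodes", call. = FALSE)
  global_efficiency_cpp(adjacency)
}

#' Local efficiency of a binary undirected graph
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (the node itself excluded); nodes of degree < 2 score 0. The
#' network-level value is the mean over all nodes — a segregation measure.
#'
#' @inheritParams global_efficiency
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
local_efficiency <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  e <- local_efficiency_cpp(adjacency)
  names(e) <- rownames(adjacency)
  list(per_node = e, mean = mean(e))
}

#' Louvain community detection at a stated resolution
#'
#' Maximizes Newman-Girvan modularity with resolution `gamma` by the
#' Louvain algorithm, seeded for reproducibility. Isolated nodes end up in
#' singleton modules; an edgeless graph yields the all-singleton partition
#' (quality 0) with a warning.
#'
#' @param adjacency binary symmetric matrix, zero diagonal.
#' @param resolution resolution parameter gamma (> 0); 1 is the classical
#'   modularity.
#' @param seed integer seed controlling the algorithm's node-order
#'   randomness.
#' @return an object of class `scn_partition`: list with `membership`
#'   (named integer vector, module ids contiguous from 1), `n_modules`,
#'   `resolution`, `quality` (Newman-Girvan Q at this resolution).
#' @export
detect_communities <- function(adjacency, resolution = 1, seed = 1L) {
  adjacency <- check_adjacency(adjacency)
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (sum(adjacency) == 0) {
    warning("edgeless graph: returning all-singleton partition",
            call. = FALSE)
    memb <- seq_len(nrow(adjacency))
    names(memb) <- rownames(adjacency)
    out <- list(membership = memb, n_modules = nrow(adjacency),
                resolution = resolution, quality = 0)
    class(out) <- "scn_partition"
    return(out)
  }
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  cl <- with_seed(seed,
                  igraph::cluster_louvain(g, resolution = resolution))
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, sort(unique(memb)))  # contiguous ids from 1
  names(memb) <- rownames(adjacency)
  out <- list(
    membership = memb,
    n_modules = max(memb),
    resolution = resolution,
    quality = igraph::modularity(g, memb, resolution = resolution)
  )
  class(out) <- "scn_partition"
  out
}

#' @export
print.scn_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d modules at resolution %g (Q = %.4f)\n",
              x$n_modules, x$resolution, x$quality))
  invisible(x)
}

#' Participation coefficient over a module partition
#'
#' Per node `i`, `PC_i = 1 - sum_s (k_is / k_i)^2` where `k_is` counts the
#' node's edges into module `s` and `k_i` is its degree; degree-0 nodes
#' score 0. The network-level value is the mean over all nodes. High mean
#' participation means edges are spread across modules — less segregation;
#' low values mean edges concentrate within modules — more segregation.
#'
#' @param adjacency binary symmetric matrix, zero diagonal.
#' @param partition an [detect_communities()] result, or a membership
#'   vector over the nodes.
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
participation_coefficient <- function(adjacency, partition) {
  adjacency <- check_adjacency(adjacency)
  memb <- if (inherits(partition, "scn_partition")) partition$membership
          else as.integer(partition)
  if (length(memb) != nrow(adjacency))
    stop("partition covers ", length(memb), " nodes but the graph has ",
         nrow(adjacency), call. = FALSE)
  k <- rowSums(adjacency)
  mods <- sort(unique(memb))
  ind <- outer(memb, mods, "==") * 1
  kis <- adjacency %*% ind           # edges from i into each module
  frac <- kis / ifelse(k > 0, k, 1)
  pc <- 1 - rowSums(frac^2)
  pc[k == 0] <- 0
  names(pc) <- rownames(adjacency)
  list(per_node = pc, mean = mean(pc))
}

#' Segregation and integration metrics of a network
#'
#' Bundles the three network parameters of the analysis: mean local
#' efficiency, global efficiency, and modularity quantified as the mean
#' participation coefficient over a Louvain partition at the stated
#' resolution (Newman-Girvan Q of that partition is attached as a
#' diagnostic). Identical adjacency and seed give identical metrics.
#' Interpretation contract: a HIGHER mean participation coefficient means
#' LESS segregation.
#'
#' @param network an `scn` object from [estimate_sparse_network()], or a
#'   binary adjacency matrix.
#' @param resolution Louvain resolution (default 1).
#' @param seed seed for the community detection.
#' @return an object of class `scn_metrics`: list with per-node and mean
#'   local efficiency, `global_efficiency`, per-node and mean participation,
#'   and the `partition` used.
#' @export
compute_network_metrics <- function(network, resolution = 1, seed = 1L) {
  adjacency <- if (inherits(network, "scn")) network$adjacency else network
  adjacency <- check_adjacency(adjacency)
  eloc <- local_efficiency(adjacency)
  eglob <- if (nrow(adjacency) >= 2L) global_efficiency_cpp(adjacency) else 0
  part <- if (sum(adjacency) == 0) {
    memb <- seq_len(nrow(adjacency))
    names(memb) <- rownames(adjacency)
    structure(list(membership = memb, n_modules = nrow(adjacency),
                   resolution = resolution, quality = 0),
              class = "scn_partition")
  } else {
    detect_communities(adjacency, resolution = resolution, seed = seed)
  }
  pc <- participation_coefficient(adjacency, part)
  out <- list(
    local_efficiency_per_node = eloc$per_node,
    mean_local_efficiency = eloc$mean,
    global_efficiency = eglob,
    participation_per_node = pc$per_node,
    mean_participation = pc$mean,
    partition = part
  )
  class(out) <- "scn_metrics"
  out
}

#' @export
print.scn_metrics <- function(x, ...) {
  cat("Network metrics\n")
  cat(sprintf("  mean local efficiency:  %.4f\n", x$mean_local_efficiency))
  cat(sprintf("  global efficiency:      %.4f\n", x$global_efficiency))
  cat(sprintf("  mean participation:     %.4f (%d modules, Q = %.4f)\n",
              x$mean_participation, x$partition$n_modules,
              x$partition$quality))
  invisible(x)
}

# fast internal path: metric scalar from adjacency, skipping re-validation
metric_value <- function(adjacency, metric_name, resolution, seed) {
  switch(metric_name,
    global_efficiency = global_efficiency_cpp(adjacency),
    local_efficiency = mean(local_efficiency_cpp(adjacency)),
    participation = {
      if (sum(adjacency) == 0) return(0)
      g <- igraph::graph_from_adjacency_matrix(adjacency,
                                               mode = "undirected")
      cl <- with_seed(seed,
                      igraph::cluster_louvain(g, resolution = resolution))
      memb <- as.integer(igraph::membership(cl))
      k <- rowSums(adjacency)
      ind <- outer(memb, sort(unique(memb)), "==") * 1
      frac <- (adjacency %*% ind) / ifelse(k > 0, k, 1)
      pc <- 1 - rowSums(frac^2)
      pc[k == 0] <- 0
      mean(pc)
    },
    stop("unknown metric: '", metric_name, "'", call. = FALSE))
}
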