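## Modular organization ---------------------------------------------------
##
## Louvain community detection on the positive-weight subgraph, with the
## resolution parameter R tuned by maximizing Q - Q_shuffled over a grid
## (0.4..0.9 step 0.1), where the shuffled networks keep every edge weight
## but reassign each edge to a uniformly random node pair (collisions sum
## their weights). Louvain is stochastic, so detection is best-of-restarts
## under a fixed seed.

.positive_subgraph <- function(graph) {
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  igraph::subgraph_from_edges(graph, igraph::E(graph)[w > 0],
                              delete.vertices = FALSE)
}

#' Endpoint-shuffled null network
#'
#' Keeps the multiset of edge weights, reassigns each edge to a uniformly
#' random unordered node pair (no self loops); colliding pairs sum their
#' weights, so the edge count may drop but total weight is conserved. The
#' degree sequence is not preserved.
#'
#' @param graph an igraph graph with weights.
#' @param seed integer seed.
#' @return an igraph graph on the same nodes.
#' @export
shuffle_network <- function(graph, seed) {
  n <- igraph::vcount(graph)
  if (n < 2) stopf("need >= 2 nodes")
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  m <- length(w)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  with_seed(seed, {
    a <- sample.int(n, m, replace = TRUE)
    b <- sample.int(n - 1L, m, replace = TRUE)
    b <- ifelse(b >= a, b + 1L, b)          # uniform pair, no self loops
    key <- paste(pmin(a, b), pmax(a, b))
    agg <- tapply(w, key, sum)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    el <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
    g <- igraph::graph_from_edgelist(
      matrix(nodes[el], ncol = 2), directed = FALSE)
    g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
    igraph::E(g)$weight <- as.numeric(agg)
    g
  })
}

#' Louvain community detection at a fixed resolution
#'
#' Runs on the positive-weight subgraph; negative edges are excluded from
#' detection (Newman modularity assumes nonnegative weights) but retained
#' for the correlation summaries. Best of `n_restarts` runs by modularity.
#'
#' @param graph an igraph graph.
#' @param R resolution parameter (> 0).
#' @param seed integer seed.
#' @param n_restarts restarts kept by maximum Q.
#' @return list of class `partition`: `membership` (named), `Q` (modularity
#'   at resolution R on the positive subgraph), `R`, `n_communities`.
#' @export
detect_communities <- function(graph, R = 1, seed = 1, n_restarts = 10) {
  if (R <= 0) stopf("R must be > 0")
  gp <- .positive_subgraph(graph)
  nodes <- igraph::V(gp)$name %||% as.character(seq_len(igraph::vcount(gp)))
  if (igraph::ecount(gp) == 0) {
    ## no positive edges: every node is its own community, Q defined as 0
    memb <- setNames(seq_along(nodes), nodes)
    return(structure(list(membership = memb, Q = 0, R = R,
                          n_communities = length(nodes)),
                     class = "partition"))
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(gp, resolution = R)
      q <- igraph::modularity(gp, igraph::membership(cl),
                              weights = igraph::E(gp)$weight, resolution = R)
      if (is.null(best) || q > best$Q)
        best <- list(membership = setNames(as.integer(igraph::membership(cl)),
                                           nodes),
                     Q = q)
    }
  })
  structure(list(membership = best$membership, Q = best$Q, R = R,
                 n_communities = length(unique(best$membership))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities, Q = %.4f at R = %g\n",
              x$n_communities, x$Q, x$R))
  invisible(x)
}

#' Tune the Louvain resolution against shuffled networks
#'
#' For each R on the grid, computes Q of the real graph minus the mean Q of
#' `n_shuffles` endpoint-shuffled graphs (each re-detected at that R); the
#' selected R* maximizes the mean difference, ties going to the smallest R.
#'
#' @param graph an igraph graph with at least one positive edge.
#' @param r_grid resolution grid (default 0.4..0.9 step 0.1).
#' @param n_shuffles shuffled networks per R (default 1000).
#' @param seed integer seed.
#' @param n_restarts Louvain restarts per detection.
#' @return list of class `resolution_tuning`: `R_star`, `tuning`
#'   (data.frame R, Q, mean_Q_shuffled, delta_Q).
#' @export
tune_resolution <- function(graph, r_grid = seq(0.4, 0.9, by = 0.1),
                            n_shuffles = 1000, seed = 1, n_restarts = 5) {
  gp <- .positive_subgraph(graph)
  if (igraph::ecount(gp) == 0) stopf("graph has no positive edge")
  shuffled <- lapply(seq_len(n_shuffles), function(s)
    shuffle_network(gp, seed = derive_seed(seed, "communities") + s))
  rows <- lapply(seq_along(r_grid), function(k) {
    R <- r_grid[k]
    q <- detect_communities(graph, R, seed = derive_seed(seed, "communities") + k,
                            n_restarts = n_restarts)$Q
    qs <- vapply(seq_along(shuffled), function(s) {
      detect_communities(shuffled[[s]], R,
                         seed = derive_seed(seed, "communities") + 1000L * k + s,
                         n_restarts = 1)$Q
    }, numeric(1))
    data.frame(R = R, Q = q, mean_Q_shuffled = mean(qs),
               delta_Q = q - mean(qs))
  })
  tuning <- do.call(rbind, rows)
  R_star <- tuning$R[which.max(tuning$delta_Q)]   # which.max: first = smallest R
  structure(list(R_star = R_star, tuning = tuning),
            class = "resolution_tuning")
}

#' Mean correlation within and between communities
#'
#' As [area_summary()] but over the communities of a partition; negative
#' edges are included. Singleton communities have no within mean.
#'
#' @param partition a `partition`.
#' @param matrix a `corr_matrix` covering the partitioned nodes.
#' @return data.frame (community_a, community_b, mean_r, n_pairs).
#' @export
community_summary <- function(partition, matrix) {
  memb <- partition$membership
  area_map <- setNames(sprintf("c%02d", memb), names(memb))
  out <- area_summary(matrix, area_map)
  names(out)[1:2] <- c("community_a", "community_b")
  out
}
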