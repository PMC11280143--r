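## Interregional c-Fos correlation networks -------------------------------
##
## Per experimental group: Kendall tau-b between all region pairs across
## samples (relative densities), entries gated to exactly 0 when the
## two-sided p >= 0.05, zero diagonal. Graphs are built from the gated
## matrix; node metrics are degree centrality DC = degree/(N-1) and the
## participation coefficient PC = 1 - sum_m (k_im/k_i)^2 over the
## communities of a supplied partition (binary degrees). Stability sweeps
## rebuild the graph over an (|r|, p) threshold grid and track mean DC.

#' Significance-gated Kendall correlation matrix for one group
#'
#' @param density_table a [cfos_density()] table (relative densities are
#'   correlated) or a plain samples x regions matrix.
#' @param group group label selecting samples (ignored for a plain matrix).
#' @param p_max gate: entries with p >= p_max are set to exactly 0.
#' @param exact_n_max passed to [kendall_cor()].
#' @param adjust "none" (default, as the gating is defined) or "BH" for an
#'   exploratory Benjamini-Hochberg gate.
#' @return list of class `corr_matrix`: `group`, `regions`, `r`, `p`
#'   (symmetric matrices), `p_max`.
#' @export
correlation_matrix <- function(density_table, group = NULL, p_max = 0.05,
                               exact_n_max = 9, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(density_table, "density_table")) {
    m <- density_table$relative
    if (!is.null(group)) m <- m[density_table$samples$group == group, , drop = FALSE]
  } else m <- density_table
  if (nrow(m) < 4) stopf("need >= 4 samples in the group")
  regions <- colnames(m)
  n <- ncol(m)
  r <- p <- matrix(0, n, n, dimnames = list(regions, regions))
  p[] <- NA_real_
  const <- apply(m, 2, function(x) sd(x) == 0)
  if (any(const))
    warnf("%d constant region(s); their correlations are set to 0", sum(const))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (const[i] || const[j]) next
    kc <- kendall_cor(m[, i], m[, j], exact_n_max = exact_n_max)
    r[i, j] <- r[j, i] <- kc$tau
    p[i, j] <- p[j, i] <- kc$p
  }
  if (adjust == "BH") {
    ut <- upper.tri(p)
    padj <- stats::p.adjust(p[ut], "BH")
    p[ut] <- padj; p <- pmax(p, t(p), na.rm = TRUE)
    diag(p) <- NA_real_
  }
  r_raw <- r
  gate <- is.na(p) | p >= p_max
  r[gate] <- 0
  diag(r) <- 0
  diag(r_raw) <- 0
  structure(list(group = group, regions = regions, r = r, r_raw = r_raw,
                 p = p, p_max = p_max),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  ut <- upper.tri(x$r)
  nsig <- sum(x$r[ut] != 0)
  cat(sprintf("corr_matrix (%s): %d regions, %d significant edges (p < %g)\n",
              x$group %||% "ungrouped", length(x$regions), nsig, x$p_max))
  invisible(x)
}

#' Build the correlation graph
#'
#' Nodes are regions; an edge exists iff |r| >= `r_abs_min` and p < `p_max`;
#' the edge weight is r.
#'
#' @param matrix a `corr_matrix`.
#' @param r_abs_min,p_max thresholds.
#' @return an igraph graph with a `weight` edge attribute.
#' @export
build_graph <- function(matrix, r_abs_min = 0, p_max = 0.05) {
  r <- matrix$r_raw %||% matrix$r
  keep <- !is.na(matrix$p) & matrix$p < p_max & abs(r) >= pmax(r_abs_min, 1e-12)
  r[!keep] <- 0
  diag(r) <- 0
  g <- igraph::graph_from_adjacency_matrix(r, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Degree centrality and participation coefficient
#'
#' DC_i = degree_i / (N - 1). PC_i = 1 - sum_m (k_im / k_i)^2 with binary
#' degrees k_im into each community m of `partition`; isolated nodes get
#' DC = PC = 0.
#'
#' @param graph an igraph graph.
#' @param partition named membership vector covering all nodes (see
#'   [detect_communities()]), or NULL for a single community.
#' @return data.frame (region, DC, PC).
#' @export
node_metrics <- function(graph, partition = NULL) {
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  n <- length(nodes)
  memb <- if (is.null(partition)) setNames(rep(1L, n), nodes)
          else if (is.list(partition)) partition$membership
          else partition
  if (!all(nodes %in% names(memb))) stopf("partition must cover all nodes")
  deg <- igraph::degree(graph)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) != 0
  pc <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k == 0) return(0)
    km <- tapply(adj[i, ], memb[nodes], sum)
    1 - sum((km / k)^2)
  }, numeric(1))
  data.frame(region = nodes,
             DC = if (n > 1) as.numeric(deg) / (n - 1) else 0,
             PC = pc, stringsAsFactors = FALSE)
}

#' Mean degree centrality across a threshold grid
#'
#' Rebuilds the graph for every (|r|, p) threshold pair and records the mean
#' DC over nodes (graph degree at each sweep point).
#'
#' @param matrix a `corr_matrix`.
#' @param r_grid,p_grid threshold grids.
#' @return data.frame (r_abs_min, p_max, mean_dc, n_edges).
#' @export
stability_sweep <- function(matrix, r_grid = seq(0, 0.8, by = 0.1),
                            p_grid = c(0.05, 0.01, 0.005, 0.001)) {
  out <- expand.grid(r_abs_min = r_grid, p_max = p_grid)
  res <- t(vapply(seq_len(nrow(out)), function(k) {
    g <- build_graph(matrix, out$r_abs_min[k], out$p_max[k])
    c(mean(igraph::degree(g)) / max(1, igraph::vcount(g) - 1),
      igraph::ecount(g))
  }, numeric(2)))
  out$mean_dc <- res[, 1]; out$n_edges <- res[, 2]
  out
}

#' Mean correlation within and between parent areas
#'
#' Means are over all gated entries (zeros included: a gated-to-zero pair is
#' "no correlation"); the diagonal is excluded. An area with fewer than two
#' regions has no within mean (NA).
#'
#' @param matrix a `corr_matrix`.
#' @param area_map named character vector region -> area.
#' @param significant_only if TRUE, average only the significant entries.
#' @return data.frame (area_a, area_b, mean_r, n_pairs); rows with
#'   area_a == area_b are within-area means.
#' @export
area_summary <- function(matrix, area_map, significant_only = FALSE) {
  regs <- matrix$regions
  if (!all(regs %in% names(area_map))) stopf("area_map must cover all regions")
  areas <- sort(unique(area_map[regs]))
  grid <- expand.grid(a = areas, b = areas, stringsAsFactors = FALSE)
  grid <- grid[grid$a <= grid$b, ]
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    ia <- which(area_map[regs] == grid$a[k])
    ib <- which(area_map[regs] == grid$b[k])
    if (grid$a[k] == grid$b[k]) {
      if (length(ia) < 2)
        return(data.frame(area_a = grid$a[k], area_b = grid$b[k],
                          mean_r = NA_real_, n_pairs = 0L))
      pr <- t(utils::combn(ia, 2))
    } else {
      pr <- as.matrix(expand.grid(ia, ib))
    }
    vals <- matrix$r[pr]
    if (significant_only) vals <- vals[vals != 0]
    data.frame(area_a = grid$a[k], area_b = grid$b[k],
               mean_r = if (length(vals)) mean(vals) else NA_real_,
               n_pairs = length(vals))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fraction of significant correlations that are negative
#'
#' @param matrix a `corr_matrix`.
#' @return proportion over upper-triangle significant entries (NaN if none).
#' @export
negative_fraction <- function(matrix) {
  ut <- upper.tri(matrix$r)
  sig <- matrix$r[ut][matrix$r[ut] != 0]
  if (!length(sig)) return(NaN)
  mean(sig < 0)
}

#' Restrict a correlation matrix to a region list
#'
#' Missing regions are reported (message), not fatal; an empty intersection
#' is an error. Gating is preserved (entries are copied).
#'
#' @param matrix a `corr_matrix`.
#' @param region_list character vector of region names.
#' @return a `corr_matrix` over the intersection.
#' @export
extract_subnetwork <- function(matrix, region_list) {
  found <- intersect(region_list, matrix$regions)
  missing <- setdiff(region_list, matrix$regions)
  if (!length(found)) stopf("none of the requested regions are in the matrix")
  if (length(missing))
    message(sprintf("extract_subnetwork: %d region(s) not in matrix: %s",
                    length(missing), paste(missing, collapse = ", ")))
  structure(list(group = matrix$group, regions = found,
                 r = matrix$r[found, found, drop = FALSE],
                 r_raw = (matrix$r_raw %||% matrix$r)[found, found, drop = FALSE],
                 p = matrix$p[found, found, drop = FALSE],
                 p_max = matrix$p_max),
            class = "corr_matrix")
}

#' Core default-mode-network region set
#'
#' Prefrontal, somatomotor and medial isocortical regions conventionally
#' analyzed as the rodent default mode network, in both hemispheres, with
#' "c_"/"i_" prefixes for contralateral/ipsilateral.
#' @return character vector of region labels.
#' @export
dmn_regions <- function() {
  core <- c("ACAd", "ACAv", "PL", "ILA", "ORBl", "ORBm", "ORBvl",
            "SSp-tr", "SSp-ll", "MOs",
            "VISa", "VISam", "RSPagl", "RSPd", "RSPv")
  c(paste0("c_", core), paste0("i_", core))
}
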