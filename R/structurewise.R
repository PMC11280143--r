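## Structure-wise comparisons along the AP axis ---------------------------
##
## For one region, groups are compared bin-by-bin: the Friedman
## repeated-measures rank test treats AP bins as blocks and groups as
## conditions, with the group-mean count in each bin as the condition value
## (groups have unequal sizes, so means are the one-observation-per-cell
## reduction; this mapping is a documented design choice). Post hoc pairs
## use a two-sided Wilcoxon signed-rank on the bin-matched group means with
## one-step Bonferroni. The summed-difference metric averages all A x B
## sample-pair differences per bin and sums over bins.

#' Friedman repeated-measures test across groups for one region
#'
#' @param traces_by_group named list of matrices (samples x bins) sharing the
#'   bin grid.
#' @return list of class `friedman_result`: `chi2`, `df`, `p`, `n_blocks`,
#'   `untestable`. Uses midranks and the tie-corrected chi-square
#'   approximation. Fewer than 3 usable blocks flags the region untestable
#'   (no p emitted).
#' @export
friedman_compare <- function(traces_by_group) {
  k <- length(traces_by_group)
  if (k < 2) stopf("need at least 2 groups")
  nb <- unique(vapply(traces_by_group, ncol, 1L))
  if (length(nb) != 1) stopf("groups must share the bin grid")
  means <- vapply(traces_by_group, colMeans, numeric(nb))  # blocks x groups
  n <- nrow(means)
  if (n < 3) {
    return(structure(list(chi2 = NA_real_, df = k - 1L, p = NA_real_,
                          n_blocks = n, untestable = TRUE),
                     class = "friedman_result"))
  }
  R <- t(apply(means, 1, rank))                            # midranks per block
  Rj <- colSums(R)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ## tie correction (scipy-style): c = 1 - sum(t^3 - t) / (n (k^3 - k))
  ties <- sum(apply(means, 1, function(row) {
    tb <- table(row); sum(tb^3 - tb)
  }))
  cc <- 1 - ties / (n * (k^3 - k))
  if (cc > 0) chi2 <- chi2 / cc else chi2 <- 0
  chi2 <- max(chi2, 0)
  p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = k - 1L, p = p, n_blocks = n,
                 untestable = FALSE),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  if (x$untestable)
    cat(sprintf("Friedman: untestable (%d blocks)\n", x$n_blocks))
  else
    cat(sprintf("Friedman: chi2 = %.4g, df = %d, p = %.4g (%d blocks)\n",
                x$chi2, x$df, x$p, x$n_blocks))
  invisible(x)
}

#' Bonferroni-adjusted pairwise post hoc tests
#'
#' Two-sided Wilcoxon signed-rank on the bin-matched group-mean traces for
#' every group pair; each p is multiplied by the number of pairs and capped
#' at 1. A pair with identical mean traces (all differences zero) carries no
#' evidence and reports adjusted p = 1. Intended to be run only when the
#' Friedman test is significant (the caller gates, as in the pipeline).
#'
#' @param traces_by_group named list of matrices (samples x bins).
#' @return data.frame (group_a, group_b, p_raw, p_adj, W).
#' @export
posthoc_pairwise <- function(traces_by_group) {
  k <- length(traces_by_group)
  nms <- names(traces_by_group) %||% as.character(seq_len(k))
  means <- lapply(traces_by_group, colMeans)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group_a = nms[pairs[1, ]], group_b = nms[pairs[2, ]],
                    p_raw = NA_real_, p_adj = NA_real_, W = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    wr <- wilcoxon_exact(means[[pairs[1, j]]], means[[pairs[2, j]]])
    p <- if (is.na(wr$p)) 1 else wr$p      # identical traces: no evidence
    out$p_raw[j] <- p
    out$p_adj[j] <- min(1, p * m)
    out$W[j] <- wr$W
  }
  out
}

#' Summed average pairwise difference ("sum of delta")
#'
#' For all |A| x |B| ordered sample pairs, per-bin differences (A - B) are
#' averaged over pairs and summed over bins. Algebraically this equals
#' sum over bins of (mean A - mean B); both routes are computed and
#' cross-checked.
#'
#' @param traces_a,traces_b matrices (samples x bins) on a shared grid.
#' @return list of class `delta_summary`: `sum_delta`, `per_bin` (mean
#'   difference trace).
#' @export
sum_of_delta <- function(traces_a, traces_b) {
  if (ncol(traces_a) != ncol(traces_b)) stopf("bin grids differ")
  per_bin <- colMeans(traces_a) - colMeans(traces_b)
  ## explicit all-pairs route as an internal cross-check
  na <- nrow(traces_a); nbm <- nrow(traces_b)
  acc <- numeric(ncol(traces_a))
  for (i in seq_len(na)) acc <- acc + colSums(
    sweep(traces_b, 2, traces_a[i, ], FUN = function(b, a) a - b))
  pairwise <- acc / (na * nbm)
  if (max(abs(pairwise - per_bin)) > 1e-8 * max(1, max(abs(per_bin))))
    stopf("internal inconsistency in sum_of_delta")
  structure(list(sum_delta = sum(per_bin), per_bin = per_bin),
            class = "delta_summary")
}

#' Structure-wise comparison over a whole cohort
#'
#' Runs the region filters, the Friedman test, post hocs (gated at Friedman
#' p < 0.05) and the summed-difference metric for every retained region.
#'
#' @param cohort a `cohort`.
#' @param signal "ochief" (two genotype groups) or "cfos" (four groups).
#' @param side hemisphere to analyze.
#' @param alpha Friedman gate for post hocs.
#' @return data.frame, one row per retained region, with chi2/df/p,
#'   sum_delta (first vs second group), and for c-Fos the Bonferroni-adjusted
#'   post hoc p per group pair in wide columns.
#' @export
structurewise_compare <- function(cohort, signal = c("ochief", "cfos"),
                                  side = c("contra", "ipsi"), alpha = 0.05) {
  signal <- match.arg(signal); side <- match.arg(side)
  ids <- if (signal == "ochief") select_regions_ochief(cohort, side)
         else intersect(select_regions_cfos(cohort),
                        cohort$regions$region_id[cohort$regions$hemisphere == side])
  groups <- if (signal == "ochief") c("WT", "Tbr1het") else .groups
  pair_cols <- if (signal == "cfos") {
    pr <- utils::combn(groups, 2)
    paste0("p_adj_", pr[1, ], "_vs_", pr[2, ])
  } else character(0)
  rows <- lapply(ids, function(rid) {
    tr <- lapply(groups, function(g) cohort_traces(cohort, rid, signal, g))
    names(tr) <- groups
    fr <- friedman_compare(tr)
    sd1 <- sum_of_delta(tr[[2]], tr[[1]])   # mutant minus WT / later vs first
    row <- data.frame(region_id = rid,
                      hemisphere = side,
                      chi2 = fr$chi2, df = fr$df, p = fr$p,
                      sum_delta = sd1$sum_delta,
                      stringsAsFactors = FALSE)
    for (pc in pair_cols) row[[pc]] <- NA_real_
    if (signal == "cfos" && !fr$untestable && !is.na(fr$p) && fr$p < alpha) {
      ph <- posthoc_pairwise(tr)
      for (j in seq_len(nrow(ph)))
        row[[paste0("p_adj_", ph$group_a[j], "_vs_", ph$group_b[j])]] <- ph$p_adj[j]
    }
    row
  })
  if (!length(rows)) return(data.frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
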