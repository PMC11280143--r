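## Rewiring vs activity-modulation correlation classifier -----------------
##
## Per region: difference traces of the axon label between genotypes
## (delta-oChIEF), stimulation-response difference traces per genotype
## (delta-c-Fos), and their second difference (delta-delta-c-Fos). The
## Pearson correlation between the mean delta-oChIEF and mean
## delta-delta-c-Fos trace is classified as positive / negative / none by
## three criteria: (1) r beyond the one-sided 95% band of an AP-reshuffled
## null, (2) |r| > 0.1, (3) the product of the two trace "tendencies"
## (signed sums of scaled values exceeding the reshuffled 99th-percentile
## threshold) has the matching sign.

#' All pairwise difference traces between two sample groups
#'
#' @param traces_a,traces_b matrices (samples x bins) on a shared grid.
#' @return list of class `delta_trace_set`: `pair_traces`
#'   (|A| x |B| rows, one per ordered pair a_i - b_j), `mean_trace`.
#' @export
delta_traces <- function(traces_a, traces_b) {
  if (ncol(traces_a) != ncol(traces_b)) stopf("bin grids differ")
  na <- nrow(traces_a); nb <- nrow(traces_b)
  pairs <- matrix(0, na * nb, ncol(traces_a))
  k <- 0L
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    k <- k + 1L
    pairs[k, ] <- traces_a[i, ] - traces_b[j, ]
  }
  structure(list(pair_traces = pairs, mean_trace = colMeans(pairs)),
            class = "delta_trace_set")
}

#' Second-difference traces (delta-delta)
#'
#' All pairwise differences between two delta-trace sets (every mutant
#' stimulation-difference trace minus every WT one).
#'
#' @param tbr1_deltas,wt_deltas `delta_trace_set`s on a shared grid.
#' @return a `delta_trace_set`.
#' @export
ddcfos <- function(tbr1_deltas, wt_deltas) {
  delta_traces(tbr1_deltas$pair_traces, wt_deltas$pair_traces)
}

#' Pearson correlation between two mean traces
#'
#' @param mean_dochief,mean_ddcfos numeric traces on a shared grid.
#' @return Pearson r over the overlapping finite bins; NA if fewer than 3
#'   such bins or either trace has zero variance.
#' @export
correlate_region <- function(mean_dochief, mean_ddcfos) {
  ok <- is.finite(mean_dochief) & is.finite(mean_ddcfos)
  if (sum(ok) < 3) return(NA_real_)
  x <- mean_dochief[ok]; y <- mean_ddcfos[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' AP-reshuffled null for one region
#'
#' Each of `n_shuffles` draws reshuffles the AP-bin order of the three trace
#' families (delta-oChIEF, WT delta-c-Fos, mutant delta-c-Fos) independently
#' of each other, recomputes the mean traces and their Pearson r (the
#' `r_shuffled` distribution), and records the 99th percentile of the
#' absolute scaled shuffled mean traces; the tendency threshold of a family
#' is the mean of those percentiles over shuffles. Scaling divides by the
#' maximum absolute value of the observed mean trace.
#'
#' With the default `mode = "family"` one bin permutation is drawn per
#' family per shuffle and applied to all its traces, so the null permutes
#' the alignment of the observed mean traces — an exact permutation null
#' for independence that preserves each trace's value distribution (signal
#' magnitude varies along the AP axis, and a valid null must keep that
#' profile). `mode = "per_trace"` instead permutes every pair trace
#' independently; it shrinks the shuffled means toward zero and is
#' anti-conservative, and is kept only for comparison.
#'
#' @param dochief_pairs,wt_dcfos_pairs,tbr1_dcfos_pairs pair-trace matrices
#'   (rows = pairs, cols = AP bins) on a shared grid.
#' @param n_shuffles number of reshuffles (>= 100; default 1000).
#' @param seed integer seed.
#' @param mode "family" (default) or "per_trace"; see Details.
#' @return list of class `reshuffle_null`: `r_obs`, `r_shuffled`,
#'   `mean_dochief`, `mean_ddcfos`, `tendency_threshold_ochief`,
#'   `tendency_threshold_ddcfos`, `tendency_ochief`, `tendency_ddcfos`
#'   (signed), `degenerate`.
#' @export
reshuffle_null <- function(dochief_pairs, wt_dcfos_pairs, tbr1_dcfos_pairs,
                           n_shuffles = 1000, seed,
                           mode = c("family", "per_trace")) {
  mode <- match.arg(mode)
  if (n_shuffles < 100) stopf("n_shuffles must be >= 100")
  mean_do <- colMeans(dochief_pairs)
  mean_dd <- colMeans(tbr1_dcfos_pairs) - colMeans(wt_dcfos_pairs)
  scale_do <- max(abs(mean_do)); scale_dd <- max(abs(mean_dd))
  degenerate <- scale_do == 0 || scale_dd == 0 ||
    sd(mean_do) == 0 || sd(mean_dd) == 0
  r_obs <- correlate_region(mean_do, mean_dd)
  if (degenerate) {
    warnf("constant difference traces; reshuffled null is degenerate")
    return(structure(list(r_obs = r_obs, r_shuffled = rep(NA_real_, n_shuffles),
                          mean_dochief = mean_do, mean_ddcfos = mean_dd,
                          tendency_threshold_ochief = NA_real_,
                          tendency_threshold_ddcfos = NA_real_,
                          tendency_ochief = 0, tendency_ddcfos = 0,
                          degenerate = TRUE),
                     class = "reshuffle_null"))
  }
  nb <- length(mean_do)
  res <- with_seed(seed, {
    if (mode == "family") {
      ## one permutation per family per shuffle: means commute, so permute
      ## the observed mean traces directly
      mwt_obs <- colMeans(wt_dcfos_pairs)
      mtb_obs <- colMeans(tbr1_dcfos_pairs)
      mdo <- t(vapply(seq_len(n_shuffles), function(s) mean_do[sample.int(nb)],
                      numeric(nb)))
      mwt <- t(vapply(seq_len(n_shuffles), function(s) mwt_obs[sample.int(nb)],
                      numeric(nb)))
      mtb <- t(vapply(seq_len(n_shuffles), function(s) mtb_obs[sample.int(nb)],
                      numeric(nb)))
      list(mdo = mdo, mdd = mtb - mwt)
    } else {
      mdo <- cpp_row_permuted_means(dochief_pairs, n_shuffles)
      mwt <- cpp_row_permuted_means(wt_dcfos_pairs, n_shuffles)
      mtb <- cpp_row_permuted_means(tbr1_dcfos_pairs, n_shuffles)
      list(mdo = mdo, mdd = mtb - mwt)
    }
  })
  r_sh <- vapply(seq_len(n_shuffles), function(s)
    correlate_region(res$mdo[s, ], res$mdd[s, ]), numeric(1))
  if (mode == "family") {
    ## a common bin permutation leaves the per-shuffle 99th percentile of
    ## the |scaled mean trace| unchanged, so the mean over shuffles equals
    ## the observed quantile; computed directly
    thr_do <- as.numeric(quantile(abs(mean_do / scale_do), 0.99))
    thr_dd <- as.numeric(quantile(abs(mean_dd / scale_dd), 0.99))
  } else {
    q99 <- function(m, sc) mean(apply(abs(m / sc), 1, quantile, 0.99))
    thr_do <- q99(res$mdo, scale_do)
    thr_dd <- q99(res$mdd, scale_dd)
  }
  structure(list(r_obs = r_obs, r_shuffled = r_sh,
                 mean_dochief = mean_do, mean_ddcfos = mean_dd,
                 tendency_threshold_ochief = thr_do,
                 tendency_threshold_ddcfos = thr_dd,
                 tendency_ochief = trace_tendency(mean_do, scale_do, thr_do),
                 tendency_ddcfos = trace_tendency(mean_dd, scale_dd, thr_dd),
                 degenerate = FALSE),
            class = "reshuffle_null")
}

#' Signed tendency of a scaled trace
#'
#' Sum of the scaled trace values whose absolute value exceeds the tendency
#' threshold; 0 when none exceed it (no tendency).
#'
#' @param mean_trace numeric trace.
#' @param scale max-|value| normalizer (0 gives tendency 0).
#' @param threshold tendency threshold on the scaled trace.
#' @return a signed number (possibly 0).
#' @export
trace_tendency <- function(mean_trace, scale, threshold) {
  if (!is.finite(scale) || scale == 0 || !is.finite(threshold)) return(0)
  v <- mean_trace / scale
  sum(v[abs(v) > threshold])
}

#' Apply the three-criterion correlation classification
#'
#' @param null a `reshuffle_null`.
#' @param r_cut absolute-r cutoff (0.1).
#' @param null_pct one-sided band of the reshuffled r distribution (0.95).
#' @return list of class `corr_classification`: `r`, `class` in
#'   {"positive", "negative", "none"}, the criterion values.
#' @export
classify_correlation <- function(null, r_cut = 0.1, null_pct = 0.95) {
  r <- null$r_obs
  tend <- null$tendency_ochief * null$tendency_ddcfos
  cls <- "none"
  if (!is.na(r) && !null$degenerate) {
    qs <- quantile(null$r_shuffled, c(1 - null_pct, null_pct), na.rm = TRUE)
    if (r > qs[2] && r > r_cut && tend > 0) cls <- "positive"
    else if (r < qs[1] && r < -r_cut && tend < 0) cls <- "negative"
  }
  structure(list(r = r, class = cls,
                 tendency_ochief = null$tendency_ochief,
                 tendency_ddcfos = null$tendency_ddcfos,
                 tendency_product = tend,
                 r_null_quantiles = if (null$degenerate) c(NA_real_, NA_real_)
                   else quantile(null$r_shuffled,
                                 c(1 - null_pct, null_pct), na.rm = TRUE)),
            class = "corr_classification")
}

#' Full rewiring-correlation analysis of a cohort
#'
#' Region gate: axon-label Friedman p < 0.05 (WT vs mutant) AND adjusted
#' post hoc p < 0.05 in either TBS-vs-ctrl c-Fos comparison. Classified per
#' region with the reshuffled null.
#'
#' @param cohort a `cohort`.
#' @param side hemisphere.
#' @param n_shuffles reshuffles per region.
#' @param seed integer seed (per-region seeds are derived from it).
#' @param alpha gate significance level.
#' @return data.frame (region_id, hemisphere, sum_dochief, r, class,
#'   tendency_product).
#' @export
rewire_analysis <- function(cohort, side = c("contra", "ipsi"),
                            n_shuffles = 1000, seed, alpha = 0.05) {
  side <- match.arg(side)
  och <- structurewise_compare(cohort, "ochief", side)
  cfs <- structurewise_compare(cohort, "cfos", side)
  gate_cols <- c("p_adj_WT_ctrl_vs_WT_TBS", "p_adj_WT_TBS_vs_WT_ctrl",
                 "p_adj_Tbr1het_ctrl_vs_Tbr1het_TBS",
                 "p_adj_Tbr1het_TBS_vs_Tbr1het_ctrl")
  gate_cols <- intersect(gate_cols, names(cfs))
  cf_sig <- if (nrow(cfs)) cfs$region_id[
    apply(cfs[, gate_cols, drop = FALSE], 1,
          function(x) any(!is.na(x) & x < alpha))] else integer(0)
  ids <- intersect(och$region_id[!is.na(och$p) & och$p < alpha], cf_sig)
  rows <- lapply(ids, function(rid) {
    do_pairs <- delta_traces(cohort_traces(cohort, rid, "ochief", "Tbr1het"),
                             cohort_traces(cohort, rid, "ochief", "WT"))
    wt_d <- delta_traces(cohort_traces(cohort, rid, "cfos", "WT_TBS"),
                         cohort_traces(cohort, rid, "cfos", "WT_ctrl"))
    tb_d <- delta_traces(cohort_traces(cohort, rid, "cfos", "Tbr1het_TBS"),
                         cohort_traces(cohort, rid, "cfos", "Tbr1het_ctrl"))
    nl <- reshuffle_null(do_pairs$pair_traces, wt_d$pair_traces,
                         tb_d$pair_traces, n_shuffles = n_shuffles,
                         seed = derive_seed(seed, "rewire") + rid)
    cl <- classify_correlation(nl)
    data.frame(region_id = rid, hemisphere = side,
               sum_dochief = sum(do_pairs$mean_trace),
               r = cl$r, class = cl$class,
               tendency_product = cl$tendency_product,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(region_id = integer(0), hemisphere = character(0),
                      sum_dochief = numeric(0), r = numeric(0),
                      class = character(0), tendency_product = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
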