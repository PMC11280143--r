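## Atlas compartmentalization and region filters --------------------------
##
## Positive pixels / detected cells are assigned to the region whose label
## covers their coordinate, counted per slice, binned along the AP axis
## (100-um half-open bins, slice AP coordinate = anterior face), and run
## through the region-selection filters: a 13 x SD total-signal filter with
## a 20th-percentile mutant floor for the axon label, a > 100-cell total
## filter for c-Fos, and an 800 cells/mm^3 density exclusion with WT-ctrl
## normalization for the network stage.

#' Compartmentalize signal into atlas regions
#'
#' @param mask_stack list of integer label matrices (one per slice), 0 =
#'   background.
#' @param signal either a list of logical/numeric matrices with the same
#'   shape (binary axon masks) or a `spot_list` from [detect_spots()] (its
#'   `pixel_um` attribute maps um coordinates back to pixels).
#' @return data.frame (region_id, slice, count); region_id 0 collects
#'   events on background.
#' @export
compartmentalize <- function(mask_stack, signal) {
  mask_stack <- .as_stack(mask_stack)
  if (inherits(signal, "spot_list")) {
    px <- attr(signal, "pixel_um")
    counts <- list()
    for (sl in unique(signal$slice)) {
      if (sl < 1 || sl > length(mask_stack))
        stopf("spot slice %d outside mask stack (1..%d)", sl, length(mask_stack))
      mk <- mask_stack[[sl]]
      sub <- signal[signal$slice == sl, ]
      ri <- pmin(pmax(floor(sub$y_um / px) + 1L, 1L), nrow(mk))
      ci <- pmin(pmax(floor(sub$x_um / px) + 1L, 1L), ncol(mk))
      lab <- mk[cbind(ri, ci)]
      tb <- table(lab)
      counts[[length(counts) + 1]] <- data.frame(
        region_id = as.integer(names(tb)), slice = sl,
        count = as.integer(tb))
    }
    out <- if (length(counts)) do.call(rbind, counts)
           else data.frame(region_id = integer(0), slice = integer(0),
                           count = integer(0))
  } else {
    signal <- .as_stack(signal)
    if (length(signal) != length(mask_stack))
      stopf("mask and signal stacks differ in length (%d vs %d)",
            length(mask_stack), length(signal))
    counts <- lapply(seq_along(mask_stack), function(sl) {
      mk <- mask_stack[[sl]]; sg <- signal[[sl]]
      if (!all(dim(mk) == dim(sg)))
        stopf("mask and signal shapes differ on slice %d", sl)
      pos <- which(as.logical(sg))
      if (!length(pos)) return(NULL)
      tb <- table(mk[pos])
      data.frame(region_id = as.integer(names(tb)), slice = sl,
                 count = as.integer(tb))
    })
    counts <- counts[!vapply(counts, is.null, TRUE)]
    out <- if (length(counts)) do.call(rbind, counts)
           else data.frame(region_id = integer(0), slice = integer(0),
                           count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Bin per-slice counts along the AP axis
#'
#' The AP coordinate of slice `s` is its anterior face
#' `(s - 1) * ap_step_um + ap_origin_um`; bins are half-open
#' \[start, start + width). Totals are conserved exactly.
#'
#' @param slice_counts data.frame (slice, count) for one region.
#' @param ap_step_um slice spacing.
#' @param bin_width_um bin width (default 100).
#' @param ap_origin_um AP coordinate of slice 1.
#' @param n_slices total slices (fixes the grid even for empty traces).
#' @return list (`bin_starts_um`, `values`).
#' @export
bin_trace <- function(slice_counts, ap_step_um, bin_width_um = 100,
                      ap_origin_um = 0, n_slices = NULL) {
  n_slices <- n_slices %||% if (nrow(slice_counts)) max(slice_counts$slice) else 1L
  ap_max <- ap_origin_um + (n_slices - 1L) * ap_step_um
  b0 <- floor(ap_origin_um / bin_width_um) * bin_width_um
  starts <- seq(b0, by = bin_width_um,
                length.out = floor((ap_max - b0) / bin_width_um) + 1L)
  values <- numeric(length(starts))
  if (nrow(slice_counts)) {
    ap <- ap_origin_um + (slice_counts$slice - 1L) * ap_step_um
    bi <- floor((ap - b0) / bin_width_um) + 1L
    agg <- tapply(slice_counts$count, bi, sum)
    values[as.integer(names(agg))] <- agg
  }
  list(bin_starts_um = starts, values = values)
}

.region_totals <- function(cohort, signal, side = NULL, genotype = NULL) {
  reg <- cohort$regions
  keep <- if (is.null(side)) rep(TRUE, nrow(reg)) else reg$hemisphere == side
  ids <- reg$region_id[keep]
  srows <- if (is.null(genotype)) rep(TRUE, nrow(cohort$samples))
           else cohort$samples$genotype == genotype
  vapply(as.character(ids), function(r)
    sum(cohort[[signal]][[r]][srows, , drop = FALSE]), numeric(1))
}

#' Region filter for axon-label comparisons
#'
#' A region on the requested side is retained iff its total signal summed
#' over both genotypes exceeds 13 x SD of the pooled per-bin axon pixel
#' counts of all contralateral regions (all samples and AP bins pooled; the
#' same SD is reused when filtering the ipsilateral side) AND its
#' mutant-genotype total strictly exceeds the 20th percentile of the mutant
#' per-region totals on that side.
#'
#' The SD reference is the distribution of the quantification unit (binned
#' pixel counts), not of per-region totals: a total-based SD scales with the
#' largest region's total itself (13 x SD > total whenever fewer than ~170
#' regions exist), which would make the filter drop every region at toy
#' scale and contradicts its purpose as a low-signal floor.
#'
#' @param cohort a `cohort`.
#' @param side "contra" or "ipsi".
#' @param sd_multiplier,percentile filter constants (13, 0.20).
#' @return integer vector of retained region ids.
#' @export
select_regions_ochief <- function(cohort, side = c("contra", "ipsi"),
                                  sd_multiplier = 13, percentile = 0.20) {
  side <- match.arg(side)
  tot <- .region_totals(cohort, "ochief", side = side)
  tot_het <- .region_totals(cohort, "ochief", side = side, genotype = "Tbr1het")
  contra_ids <- cohort$regions$region_id[cohort$regions$hemisphere == "contra"]
  pooled <- unlist(lapply(as.character(contra_ids),
                          function(r) as.vector(cohort$ochief[[r]])))
  sd_ref <- sd(pooled)
  if (!is.finite(sd_ref)) sd_ref <- 0
  q20 <- as.numeric(quantile(tot_het, percentile, type = 7))
  ids <- cohort$regions$region_id[cohort$regions$hemisphere == side]
  ids[tot > sd_multiplier * sd_ref & tot_het > q20]
}

#' Region filter for c-Fos comparisons
#'
#' Retains regions whose c-Fos cell total summed over all four groups is
#' strictly greater than `min_cells` (default 100).
#'
#' @param cohort a `cohort`.
#' @param min_cells threshold (strict >).
#' @return integer vector of retained region ids.
#' @export
select_regions_cfos <- function(cohort, min_cells = 100) {
  tot <- .region_totals(cohort, "cfos")
  cohort$regions$region_id[tot > min_cells]
}

#' Volume-based c-Fos density table
#'
#' Density = total cells / region volume (cells/mm^3). Regions whose density
#' summed over all samples is below `density_exclusion` are dropped; the
#' relative density divides by the WT-ctrl group mean, so WT-ctrl averages 1
#' per retained region. Regions with zero WT-ctrl mean are dropped with a
#' warning rather than producing infinities.
#'
#' @param cohort a `cohort`.
#' @param density_exclusion raw-density exclusion threshold (800 cells/mm^3).
#' @param exclude_regions optional region ids to drop up front (e.g. the
#'   injection-site artifact list).
#' @return list of class `density_table`: `density` and `relative` (samples
#'   x regions matrices), `regions` (retained catalog rows), `samples`.
#' @export
cfos_density <- function(cohort, density_exclusion = 800,
                         exclude_regions = integer(0)) {
  dens <- cohort$density
  keep_ids <- setdiff(as.integer(colnames(dens)), exclude_regions)
  dens <- dens[, as.character(keep_ids), drop = FALSE]
  keep <- colSums(dens) >= density_exclusion
  dens <- dens[, keep, drop = FALSE]
  wt_ctrl <- cohort$samples$group == "WT_ctrl"
  ref <- colMeans(dens[wt_ctrl, , drop = FALSE])
  if (any(ref == 0)) {
    warnf("dropping %d region(s) with zero WT-ctrl mean density",
          sum(ref == 0))
    dens <- dens[, ref > 0, drop = FALSE]
    ref <- ref[ref > 0]
  }
  rel <- sweep(dens, 2, ref, "/")
  structure(list(density = dens, relative = rel,
                 regions = cohort$regions[
                   match(as.integer(colnames(dens)), cohort$regions$region_id), ],
                 samples = cohort$samples),
            class = "density_table")
}
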