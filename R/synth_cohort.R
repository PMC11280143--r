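## Synthetic cohorts ------------------------------------------------------
##
## Generates per-sample, per-region AP-binned axon-label (oChIEF) traces and
## c-Fos traces/densities with known ground truth: genotype-dependent
## contralateral loss / ipsilateral gain of axon signal, group offsets on
## c-Fos density, sample-level latent factors that plant interregional
## correlation communities, and optional regions where the axon-rewiring
## effect and the stimulation response share the same AP profile (coupled
## regions for the rewiring classifier).

.groups <- c("WT_ctrl", "Tbr1het_ctrl", "WT_TBS", "Tbr1het_TBS")

#' Describe a synthetic cohort
#'
#' Defaults are the study conditions: group sizes 6/7/7/7
#' (WT ctrl / het ctrl / WT TBS / het TBS), negative-binomial counts with
#' variance inflation `dispersion = 2`, and for the mutant genotype a
#' contralateral axon-signal multiplier of 0.1 (near-complete loss) and an
#' ipsilateral multiplier of 2 (gain/mistargeting). Passing
#' `contra_mult = 1, ipsi_mult = 1` with zero offsets and no latent factors
#' yields the null configuration used for calibration.
#'
#' @param n_per_group named integer vector over the four groups.
#' @param ochief_base expected axon-label pixels per bin at the profile peak.
#' @param cfos_base_density baseline c-Fos density (cells/mm^3).
#' @param dispersion variance/mean ratio of the count noise (>= 1; 1 =
#'   Poisson).
#' @param contra_mult,ipsi_mult mutant-genotype multipliers on the axon-label
#'   mean, by hemisphere.
#' @param cfos_group_log_offsets named numeric over groups, added to
#'   log-density in every region.
#' @param sample_scale_sd lognormal sd of per-sample axon labeling efficiency.
#' @param cfos_noise_sd sd of the per-region, per-sample residual on
#'   log-density.
#' @param latent NULL or `list(communities = <list of region-id vectors>,
#'   loading = <numeric>)`; each community gets one N(0,1) factor per sample
#'   multiplying the loading on log-density.
#' @param coupled region ids whose rewiring and stimulation-response effects
#'   share the region's AP profile (planted positive coupling).
#' @param coupling_ochief,coupling_cfos effect sizes for coupled regions:
#'   extra mutant axon multiplier and extra mutant-TBS log-density offset.
#' @return a list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(WT_ctrl = 6, Tbr1het_ctrl = 7,
                                          WT_TBS = 7, Tbr1het_TBS = 7),
                          ochief_base = 200, cfos_base_density = 2000,
                          dispersion = 2, contra_mult = 0.1, ipsi_mult = 2,
                          cfos_group_log_offsets = c(WT_ctrl = 0, Tbr1het_ctrl = 0,
                                                     WT_TBS = 0, Tbr1het_TBS = 0),
                          sample_scale_sd = 0.15, cfos_noise_sd = 0.3,
                          latent = NULL, coupled = integer(0),
                          coupling_ochief = 2.5, coupling_cfos = 0.8) {
  stopifnot(all(.groups %in% names(n_per_group)))
  if (any(n_per_group < 3)) stopf("need >= 3 samples per group")
  if (dispersion < 1) stopf("dispersion must be >= 1")
  if (!is.null(latent)) {
    if (!is.list(latent$communities) || any(lengths(latent$communities) < 3))
      stopf("every planted community needs >= 3 regions")
    if (latent$loading < 0) stopf("latent loading must be >= 0")
  }
  if (contra_mult < 0 || ipsi_mult < 0) stopf("multipliers must be >= 0")
  structure(as.list(environment()), class = "cohort_design")
}

.rcounts <- function(n, mu, dispersion) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    if (dispersion > 1)
      out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / (dispersion - 1))
    else
      out[pos] <- stats::rpois(sum(pos), mu[pos])
  }
  out
}

#' Simulate a cohort of AP-binned traces and densities
#'
#' @param atlas a [make_atlas()] atlas (only the catalog is used; traces are
#'   generated directly on the 100-um bin grid of each region).
#' @param design a [cohort_design()].
#' @param seed integer seed; identical (atlas, design, seed) reproduce the
#'   cohort exactly.
#' @param bin_width_um trace bin width (100 um).
#' @return object of class `cohort`: `samples` (data.frame), `regions`
#'   (atlas catalog), `ochief` / `cfos` (per-region matrices samples x bins
#'   with a `bin_starts` attribute), `density` (samples x regions matrix of
#'   cells/mm^3), `truth` (planted ground truth).
#' @export
simulate_cohort <- function(atlas, design = cohort_design(), seed,
                            bin_width_um = 100) {
  reg <- atlas$regions
  ng <- design$n_per_group[.groups]
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(sum(ng))),
    group = rep(.groups, ng),
    stringsAsFactors = FALSE
  )
  samples$genotype <- ifelse(grepl("^WT", samples$group), "WT", "Tbr1het")
  samples$stim <- ifelse(grepl("TBS$", samples$group), "TBS", "ctrl")
  ns <- nrow(samples)
  nr <- nrow(reg)

  ## region membership in planted communities (0 = none)
  community <- setNames(integer(nr), reg$region_id)
  if (!is.null(design$latent))
    for (k in seq_along(design$latent$communities))
      community[as.character(design$latent$communities[[k]])] <- k

  with_seed(seed, {
    ## shared AP profile per region, aligned to the 100-um grid
    bin_grid <- lapply(seq_len(nr), function(i) {
      b0 <- floor(reg$ap_start_um[i] / bin_width_um) * bin_width_um
      nb <- max(3L, ceiling((reg$ap_end_um[i] - b0) / bin_width_um))
      seq(b0, by = bin_width_um, length.out = nb)
    })
    ## independent AP profiles for the two signals: axon innervation is a
    ## focal bump; the c-Fos cell distribution is a broad, separately
    ## located bump. Under zero effects the two signals must share no
    ## magnitude pattern, or the "null" would plant a coupling.
    bump <- function(nb, smin, smax) {
      mu <- runif(1, 1, nb); s <- runif(1, smin * nb, smax * nb)
      p <- exp(-((seq_len(nb) - mu)^2) / (2 * s^2))
      p / max(p)
    }
    profile <- lapply(bin_grid, function(b) bump(length(b), 1 / 6, 1 / 2))
    profile_c <- lapply(bin_grid, function(b) bump(length(b), 1 / 2, 1))

    scale_s <- rlnorm(ns, 0, design$sample_scale_sd)
    nfac <- if (is.null(design$latent)) 0L else length(design$latent$communities)
    z <- if (nfac) matrix(rnorm(ns * nfac), ns, nfac) else NULL
    if (nfac > 1 && ns > nfac) {
      ## orthogonalize factor scores so planted communities are exactly
      ## independent (no chance inter-factor correlation across samples)
      z <- scale(z, center = TRUE, scale = FALSE)
      z <- qr.Q(qr(z)) * sqrt(ns - 1)
    }

    ochief_mult <- ifelse(reg$hemisphere == "contra",
                          design$contra_mult, design$ipsi_mult)
    ochief_mult[reg$region_id %in% design$coupled] <-
      design$coupling_ochief
    names(ochief_mult) <- reg$region_id

    off <- design$cfos_group_log_offsets[.groups]
    ochief <- cfos <- setNames(vector("list", nr), reg$region_id)
    density <- matrix(0, ns, nr, dimnames = list(samples$sample_id, reg$region_id))
    for (i in seq_len(nr)) {
      nb <- length(bin_grid[[i]])
      pr <- profile[[i]]
      om <- matrix(0L, ns, nb, dimnames = list(samples$sample_id, NULL))
      cm <- matrix(0L, ns, nb, dimnames = list(samples$sample_id, NULL))
      pshare_o <- pr / sum(pr)
      pshare_c <- profile_c[[i]] / sum(profile_c[[i]])
      coupled_here <- reg$region_id[i] %in% design$coupled
      for (s in seq_len(ns)) {
        mult <- if (samples$genotype[s] == "Tbr1het") ochief_mult[i] else 1
        mu_o <- design$ochief_base * pr * mult * scale_s[s]
        om[s, ] <- .rcounts(nb, mu_o, design$dispersion)

        lo <- log(design$cfos_base_density) + off[[samples$group[s]]] +
          rnorm(1, 0, design$cfos_noise_sd)
        if (nfac && community[i] > 0)
          lo <- lo + design$latent$loading * z[s, community[i]]
        mu_c <- exp(lo) * reg$volume_mm3[i] * pshare_c
        ## coupled regions: the extra mutant-TBS activation is deposited
        ## along the axon-innervation profile (the shared AP shape that the
        ## classifier is meant to detect)
        if (coupled_here && samples$group[s] == "Tbr1het_TBS")
          mu_c <- mu_c + (exp(design$coupling_cfos) - 1) *
            exp(lo) * reg$volume_mm3[i] * pshare_o
        cm[s, ] <- .rcounts(nb, mu_c, design$dispersion)
      }
      attr(om, "bin_starts") <- bin_grid[[i]]
      attr(cm, "bin_starts") <- bin_grid[[i]]
      ochief[[i]] <- om; cfos[[i]] <- cm
      density[, i] <- rowSums(cm) / reg$volume_mm3[i]
    }

    truth <- list(ochief_mult = ochief_mult,
                  cfos_group_log_offsets = off,
                  community = community,
                  coupled = design$coupled,
                  profiles = setNames(profile, reg$region_id))
    structure(list(samples = samples, regions = reg, ochief = ochief,
                   cfos = cfos, density = density, truth = truth,
                   bin_width_um = bin_width_um),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples (%s), %d regions, %g-um bins\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", "),
              nrow(x$regions), x$bin_width_um))
  invisible(x)
}

#' Extract the trace matrix of one region for a set of samples
#'
#' @param cohort a `cohort`.
#' @param region_id region id.
#' @param signal "ochief" or "cfos".
#' @param group optional group label or genotype ("WT"/"Tbr1het") filter.
#' @return matrix samples x bins with `bin_starts` attribute.
#' @export
cohort_traces <- function(cohort, region_id, signal = c("ochief", "cfos"),
                          group = NULL) {
  signal <- match.arg(signal)
  m <- cohort[[signal]][[as.character(region_id)]]
  if (is.null(m)) stopf("unknown region id %s", region_id)
  if (!is.null(group)) {
    keep <- if (group %in% c("WT", "Tbr1het")) cohort$samples$genotype == group
            else cohort$samples$group == group
    bs <- attr(m, "bin_starts")
    m <- m[keep, , drop = FALSE]
    attr(m, "bin_starts") <- bs
  }
  m
}

#' Write / read a cohort as plain-text CSV
#'
#' Long format, one row per (sample, region, bin):
#' `sample_id, region_id, hemisphere, ap_bin_start_um, ochief_pixels,
#' cfos_cells`, plus a `<stem>_samples.csv` metadata table and an optional
#' `<stem>_truth.json`.
#'
#' @param cohort a `cohort`.
#' @param stem path stem (files `<stem>_traces.csv`, `<stem>_samples.csv`,
#'   `<stem>_regions.csv`, `<stem>_truth.json`).
#' @return `stem`, invisibly.
#' @export
write_cohort <- function(cohort, stem) {
  rows <- lapply(seq_len(nrow(cohort$regions)), function(i) {
    rid <- cohort$regions$region_id[i]
    om <- cohort$ochief[[as.character(rid)]]
    cm <- cohort$cfos[[as.character(rid)]]
    bs <- attr(om, "bin_starts")
    data.frame(
      sample_id = rep(rownames(om), times = ncol(om)),
      region_id = rid,
      hemisphere = cohort$regions$hemisphere[i],
      ap_bin_start_um = rep(bs, each = nrow(om)),
      ochief_pixels = as.vector(om),
      cfos_cells = as.vector(cm),
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), paste0(stem, "_traces.csv"), row.names = FALSE)
  write.csv(cohort$samples, paste0(stem, "_samples.csv"), row.names = FALSE)
  write.csv(cohort$regions, paste0(stem, "_regions.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(
      cohort$truth[c("ochief_mult", "community", "coupled")],
      paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  tr <- read.csv(paste0(stem, "_traces.csv"), stringsAsFactors = FALSE)
  samples <- read.csv(paste0(stem, "_samples.csv"), stringsAsFactors = FALSE)
  regions <- read.csv(paste0(stem, "_regions.csv"), stringsAsFactors = FALSE)
  ids <- regions$region_id
  ochief <- cfos <- setNames(vector("list", length(ids)), ids)
  density <- matrix(0, nrow(samples), length(ids),
                    dimnames = list(samples$sample_id, ids))
  for (i in seq_along(ids)) {
    sub <- tr[tr$region_id == ids[i], ]
    bs <- sort(unique(sub$ap_bin_start_um))
    om <- cm <- matrix(0L, nrow(samples), length(bs),
                       dimnames = list(samples$sample_id, NULL))
    om[cbind(match(sub$sample_id, samples$sample_id),
             match(sub$ap_bin_start_um, bs))] <- sub$ochief_pixels
    cm[cbind(match(sub$sample_id, samples$sample_id),
             match(sub$ap_bin_start_um, bs))] <- sub$cfos_cells
    attr(om, "bin_starts") <- bs; attr(cm, "bin_starts") <- bs
    ochief[[i]] <- om; cfos[[i]] <- cm
    density[, i] <- rowSums(cm) / regions$volume_mm3[i]
  }
  structure(list(samples = samples, regions = regions, ochief = ochief,
                 cfos = cfos, density = density, truth = NULL,
                 bin_width_um = diff(attr(ochief[[1]], "bin_starts"))[1] %||% 100),
            class = "cohort")
}

#' Simulate paired pre/post behavior durations
#'
#' One row per (mouse, behavior, condition); the TBS arm is the control arm
#' plus a behavior-specific planted shift and paired noise, truncated at 0.
#'
#' @param n_mice number of mice (>= 5).
#' @param behaviors character vector of behavior classes.
#' @param paired_shift named numeric (seconds) added to the TBS arm; behaviors
#'   not named get shift 0.
#' @param seed integer seed.
#' @param baseline_mean_s,baseline_sd_log,pair_noise_s generator scales.
#' @return data.frame (mouse_id, behavior, condition, seconds).
#' @export
simulate_behavior <- function(n_mice = 7,
                              behaviors = c("nose_to_nose", "side_by_side",
                                            "side_reverse_side", "nose_to_tail",
                                            "nose_to_body", "following",
                                            "sniffing", "huddle", "lookaround",
                                            "climbing"),
                              paired_shift = numeric(0), seed,
                              baseline_mean_s = 30, baseline_sd_log = 0.5,
                              pair_noise_s = 4) {
  if (n_mice < 5) stopf("need >= 5 mice")
  with_seed(seed, {
    rows <- list()
    for (b in behaviors) {
      shift <- if (b %in% names(paired_shift)) paired_shift[[b]] else 0
      ctrl <- rlnorm(n_mice, log(baseline_mean_s), baseline_sd_log)
      tbs <- pmax(0, ctrl + shift + rnorm(n_mice, 0, pair_noise_s))
      rows[[b]] <- data.frame(
        mouse_id = rep(sprintf("m%02d", seq_len(n_mice)), 2),
        behavior = b,
        condition = rep(c("ctrl", "TBS"), each = n_mice),
        seconds = c(ctrl, tbs),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
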