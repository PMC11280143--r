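test_that("Kendall tau-b reproduces enumeration examples", {
  ## perfectly concordant pair at n = 7: exact two-sided p = 2/7!
  k <- kendall_cor(1:7, c(2, 4, 6, 8, 10, 12, 14))
  expect_equal(k$tau, 1)
  expect_equal(k$p, 2 / factorial(7))
  ## n = 4 with one discordant pair is nowhere near significant
  k2 <- kendall_cor(1:4, c(1, 2, 4, 3))
  expect_equal(k2$p, 2 * 4 / 24)     # D <= 1: 1 + 3 permutations, both tails
  expect_gt(k2$p, 0.05)
  ## degenerate input
  expect_true(is.na(kendall_cor(1:5, rep(2, 5))$tau))
})

test_that("Kendall exact p agrees with permutation enumeration (100 fixtures)", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:7, 1)
    x <- sample(seq_len(3 * n), n)   # untied
    y <- sample(seq_len(3 * n), n)
    k <- kendall_cor(x, y)
    expect_true(k$exact)
    expect_equal(k$p, kendall_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("tied data switch to the tie-corrected normal approximation", {
  x <- c(1, 1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 2, 2, 5, 4, 6)
  k <- kendall_cor(x, y)
  expect_false(k$exact)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  expect_equal(k$tau, unname(ct$estimate), tolerance = 1e-10)
})

test_that("correlation matrices are symmetric, gated, zero-diagonal", {
  a <- toy_atlas()
  co <- simulate_cohort(a, null_design(7), seed = 71)
  dt <- cfos_density(co)
  cm <- correlation_matrix(dt, "WT_ctrl")
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(0, ncol(cm$r)))
  ut <- upper.tri(cm$r)
  expect_true(all(cm$r[ut][cm$p[ut] >= 0.05] == 0))
  expect_true(all(abs(cm$r) <= 1))
  expect_error(correlation_matrix(dt$relative[1:3, ]), ">= 4 samples")
  ## constant region warns and stays zero
  m <- dt$relative[dt$samples$group == "WT_ctrl", ]
  m[, 2] <- 1
  expect_warning(cm2 <- correlation_matrix(m), "constant")
  expect_true(all(cm2$r[, 2] == 0))
})

test_that("graph construction is threshold-monotone and matches adjacency", {
  a <- toy_atlas()
  co <- simulate_cohort(a, null_design(7, latent = list(
    communities = list(a$regions$region_id[1:4],
                       a$regions$region_id[5:8],
                       a$regions$region_id[9:12]),
    loading = 0.9)), seed = 72)
  cm <- correlation_matrix(cfos_density(co), "WT_ctrl")
  g0 <- build_graph(cm)
  expect_equal(igraph::ecount(g0), sum(cm$r[upper.tri(cm$r)] != 0))
  ## raising |r| threshold never adds edges
  e <- vapply(c(0, 0.2, 0.4, 0.6, 0.8),
              function(r) igraph::ecount(build_graph(cm, r)), 1)
  expect_true(all(diff(e) <= 0))
  ## all-zero matrix -> edgeless graph
  cm0 <- cm; cm0$r[] <- 0; cm0$r_raw[] <- 0
  expect_equal(igraph::ecount(build_graph(cm0)), 0)
  ## hand-built adjacency on a tiny matrix
  r <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  p <- matrix(1, 3, 3, dimnames = dimnames(r))
  r["A", "B"] <- r["B", "A"] <- 0.8; p["A", "B"] <- p["B", "A"] <- 0.01
  cm1 <- structure(list(regions = c("A", "B", "C"), r = r, r_raw = r, p = p,
                        p_max = 0.05), class = "corr_matrix")
  g1 <- build_graph(cm1)
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$weight, 0.8)
})

test_that("node metrics closed forms", {
  gk <- igraph::make_full_graph(6)
  igraph::V(gk)$name <- paste0("v", 1:6)
  nm <- node_metrics(gk)
  expect_equal(nm$DC, rep(1, 6))
  expect_equal(nm$PC, rep(0, 6))         # single community
  ## node with degree 4 split 2/2 across two communities: PC = 0.5
  el <- rbind(c("x", "a1"), c("x", "a2"), c("x", "b1"), c("x", "b2"))
  g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- setNames(c(1, 1, 1, 2, 2), c("x", "a1", "a2", "b1", "b2"))
  nm2 <- node_metrics(g2, memb)
  expect_equal(nm2$PC[nm2$region == "x"], 0.5)
  ## all edges inside own community: PC = 0
  expect_equal(nm2$PC[nm2$region == "a1"], 0)
  ## isolated node: DC = PC = 0
  g3 <- g2 + igraph::vertices("iso")
  nm3 <- node_metrics(g3, c(memb, iso = 1))
  expect_equal(nm3$DC[nm3$region == "iso"], 0)
  expect_equal(nm3$PC[nm3$region == "iso"], 0)
})

test_that("stability sweep is monotone and reproduces the ungated graph", {
  a <- toy_atlas()
  co <- simulate_cohort(a, null_design(7), seed = 73)
  cm <- correlation_matrix(cfos_density(co), "Tbr1het_TBS")
  sw <- stability_sweep(cm, r_grid = c(0, 0.3, 0.6), p_grid = c(0.05, 0.01))
  for (p in unique(sw$p_max)) {
    sub <- sw[sw$p_max == p, ]
    expect_true(all(diff(sub$mean_dc) <= 0))
  }
  ## p_max = 1, r = 0 gives the fully ungated graph
  sw1 <- stability_sweep(cm, r_grid = 0, p_grid = 1)
  g_all <- build_graph(cm, 0, 1)
  expect_equal(sw1$mean_dc,
               mean(igraph::degree(g_all)) / (igraph::vcount(g_all) - 1))
})

test_that("area summaries average gated entries, within and between", {
  r <- matrix(0.5, 4, 4, dimnames = rep(list(c("A1", "A2", "B1", "B2")), 2))
  diag(r) <- 0
  p <- matrix(0.01, 4, 4)
  cm <- structure(list(regions = colnames(r), r = r, r_raw = r, p = p,
                       p_max = 0.05), class = "corr_matrix")
  amap <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  s <- area_summary(cm, amap)
  expect_true(all(s$mean_r == 0.5))
  ## block-diagonal: between-area means are 0 (gated semantics)
  r2 <- r; r2[c("A1", "A2"), c("B1", "B2")] <- 0; r2[c("B1", "B2"), c("A1", "A2")] <- 0
  cm2 <- cm; cm2$r <- r2
  s2 <- area_summary(cm2, amap)
  expect_equal(s2$mean_r[s2$area_a == "A" & s2$area_b == "B"], 0)
  expect_equal(s2$mean_r[s2$area_a == "A" & s2$area_b == "A"], 0.5)
  ## area with a single region has no within mean
  amap2 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "C")
  s3 <- area_summary(cm, amap2)
  expect_true(is.na(s3$mean_r[s3$area_a == "C" & s3$area_b == "C"]))
})

test_that("negative fraction counts significant negatives only", {
  r <- matrix(0, 30, 30)
  idx <- which(upper.tri(r))
  r[idx[1:200]] <- 0.5
  r[idx[1:3]] <- -0.5                       # 3 of 200 significant are negative
  r <- pmax(r, t(r)) + pmin(r, t(r))
  cm <- structure(list(regions = as.character(1:30), r = r, r_raw = r,
                       p = matrix(0.01, 30, 30), p_max = 0.05),
                  class = "corr_matrix")
  expect_equal(negative_fraction(cm), 3 / 200)
  cm$r[cm$r < 0] <- 0.5
  expect_equal(negative_fraction(cm), 0)
  cm$r[cm$r > 0] <- -0.5
  expect_equal(negative_fraction(cm), 1)
})

test_that("subnetwork extraction restricts and preserves gating", {
  a <- toy_atlas()
  co <- simulate_cohort(a, null_design(7), seed = 74)
  cm <- correlation_matrix(cfos_density(co), "WT_TBS")
  keep <- cm$regions[1:5]
  sub <- extract_subnetwork(cm, keep)
  expect_equal(sub$regions, keep)
  expect_equal(sub$r, cm$r[keep, keep])
  ## identity restriction
  full <- extract_subnetwork(cm, cm$regions)
  expect_equal(full$r, cm$r)
  ## missing regions reported, not fatal; empty intersection fatal
  expect_message(extract_subnetwork(cm, c(keep, "nope")), "not in matrix")
  expect_error(extract_subnetwork(cm, c("x", "y")), "none of")
  ## DMN region list is bilateral and prefixed
  expect_length(dmn_regions(), 30)
  ## node metrics on the restricted graph equal metrics on the subgraph
  gs <- build_graph(sub)
  part <- detect_communities(gs, R = 1, seed = 1)
  expect_equal(node_metrics(gs, part),
               node_metrics(build_graph(sub), part))
})

test_that("null edge rate stays near the exact-test size", {
  ## quick version of the calibration property (full run in acceptance)
  a <- toy_atlas()
  rate <- mean(vapply(1:30, function(s) {
    co <- simulate_cohort(a, pure_noise_design(7), seed = 7000 + s)
    m <- cfos_density(co)$relative[co$samples$group == "WT_ctrl", ]
    cnt <- 0L; tot <- 0L
    for (i in 1:(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
      tot <- tot + 1L
      cnt <- cnt + (kendall_cor(m[, i], m[, j])$p < 0.05)
    }
    cnt / tot
  }, 1))
  expect_lt(rate, 0.08)
  expect_gt(rate, 0.005)
})
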