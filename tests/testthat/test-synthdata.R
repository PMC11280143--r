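test_that("make_atlas builds mirrored non-overlapping label masks", {
  dir <- withr::local_tempdir()
  a <- make_atlas(4, 2000, seed = 1, dir = dir)
  expect_equal(nrow(a$regions), 8)
  expect_setequal(a$regions$region_id, 1:8)
  masks <- atlas_masks(a)
  labs <- sort(unique(unlist(lapply(masks, unique))))
  expect_true(all(labs %in% 0:8))
  ## volumes equal voxel count x voxel volume
  vox <- (a$pixel_um / 1000)^2 * (a$ap_step_um / 1000)
  counts <- table(factor(unlist(masks), levels = 1:8))
  expect_equal(a$regions$volume_mm3, as.numeric(counts) * vox, tolerance = 1e-12)
  ## mirrored hemispheres
  w <- ncol(masks[[1]])
  left <- masks[[1]][, 1:(w / 2)]
  right <- masks[[1]][, w:(w / 2 + 1)]
  expect_equal(right[right > 0] - 4, left[left > 0])
})

test_that("make_atlas is byte-deterministic and validates inputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a1 <- make_atlas(6, 1500, seed = 9, dir = d1)
  a2 <- make_atlas(6, 1500, seed = 9, dir = d2)
  expect_identical(readBin(a1$mask_ref, "raw", file.size(a1$mask_ref)),
                   readBin(a2$mask_ref, "raw", file.size(a2$mask_ref)))
  expect_identical(a1$regions, a2$regions)
  expect_error(make_atlas(3, 2000, seed = 1), "at least 4")
  expect_error(make_atlas(8, 500, seed = 1), "10 bins")
  expect_error(make_atlas(97, 2000, seed = 1, hemisphere_width_px = 8),
               "tile")
})

test_that("atlas catalog roundtrips through JSON", {
  dir <- withr::local_tempdir()
  a <- make_atlas(4, 2000, seed = 2, dir = dir)
  p <- file.path(dir, "atlas.json")
  write_atlas(a, p)
  b <- read_atlas(p)
  expect_equal(b$regions, a$regions)
  expect_equal(b$ap_step_um, a$ap_step_um)
})

test_that("null cohort has equal group means and ~zero planted correlation", {
  a <- toy_atlas()
  co <- simulate_cohort(a, null_design(8), seed = 21)
  rid <- as.character(a$regions$region_id[1])
  gm <- vapply(c("WT_ctrl", "Tbr1het_ctrl", "WT_TBS", "Tbr1het_TBS"),
               function(g) sum(cohort_traces(co, rid, "cfos", g)), 1)
  expect_lt(diff(range(gm)) / mean(gm), 0.6)   # sampling error only
  ## cross-region mean Kendall tau near 0 without latent factors
  m <- cfos_density(co)$relative
  taus <- vapply(2:ncol(m), function(j) kendall_cor(m[, 1], m[, j])$tau, 1)
  expect_lt(abs(mean(taus)), 0.2)
})

test_that("genotype multipliers scale the mutant axon traces", {
  a <- toy_atlas()
  co <- simulate_cohort(a, cohort_design(contra_mult = 0.1, ipsi_mult = 2),
                        seed = 22)
  contra <- as.character(a$regions$region_id[a$regions$hemisphere == "contra"][1])
  ipsi <- as.character(a$regions$region_id[a$regions$hemisphere == "ipsi"][1])
  for (rg in list(c(contra, 0.1), c(ipsi, 2))) {
    wt <- sum(cohort_traces(co, rg[1], "ochief", "WT")) /
      sum(co$samples$genotype == "WT")
    het <- sum(cohort_traces(co, rg[1], "ochief", "Tbr1het")) /
      sum(co$samples$genotype == "Tbr1het")
    expect_equal(het / wt, as.numeric(rg[2]), tolerance = 0.35)
  }
})

test_that("latent loading plants within-community Kendall structure", {
  ## Monte-Carlo over seeds: mean within-community tau exceeds between
  a <- toy_atlas(12, 2400, seed = 3)
  comm <- split(a$regions$region_id, rep(1:4, each = 6))
  wins <- vapply(1:20, function(s) {
    des <- null_design(8, latent = list(communities = comm, loading = 0.9))
    co <- simulate_cohort(a, des, seed = 500 + s)
    m <- cfos_density(co)$relative[co$samples$group == "WT_ctrl", ]
    cc <- co$truth$community[colnames(m)]
    tw <- tb <- c()
    for (i in 1:(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
      tau <- kendall_cor(m[, i], m[, j])$tau
      if (cc[i] == cc[j]) tw <- c(tw, tau) else tb <- c(tb, tau)
    }
    mean(tw) > mean(tb)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cohort is seed-deterministic and roundtrips through CSV", {
  a <- toy_atlas()
  co1 <- simulate_cohort(a, null_design(5), seed = 77)
  co2 <- simulate_cohort(a, null_design(5), seed = 77)
  expect_identical(co1$ochief, co2$ochief)
  expect_identical(co1$density, co2$density)
  stem <- file.path(withr::local_tempdir(), "c")
  write_cohort(co1, stem)
  rt <- read_cohort(stem)
  rid <- as.character(a$regions$region_id[3])
  expect_equal(unname(rt$ochief[[rid]]), unname(co1$ochief[[rid]]))
  expect_equal(rt$density, co1$density)
})

test_that("cohort_design validates its inputs", {
  expect_error(null_design(2), ">= 3 samples")
  expect_error(null_design(5, latent = list(communities = list(1:2), loading = 1)),
               ">= 3 regions")
  expect_error(null_design(5, latent = list(communities = list(1:3), loading = -1)),
               "loading")
  expect_error(cohort_design(contra_mult = -0.5), "multipliers")
})

test_that("render_section_image honors its contracts", {
  ## background only
  fx0 <- render_section_image(c(40, 40), 0, 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(fx0$spots), 0)
  expect_false(any(fx0$ridge_mask))
  expect_lt(diff(range(fx0$image)), 0.5 * 20)   # smooth drift only
  ## determinism
  f1 <- render_section_image(c(64, 64), 5, 1, seed = 4)
  f2 <- render_section_image(c(64, 64), 5, 1, seed = 4)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$spots, f2$spots)
  ## pixel size precondition
  expect_error(render_section_image(c(32, 32), 0, 0, pixel_um = 5), "pixel_um")
})

test_that("simulate_behavior plants paired shifts and respects seeds", {
  b1 <- simulate_behavior(7, paired_shift = c(nose_to_nose = 60), seed = 6)
  b2 <- simulate_behavior(7, paired_shift = c(nose_to_nose = 60), seed = 6)
  expect_identical(b1, b2)
  expect_true(all(b1$seconds >= 0))
  nn <- b1[b1$behavior == "nose_to_nose", ]
  expect_gt(mean(nn$seconds[nn$condition == "TBS"]),
            mean(nn$seconds[nn$condition == "ctrl"]))
  expect_error(simulate_behavior(4, seed = 1), ">= 5")
  ## large planted shift at n = 7 can reach W = 0
  res <- behavior_compare(b1)
  expect_equal(res$W[res$behavior == "nose_to_nose"], 0)
})
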