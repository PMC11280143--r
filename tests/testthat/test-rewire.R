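test_that("delta traces enumerate all ordered pairs and their mean", {
  A <- matrix(c(1, 2, 3, 4), 2, 2)     # two samples, two bins
  B <- matrix(c(10, 20, 30, 40), 2, 2)
  dt <- delta_traces(A, B)
  expect_equal(nrow(dt$pair_traces), 4)
  expect_equal(dt$mean_trace, colMeans(A) - colMeans(B))
  ## singletons: A = B -> zero trace; constant offset c -> mean == c
  z <- delta_traces(matrix(1:3, 1), matrix(1:3, 1))
  expect_equal(z$mean_trace, c(0, 0, 0))
  off <- delta_traces(matrix(1:3 + 5, 1), matrix(1:3, 1))
  expect_equal(off$mean_trace, c(5, 5, 5))
  ## hand computation on a small fixture (rows ordered (a1,b1),(a1,b2),...)
  expect_equal(dt$pair_traces[2, ], A[1, ] - B[2, ])
  expect_equal(dt$pair_traces[3, ], A[2, ] - B[1, ])
  ## second difference inherits the pair structure
  dd <- ddcfos(dt, delta_traces(B, A))
  expect_equal(nrow(dd$pair_traces), 16)
  expect_equal(dd$mean_trace, 2 * (colMeans(A) - colMeans(B)))
})

test_that("correlate_region covers exact lines and degenerate input", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlate_region(x, 2 * x), 1)
  expect_equal(correlate_region(x, -x), -1)
  expect_true(is.na(correlate_region(x, rep(1, 5))))         # zero variance
  expect_true(is.na(correlate_region(c(1, 2, NA, NA, NA),
                                     c(2, 1, NA, NA, NA))))  # <3 finite bins
  ## covariance-formula oracle on a random fixture
  set.seed(3)
  y <- rnorm(20); z <- rnorm(20)
  expect_equal(correlate_region(y, z),
               mean((y - mean(y)) * (z - mean(z))) / (sd(y) * sd(z)) *
                 20 / 19, tolerance = 1e-12)
})

test_that("reshuffle_null is seed-deterministic and flags degenerate traces", {
  set.seed(10)
  dop <- matrix(rnorm(60), 4, 15)
  wtd <- matrix(rnorm(45), 3, 15)
  tbd <- matrix(rnorm(45), 3, 15)
  n1 <- reshuffle_null(dop, wtd, tbd, n_shuffles = 150, seed = 5)
  n2 <- reshuffle_null(dop, wtd, tbd, n_shuffles = 150, seed = 5)
  expect_identical(n1$r_shuffled, n2$r_shuffled)
  expect_error(reshuffle_null(dop, wtd, tbd, n_shuffles = 50, seed = 1),
               ">= 100")
  expect_warning(nl <- reshuffle_null(matrix(1, 2, 15), wtd, tbd,
                                      n_shuffles = 100, seed = 1),
                 "degenerate")
  expect_true(nl$degenerate)
  expect_equal(classify_correlation(nl)$class, "none")
})

test_that("classification applies the three criteria literally", {
  mk_null <- function(r_obs, r_sh, t_do, t_dd) {
    structure(list(r_obs = r_obs, r_shuffled = r_sh,
                   mean_dochief = 1:5, mean_ddcfos = 1:5,
                   tendency_threshold_ochief = 0.5,
                   tendency_threshold_ddcfos = 0.5,
                   tendency_ochief = t_do, tendency_ddcfos = t_dd,
                   degenerate = FALSE), class = "reshuffle_null")
  }
  null_r <- seq(-0.5, 0.5, length.out = 200)
  ## beyond the null band but |r| <= 0.1: criterion 2 fails -> none
  expect_equal(classify_correlation(mk_null(0.05, null_r / 10, 1, 1))$class,
               "none")
  ## all three pass -> positive
  expect_equal(classify_correlation(mk_null(0.9, null_r, 1, 1))$class,
               "positive")
  ## tendency product of wrong sign blocks the call
  expect_equal(classify_correlation(mk_null(0.9, null_r, 1, -1))$class, "none")
  expect_equal(classify_correlation(mk_null(-0.9, null_r, 1, -1))$class,
               "negative")
  ## inside the null band -> none regardless of r
  expect_equal(classify_correlation(mk_null(0.4, null_r, 1, 1))$class, "none")
})

test_that("trace tendency sums only threshold-exceeding scaled bins", {
  tr <- c(0.2, -0.1, 1, -0.8, 0.1)
  expect_equal(trace_tendency(tr, 1, 0.9), 1)
  expect_equal(trace_tendency(tr, 1, 0.75), 1 - 0.8)
  expect_equal(trace_tendency(tr, 1, 1.5), 0)
  expect_equal(trace_tendency(tr, 0, 0.5), 0)
})

test_that("planted coupled regions classify positive; plumbing end-to-end", {
  a <- toy_atlas()
  rid <- a$regions$region_id[a$regions$hemisphere == "ipsi"][1]
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(a, null_design(7, coupled = rid), seed = 900 + s)
    classify_one(co, rid, n_shuffles = 200, seed = s)$class == "positive"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  ## rewire_analysis output contract on a cohort with planted effects
  des <- cohort_design(contra_mult = 0.1, ipsi_mult = 2, coupled = rid,
                       cfos_group_log_offsets = c(WT_ctrl = 0,
                                                  Tbr1het_ctrl = 0,
                                                  WT_TBS = 0.4,
                                                  Tbr1het_TBS = 0.4),
                       sample_scale_sd = 0, cfos_noise_sd = 0)
  co <- simulate_cohort(a, des, seed = 55)
  res <- rewire_analysis(co, "ipsi", n_shuffles = 100, seed = 5)
  expect_true(all(c("region_id", "r", "class", "sum_dochief") %in% names(res)))
  expect_true(all(res$class %in% c("positive", "negative", "none")))
  if (rid %in% res$region_id)
    expect_equal(res$class[res$region_id == rid], "positive")
})

test_that("classifier output is invariant to sample ordering", {
  a <- toy_atlas()
  rid <- a$regions$region_id[1]
  co <- simulate_cohort(a, null_design(5), seed = 66)
  cl1 <- classify_one(co, rid, n_shuffles = 100, seed = 2)
  ## permute samples inside each genotype: pair sets are identical as sets,
  ## so mean traces and r are unchanged
  co2 <- co
  perm <- c(sample(which(co$samples$genotype == "WT")),
            sample(which(co$samples$genotype == "Tbr1het")))
  co2$samples <- co2$samples[perm, ]
  for (r in names(co2$ochief)) {
    co2$ochief[[r]] <- co2$ochief[[r]][perm, ]
    co2$cfos[[r]] <- co2$cfos[[r]][perm, ]
  }
  cl2 <- classify_one(co2, rid, n_shuffles = 100, seed = 2)
  expect_equal(cl1$r, cl2$r)
  expect_equal(cl1$class, cl2$class)
})
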