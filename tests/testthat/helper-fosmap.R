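# shared fixtures and independent oracles -------------------------------

toy_atlas <- local({
  cache <- NULL
  function(n = 8, span = 2400, seed = 3) {
    key <- sprintf("%d_%d_%d", n, span, seed)
    if (is.null(cache) || attr(cache, "key") != key) {
      a <- make_atlas(n, span, seed = seed)
      attr(a, "key") <- key
      cache <<- a
    }
    cache
  }
})

null_design <- function(n = 7, ...) {
  cohort_design(n_per_group = c(WT_ctrl = n, Tbr1het_ctrl = n,
                                WT_TBS = n, Tbr1het_TBS = n),
                contra_mult = 1, ipsi_mult = 1, ...)
}

## pure count-noise null: no animal-level variance components, so the
## bin-blocked Friedman design is nominally calibrated (see vignette)
pure_noise_design <- function(n = 7, ...) {
  null_design(n, sample_scale_sd = 0, cfos_noise_sd = 0, ...)
}

## all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## brute-force Kendall oracle: permutation-enumeration two-sided p
kendall_oracle <- function(x, y) {
  n <- length(x)
  S_of <- function(a, b) {
    s <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    s
  }
  s_obs <- S_of(x, y)
  perms <- all_perms(n)
  ys <- sort(y)
  s_null <- apply(perms, 1, function(p) S_of(x, ys[p]))
  min(1, mean(s_null >= abs(s_obs)) + mean(s_null <= -abs(s_obs)))
}

## brute-force Wilcoxon oracle: full 2^n sign enumeration
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  S <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wplus <- as.vector(signs %*% r)
  mean(wplus <= w_obs | wplus >= S - w_obs)
}

## independent Friedman oracle: explicit ranks, textbook statistic with the
## tie correction written from the formula
friedman_oracle <- function(mat) {   # blocks x groups
  n <- nrow(mat); k <- ncol(mat)
  R <- matrix(0, n, k)
  tie_term <- 0
  for (b in seq_len(n)) {
    v <- mat[b, ]
    sorted <- sort(v)
    R[b, ] <- vapply(v, function(x) mean(which(sorted == x)), 1)
    tb <- table(v)
    tie_term <- tie_term + sum(tb^3 - tb)
  }
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  cc <- 1 - tie_term / (n * (k^3 - k))
  if (cc > 0) stat <- stat / cc else stat <- 0
  list(chi2 = max(stat, 0), p = pchisq(max(stat, 0), k - 1, lower.tail = FALSE))
}

## paired data realizing a target Wilcoxon W with n untied pairs
pairs_with_W <- function(n, W) {
  stopifnot(W <= n * (n + 1) / 4)
  neg <- integer(0); left <- W
  for (r in rev(seq_len(n))) if (r <= left) { neg <- c(neg, r); left <- left - r }
  stopifnot(left == 0)
  s <- rep(1, n); s[neg] <- -1
  list(a = seq_len(n) * s, b = rep(0, n))
}

## spot match metrics at a radius
match_spots <- function(truth, detected, radius_um = 5) {
  if (!nrow(detected)) return(list(recall = 0, precision = NaN))
  d <- outer(seq_len(nrow(truth)), seq_len(nrow(detected)),
             Vectorize(function(i, j)
               sqrt((truth$x_um[i] - detected$x_um[j])^2 +
                    (truth$y_um[i] - detected$y_um[j])^2)))
  list(recall = mean(apply(d, 1, min) <= radius_um),
       precision = mean(apply(d, 2, min) <= radius_um))
}

## one-region classifier wrapper used by calibration/recovery suites
classify_one <- function(co, rid, n_shuffles = 200, seed = 1) {
  dop <- delta_traces(cohort_traces(co, rid, "ochief", "Tbr1het"),
                      cohort_traces(co, rid, "ochief", "WT"))
  wtd <- delta_traces(cohort_traces(co, rid, "cfos", "WT_TBS"),
                      cohort_traces(co, rid, "cfos", "WT_ctrl"))
  tbd <- delta_traces(cohort_traces(co, rid, "cfos", "Tbr1het_TBS"),
                      cohort_traces(co, rid, "cfos", "Tbr1het_ctrl"))
  classify_correlation(reshuffle_null(dop$pair_traces, wtd$pair_traces,
                                      tbd$pair_traces,
                                      n_shuffles = n_shuffles, seed = seed))
}
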