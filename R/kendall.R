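## Kendall rank correlation ----------------------------------------------
##
## tau-b with a two-sided p-value: exact (inversion-count null, equivalent
## to full enumeration of permutations) when n < 10 and neither variable is
## tied; otherwise the standard tie-corrected normal approximation on the
## concordance statistic S. Used for the interregional c-Fos correlation
## matrices, where the paper gates edges at p < 0.05.

## number of permutations of 1..n with d inversions, d = 0..n(n-1)/2
.kendall_null_counts <- function(n) {
  key <- as.character(n)
  cache <- .fosmap_env$kcounts %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  counts <- 1
  for (i in seq_len(n - 1)) {
    ## multiply by (1 + x + ... + x^i)
    new <- numeric(length(counts) + i)
    for (k in 0:i) new[(k + 1):(k + length(counts))] <-
        new[(k + 1):(k + length(counts))] + counts
    counts <- new
  }
  cache[[key]] <- counts
  .fosmap_env$kcounts <- cache
  counts
}

#' Kendall tau-b correlation with small-sample exact p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param exact_n_max use the exact null for tie-free samples up to this n
#'   (default 9).
#' @return list: `tau` (tau-b), `p` (two-sided), `S` (concordant minus
#'   discordant), `exact` (logical).
#' @export
kendall_cor <- function(x, y, exact_n_max = 9) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3) stopf("need at least 3 observations")
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  ut <- upper.tri(dx)
  S <- sum(dx[ut] * dy[ut])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    return(list(tau = NA_real_, p = NA_real_, S = S, exact = NA))
  }
  tau <- S / denom
  ties <- n1 > 0 || n2 > 0
  if (!ties && n <= exact_n_max) {
    counts <- .kendall_null_counts(n)
    ## S = n0 - 2*d where d = inversions; null symmetric about n0/2
    d <- (n0 - S) / 2
    dmax <- n0
    dmin <- min(d, dmax - d)
    p <- min(1, 2 * sum(counts[seq_len(dmin + 1)]) / factorial(n))
    exact <- TRUE
  } else {
    ## tie-corrected variance of S (standard asymptotic form)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(tau = tau, p = p, S = S, exact = exact)
}
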