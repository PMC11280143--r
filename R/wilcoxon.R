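## Exact paired Wilcoxon signed-rank test ---------------------------------
##
## W is the smaller of the two signed-rank sums; the two-tailed p-value is
## P(min(W+, W-) <= W_obs) under the exact null, computed from the
## signed-rank sum distribution (subset-sum counts over ranks 1..n). Zero
## differences are dropped before ranking (classical convention); tied
## absolute differences switch to midranks with a tie-corrected normal
## approximation, flagged on the result.

## counts of subsets of {1..n} by sum: length n(n+1)/2 + 1 vector
.signed_rank_counts <- function(n) {
  key <- as.character(n)
  cache <- .fosmap_env$srcounts %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  counts <- 1
  for (r in seq_len(n)) {
    new <- c(counts, numeric(r))
    new[(r + 1):(r + length(counts))] <-
      new[(r + 1):(r + length(counts))] + counts
    counts <- new
  }
  cache[[key]] <- counts
  .fosmap_env$srcounts <- cache
  counts
}

#' Exact two-tailed Wilcoxon signed-rank test
#'
#' @param paired_a,paired_b equal-length paired observations (a - b is
#'   tested against a symmetric-about-zero null).
#' @param exact_n_max largest n (after dropping zeros) for the exact
#'   enumeration; beyond it, or with tied |differences|, a tie-corrected
#'   normal approximation is used.
#' @return list of class `wilcoxon_result`: `n_pairs` (nonzero pairs), `W`
#'   (min signed-rank sum), `p` (two-tailed), `exact` (logical), `method`.
#'   All-zero differences are untestable: `W` and `p` are NA.
#' @export
wilcoxon_exact <- function(paired_a, paired_b, exact_n_max = 25) {
  if (length(paired_a) != length(paired_b))
    stopf("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(n_pairs = 0L, W = NA_real_, p = NA_real_,
                          exact = NA, method = "untestable (all zero)"),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))           # midranks
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  W <- min(wpos, wneg)
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_n_max) {
    counts <- .signed_rank_counts(n)
    tot <- 2^n
    S <- n * (n + 1) / 2
    ## P(W+ <= W) + P(W+ >= S - W); the two tails coincide when W = S/2
    lo <- sum(counts[seq_len(W + 1)])
    hi <- sum(counts[(S - W + 1):(S + 1)])
    p <- min(1, (lo + hi) / tot)
    exact <- TRUE
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (wpos - mu) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
    method <- if (ties) "normal approximation (tied |differences|)"
              else "normal approximation (large n)"
  }
  structure(list(n_pairs = n, W = W, p = p, exact = exact, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: n = %d, W = %s, p = %s (%s)\n",
              x$n_pairs, format(x$W), format(x$p), x$method))
  invisible(x)
}
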