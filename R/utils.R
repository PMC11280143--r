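## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## derive a stage seed from a root seed, staying inside 32-bit integer range
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, segment = 211L, quantify = 307L, compare = 401L,
            rewire = 503L, network = 601L, communities = 701L,
            behavior = 809L, qc = 907L, demo = 1009L, atlas = 1103L,
            image = 1201L)
  o <- offs[[stage]] %||% 1L
  as.integer((as.numeric(seed) * 7919 + o) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_matrix_like <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
}

## adjusted Rand index between two labelings (used by recovery tests and demo)
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same items, corrected for chance;
#' 1 means identical up to relabeling, 0 is the chance level.
#'
#' @param a,b integer/character vectors of cluster labels, same length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stopf("labelings must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
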