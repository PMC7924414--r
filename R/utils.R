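# Internal helpers: deterministic RNG streams, integer apportionment,
# number formatting shared by CSV/JSON writers.

# Derive a child seed from (seed, operation-name) so that every sampling
# operation owns an independent, reproducible RNG stream.  Adding a covariate
# to an analysis must not perturb draws made by unrelated operations.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  # keep everything in exact double arithmetic, well below 2^53
  as.integer(((abs(seed) %% 2147483647) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a seed derived from (seed, op) without disturbing the
# caller's RNG state.
with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, op))
  expr
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Allocates an integer total `n` across strata proportionally to `weights`,
#' assigning floor shares first and distributing the remaining units to the
#' strata with the largest fractional remainders.  Ties on the remainder are
#' broken by lexicographic order of the stratum names so the allocation is
#' deterministic.
#'
#' @param weights Non-negative numeric vector, optionally named.
#' @param n Integer total to allocate.
#' @return Integer vector summing exactly to `n`, same names as `weights`.
#' @examples
#' largest_remainder(c(a = 30, b = 20, c = 40, d = 10), 100)
#' @export
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  quota <- weights / sum(weights) * n
  base <- floor(quota)
  rem <- quota - base
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    nm <- names(weights)
    if (is.null(nm)) nm <- sprintf("%09d", seq_along(weights))
    ord <- order(-rem, nm)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  res <- as.integer(base)
  names(res) <- names(weights)
  res
}

# 6 significant digits, "inf" for infinities; used by all text exports.
fmt_num <- function(x) {
  out <- ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"),
                trimws(formatC(x, digits = 6, format = "g")))
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
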