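# Enrichment statistics: fold change, Pearson chi-square, two-sample KS,
# Bonferroni correction, and effect-strength ranking.

#' Contingency table of signal/background membership counts
#'
#' @param s_in,s_out Signal sites inside / outside the track.
#' @param b_in,b_out Background sites inside / outside the track.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(s_in, s_out, b_in, b_out) {
  counts <- c(s_in = s_in, s_out = s_out, b_in = b_in, b_out = b_out)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (s_in + s_out < 1) stop("zero-size signal set")
  if (b_in + b_out < 1) stop("zero-size background set")
  structure(as.list(counts), class = "contingency_table")
}

#' Fold-change enrichment of signal over background
#'
#' The fold change is the ratio of in-fractions,
#' `(s_in / (s_in + s_out)) / (b_in / (b_in + b_out))`.  When the
#' background fraction is zero the fold change is `Inf` if any signal site
#' is inside and 1 if neither set has a site inside.  The log2 fold change
#' adds a Haldane-Anscombe pseudocount of 0.5 to all four counts so it is
#' always finite.
#'
#' @param t A [contingency_table()].
#' @return List with `fc` and `log2_fc`.
#' @export
fold_change <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  sf <- t$s_in / (t$s_in + t$s_out)
  bf <- t$b_in / (t$b_in + t$b_out)
  fc <- if (t$b_in == 0) {
    if (t$s_in > 0) Inf else 1
  } else {
    sf / bf
  }
  log2_fc <- log2(((t$s_in + 0.5) / (t$s_in + t$s_out + 1)) /
                  ((t$b_in + 0.5) / (t$b_in + t$b_out + 1)))
  list(fc = fc, log2_fc = log2_fc)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected Pearson statistic with one degree of freedom (no Yates
#' continuity correction).  A degenerate table with a zero row or column
#' has no association to test: statistic 0, p-value 1.
#'
#' @param t A [contingency_table()].
#' @return List with `stat` and `p`.
#' @export
chi2_test <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  m <- matrix(c(t$s_in, t$s_out, t$b_in, t$b_out), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(stat = 0, p = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(stat = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic two-sample formula with effective sample
#' size `|a||b| / (|a| + |b|)`.  Non-finite values (the infinite-distance
#' sentinel for feature-less contigs, missing scores) are excluded from
#' each sample with a logged count.
#'
#' @param a,b Numeric samples.
#' @return List with `D`, `p`, and `n_excluded`.
#' @export
ks_test <- function(a, b) {
  fa <- a[is.finite(a)]
  fb <- b[is.finite(b)]
  n_excl <- (length(a) - length(fa)) + (length(b) - length(fb))
  if (n_excl > 0) {
    message("ks_test: excluded ", n_excl, " non-finite value(s)")
  }
  if (!length(fa) || !length(fb)) {
    stop("empty sample after excluding non-finite values")
  }
  ht <- suppressWarnings(stats::ks.test(fa, fb, exact = FALSE))
  list(D = unname(ht$statistic), p = unname(ht$p.value), n_excluded = n_excl)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of tracks tested in the current run.
#' @return Adjusted p-value(s), `min(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  vapply(p_raw, function(p) stats::p.adjust(p, method = "bonferroni", n = m),
         0.0)
}

#' Rank enrichment results by effect strength
#'
#' Orders rows by descending absolute log2 fold change (pseudocounted,
#' hence finite), breaking ties by ascending adjusted p-value and then by
#' track label.
#'
#' @param results Data frame with columns `log2_fc`, `p_adj`, `track`.
#' @return The data frame reordered; a stable total order.
#' @export
rank_results <- function(results) {
  if (!nrow(results)) return(results)
  o <- order(-abs(results$log2_fc), results$p_adj, results$track)
  out <- results[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
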