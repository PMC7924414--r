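# Sequence-motif covariates: position frequency matrices built from the
# sequence context of a site set, and motif-similarity-weighted sampling
# of control sites (e.g. reproducing the strict TTAA context of piggyBac
# integration in the controls).

# Window anchoring: a window of width w places the site base at column
# floor((w - 1) / 2) + 1, i.e. the window starts at coord - floor((w-1)/2).
# For the canonical TTAA case (w = 4) the site sits on the second T.
window_start <- function(coord, width) coord - floor((width - 1) / 2)

# Integer-coded windows (A=1 C=2 G=3 T=4, 0 for N or out-of-bounds):
# an n x width matrix, one row per site.
window_codes <- function(sequences, sites, width) {
  n <- length(sites)
  mat <- matrix(0L, nrow = n, ncol = width)
  ws <- window_start(sites$coord, width)
  for (ctg in unique(sites$contig)) {
    sel <- which(sites$contig == ctg)
    code <- seq_codes(sequences, ctg)
    len <- length(code)
    for (j in seq_len(width)) {
      pos <- ws[sel] + (j - 1)          # 0-based
      ok <- pos >= 0 & pos < len
      v <- integer(length(sel))
      v[ok] <- code[pos[ok] + 1]
      mat[sel, j] <- v
    }
  }
  mat
}

#' Build a position frequency matrix from the sequence context of sites
#'
#' Column `j` holds the frequency of each base at offset `j` of the window
#' around every site, with a pseudocount:
#' `(count + alpha) / (n_valid + 4 * alpha)`.  Bases that are `N` or fall
#' outside the contig are excluded per column, so `n_valid` can differ
#' between columns near contig edges.
#'
#' @param signal A [position_set()].
#' @param sequences A `genome_seqs` object covering all signal contigs.
#' @param flank Bases on each side of the site; window width is
#'   `2 * flank + 1`.  Ignored when `width` is given.
#' @param width Explicit window width (the site base sits at column
#'   `floor((width - 1) / 2) + 1`).
#' @param alpha Pseudocount (default 0.1).  With `alpha = 0` an
#'   all-excluded column is an error.
#' @return A `pfm` object: a 4 x width matrix (rows A, C, G, T), each
#'   column summing to 1.
#' @export
build_pfm <- function(signal, sequences, flank = NULL, width = NULL,
                      alpha = 0.1) {
  if (is.null(width)) {
    stopifnot(!is.null(flank), flank >= 0)
    width <- 2 * flank + 1
  }
  stopifnot(width >= 1, alpha >= 0, length(signal) >= 1)
  codes <- window_codes(sequences, signal, width)
  mat <- matrix(NA_real_, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  n_valid <- integer(width)
  for (j in seq_len(width)) {
    v <- codes[, j]
    v <- v[v > 0]
    n_valid[j] <- length(v)
    counts <- tabulate(v, nbins = 4)
    if (length(v) == 0 && alpha == 0) {
      stop("zero valid windows at column ", j, " with alpha = 0")
    }
    mat[, j] <- (counts + alpha) / (length(v) + 4 * alpha)
  }
  if (all(n_valid == 0)) stop("zero valid windows")
  structure(list(matrix = mat, width = width, alpha = alpha,
                 n_valid = n_valid),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm: width", x$width, ", alpha", x$alpha, "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Motif likelihood weight of each site
#'
#' The weight of a position is the product over window columns of the PFM
#' frequency of the base found there; windows containing `N` or truncated
#' by a contig edge get weight 0.
#'
#' @param pfm A [build_pfm()] object.
#' @param sequences A `genome_seqs` object.
#' @param sites A [position_set()].
#' @return Numeric vector of weights, one per site.
#' @export
pfm_weights <- function(pfm, sequences, sites) {
  codes <- window_codes(sequences, sites, pfm$width)
  w <- rep(1, length(sites))
  for (j in seq_len(pfm$width)) {
    v <- codes[, j]
    wj <- numeric(length(v))
    ok <- v > 0
    wj[ok] <- pfm$matrix[cbind(v[ok], j)]
    w <- w * wj
  }
  w
}

#' Sample control sites weighted by motif similarity
#'
#' Draws a large uniform candidate pool, weights each candidate by the
#' likelihood of its surrounding sequence under the PFM, and samples the
#' requested number of control sites with replacement with probability
#' proportional to that weight.  With a zero-pseudocount PFM built from
#' motif-constrained sites (e.g. TTAA), every control site therefore sits
#' in an exact motif occurrence.
#'
#' @param pfm A [build_pfm()] object.
#' @param sequences A `genome_seqs` object.
#' @param assembly A [genome_assembly()].
#' @param n Number of control sites.
#' @param seed Integer seed.
#' @param pool_size Uniform pool size (default `max(100 * n, 1e5)`).
#' @param restrict Optional [interval_track()] restricting the universe.
#' @return A `background_model`.
#' @export
sample_motif_matched <- function(pfm, sequences, assembly, n = 10000,
                                 seed = 1, pool_size = NULL,
                                 restrict = NULL) {
  pool_size <- pool_size %||% max(100 * n, 1e5)
  if (pool_size < n) stop("pool_size must be >= n")
  universe <- if (is.null(restrict)) full_track(assembly) else restrict
  with_op_seed(seed, "sample_motif_matched", {
    draw <- uniform_from_intervals(universe$ivs, pool_size)
    pool <- position_set(draw$contig, draw$coord)
    w <- pfm_weights(pfm, sequences, pool)
    if (all(w == 0)) stop("all motif weights are zero in the pool")
    pick <- sample.int(pool_size, n, replace = TRUE, prob = w)
    new_background(pool$contig[pick], pool$coord[pick],
                   "motif-matched background",
                   list(model = "motif_matched", n = n, seed = seed,
                        pool_size = pool_size, pfm_width = pfm$width,
                        pfm_alpha = pfm$alpha))
  })
}
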