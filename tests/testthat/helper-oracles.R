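# Independent brute-force oracles used to cross-check the package's
# interval and statistics primitives.  These deliberately share no code
# with the implementation: plain per-site linear scans and textbook
# formulas.

oracle_membership <- function(sites, ivs) {
  vapply(seq_along(sites$coord), function(i) {
    d <- ivs[ivs$contig == sites$contig[i], , drop = FALSE]
    any(d$start <= sites$coord[i] & sites$coord[i] < d$end)
  }, NA)
}

oracle_nearest <- function(sites, ivs) {
  vapply(seq_along(sites$coord), function(i) {
    d <- ivs[ivs$contig == sites$contig[i], , drop = FALSE]
    if (!nrow(d)) return(Inf)
    p <- sites$coord[i]
    min(vapply(seq_len(nrow(d)), function(j) {
      if (d$start[j] <= p && p < d$end[j]) 0
      else if (p < d$start[j]) d$start[j] - p
      else p - (d$end[j] - 1)
    }, 0.0))
  }, 0.0)
}

oracle_chi2 <- function(s_in, s_out, b_in, b_out) {
  obs <- c(s_in, s_out, b_in, b_out)
  ns <- s_in + s_out
  nb <- b_in + b_out
  tot <- ns + nb
  exp <- c(ns * (s_in + b_in) / tot, ns * (s_out + b_out) / tot,
           nb * (s_in + b_in) / tot, nb * (s_out + b_out) / tot)
  sum((obs - exp)^2 / exp)
}

oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), 0.0)
  Fb <- vapply(pts, function(x) mean(b <= x), 0.0)
  max(abs(Fa - Fb))
}

oracle_score_at <- function(sites, ivs) {
  vapply(seq_along(sites$coord), function(i) {
    d <- ivs[ivs$contig == sites$contig[i], , drop = FALSE]
    hit <- which(d$start <= sites$coord[i] & sites$coord[i] < d$end)
    if (length(hit)) d$score[hit[1]] else NA_real_
  }, 0.0)
}

# random merged interval data frame on one or more contigs
random_ivs <- function(assembly, n_per_contig = 20, max_len = 50) {
  parts <- lapply(names(assembly), function(ctg) {
    len <- unclass(assembly)[[ctg]]
    start <- sort(sample.int(len - max_len, n_per_contig))
    data.frame(contig = ctg, start = start,
               end = pmin(start + sample.int(max_len, n_per_contig,
                                             replace = TRUE), len))
  })
  do.call(rbind, parts)
}

joint_labels_for_test <- function(covs, sites) {
  sitematch:::joint_labels(covs, sites)
}

random_sites <- function(assembly, n) {
  ctg <- sample(names(assembly), n, replace = TRUE)
  position_set(ctg, floor(runif(n) * unclass(assembly)[ctg]))
}
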