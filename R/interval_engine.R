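# interval_engine: point-vs-interval primitives on merged, sorted tracks.
# Per-site lookups run on findInterval over the sorted starts of each
# contig's interval list; set algebra goes through IRanges.

# For each site, index of the interval whose start is <= coord (0 if none),
# grouped by contig.  Shared by membership, distance and score lookups.
site_interval_index <- function(sites, track) {
  n <- length(sites)
  inside <- logical(n)
  idx <- integer(n)
  ivs <- track$ivs
  for (ctg in unique(sites$contig)) {
    sel <- which(sites$contig == ctg)
    d <- ivs[ivs$contig == ctg, , drop = FALSE]
    if (!nrow(d)) next
    i <- findInterval(sites$coord[sel], d$start)
    idx[sel] <- i
    hit <- i > 0
    hit[hit] <- sites$coord[sel][hit] < d$end[i[hit]]
    inside[sel] <- hit
  }
  list(inside = inside, idx = idx)
}

#' Count positions inside and outside a track
#'
#' A position `p` is inside iff some interval satisfies
#' `start <= p < end`.  Contigs absent from the track contribute only to
#' the outside count.
#'
#' @param sites A [position_set()].
#' @param track An [interval_track()].
#' @return List with integer counts `n_in` and `n_out`,
#'   `n_in + n_out == length(sites)`.
#' @export
count_membership <- function(sites, track) {
  if (!length(sites)) stop("empty position set")
  inside <- site_interval_index(sites, track)$inside
  list(n_in = sum(inside), n_out = sum(!inside))
}

# logical membership vector, one element per site (internal)
membership_flags <- function(sites, track) site_interval_index(sites, track)$inside

#' Distance from each position to the nearest covered base of a track
#'
#' Distance is 0 for positions inside an interval; otherwise the unsigned
#' gap in bases to the nearest interval edge on the same contig.  Positions
#' on contigs carrying no track interval get `Inf`.
#'
#' @param sites A [position_set()].
#' @param track A non-empty [interval_track()].
#' @return Numeric vector of distances, one per site, order preserved.
#' @export
nearest_distance <- function(sites, track) {
  if (!nrow(track$ivs)) stop("empty track")
  n <- length(sites)
  out <- rep(Inf, n)
  ivs <- track$ivs
  for (ctg in unique(sites$contig)) {
    sel <- which(sites$contig == ctg)
    d <- ivs[ivs$contig == ctg, , drop = FALSE]
    if (!nrow(d)) next
    p <- sites$coord[sel]
    i <- findInterval(p, d$start)
    dist <- rep(Inf, length(p))
    # gap to the interval on the left (p beyond its end), 0 if inside
    hasl <- i > 0
    if (any(hasl)) {
      il <- i[hasl]
      dist[hasl] <- pmax(p[hasl] - (d$end[il] - 1), 0)
    }
    # gap to the interval on the right
    hasr <- i < nrow(d)
    if (any(hasr)) {
      ir <- i[hasr] + 1L
      dist[hasr] <- pmin(dist[hasr], d$start[ir] - p[hasr])
    }
    out[sel] <- dist
  }
  out
}

#' Complement of a track within an assembly
#'
#' The union of a merged track and its complement tiles every contig of the
#' assembly exactly; their intersection is empty.
#'
#' @param track An [interval_track()].
#' @param assembly A [genome_assembly()].
#' @return An [interval_track()] covering all uncovered bases.
#' @export
complement_track <- function(track, assembly) {
  parts <- lapply(names(assembly), function(ctg) {
    len <- contig_length(assembly, ctg)
    d <- track$ivs[track$ivs$contig == ctg, , drop = FALSE]
    full <- IRanges::IRanges(1, len)
    r <- from_iranges(IRanges::setdiff(full, to_iranges(d$start, d$end)))
    if (length(r$start)) iv_df(ctg, r$start, r$end) else iv_df()
  })
  interval_track(do.call(rbind, parts),
                 label = paste0("not(", track$label, ")"))
}

#' Combine two tracks by set algebra on their base sets
#'
#' @param a,b [interval_track()] objects.
#' @param mode `"union"`, `"intersection"` or `"difference"` (a minus b).
#' @param label Label for the result.
#' @return A merged [interval_track()].
#' @export
blend_tracks <- function(a, b, mode = c("union", "intersection", "difference"),
                         label = NULL) {
  mode <- match.arg(mode)
  label <- label %||% paste0(mode, "(", a$label, ",", b$label, ")")
  ctgs <- union(unique(a$ivs$contig), unique(b$ivs$contig))
  parts <- lapply(sort(ctgs), function(ctg) {
    da <- a$ivs[a$ivs$contig == ctg, , drop = FALSE]
    db <- b$ivs[b$ivs$contig == ctg, , drop = FALSE]
    ra <- to_iranges(da$start, da$end)
    rb <- to_iranges(db$start, db$end)
    r <- switch(mode,
                union = IRanges::union(ra, rb),
                intersection = IRanges::intersect(ra, rb),
                difference = IRanges::setdiff(ra, rb))
    r <- from_iranges(r)
    if (length(r$start)) iv_df(ctg, r$start, r$end) else iv_df()
  })
  interval_track(do.call(rbind, parts), label = label)
}

#' Score of the covering interval for each position
#'
#' @param sites A [position_set()].
#' @param track A [scored_track()].
#' @return Numeric vector, one score per site; `NA` for uncovered positions.
#' @export
score_at <- function(sites, track) {
  stopifnot(inherits(track, "scored_track"))
  hit <- site_interval_index(sites, track)
  out <- rep(NA_real_, length(sites))
  if (any(hit$inside)) {
    ivs_by_contig <- split(track$ivs, track$ivs$contig)
    for (ctg in unique(sites$contig[hit$inside])) {
      sel <- which(sites$contig == ctg & hit$inside)
      out[sel] <- ivs_by_contig[[ctg]]$score[hit$idx[sel]]
    }
  }
  out
}
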