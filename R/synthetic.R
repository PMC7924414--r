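# synthetic: fixture generator -- random genomes, annotation tracks,
# k-mer occurrence tracks, and integration-site sets with known
# ground-truth preferences, so the whole analysis stack is testable
# without external downloads.

#' Generate a random genome
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc / 2` and
#' `P(A) = P(T) = (1 - gc) / 2`.  Deterministic for a fixed seed.  When
#' `dir` is given, a FASTA and a chrom.sizes file are written there.
#'
#' @param lengths Named numeric vector of contig lengths.
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param dir Optional output directory for `genome.fa` and
#'   `genome.chrom.sizes`.
#' @return List with `assembly`, `sequences`, and (when written)
#'   `fasta_path`, `sizes_path`.
#' @export
gen_genome <- function(lengths, gc = 0.41, seed = 1, dir = NULL) {
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must be strictly between 0 and 1")
  }
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  assembly <- genome_assembly(lengths)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  strings <- with_op_seed(seed, "gen_genome", {
    vapply(names(assembly), function(ctg) {
      paste(sample(names(probs), contig_length(assembly, ctg),
                   replace = TRUE, prob = probs), collapse = "")
    }, "", USE.NAMES = TRUE)
  })
  seqs <- genome_seqs(strings)
  out <- list(assembly = assembly, sequences = seqs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$fasta_path <- write_fasta(seqs, file.path(dir, "genome.fa"))
    out$sizes_path <- write_chrom_sizes(assembly,
                                        file.path(dir, "genome.chrom.sizes"))
  }
  out
}

#' Generate a random annotation track with a target coverage
#'
#' Intervals with exponential-ish lengths around `mean_len` are placed
#' uniformly and merged; intervals are added until the realized coverage
#' is within 10% relative of `coverage * genome size`.
#'
#' @param assembly A [genome_assembly()].
#' @param coverage Target covered fraction, in (0, 1).
#' @param mean_len Mean interval length in bases.
#' @param seed Integer seed.
#' @param label Track label.
#' @return An [interval_track()].
#' @export
gen_track <- function(assembly, coverage = 0.1, mean_len = 1000, seed = 1,
                      label = "synthetic track") {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  if (coverage > 0.8) stop("infeasible coverage spec (> 0.8 with merging)")
  with_op_seed(seed, paste0("gen_track:", label), {
    parts <- lapply(names(assembly), function(ctg) {
      len <- contig_length(assembly, ctg)
      target <- coverage * len
      df <- iv_df()
      covered <- 0
      for (round in 1:60) {
        if (covered >= 0.9 * target) break
        need <- target - covered
        m <- max(1L, ceiling(need / mean_len))
        lens <- pmax(1, round(stats::rexp(m, rate = 1 / mean_len)))
        starts <- floor(stats::runif(m) * pmax(1, len - lens))
        df <- rbind(df, iv_df(ctg, starts, pmin(starts + lens, len)))
        df <- merge_intervals(df)
        covered <- sum(df$end - df$start)
        # back off if a batch overshot: drop the longest intervals
        while (covered > 1.1 * target && nrow(df) > 1) {
          drop <- which.max(df$end - df$start)
          covered <- covered - (df$end[drop] - df$start[drop])
          df <- df[-drop, , drop = FALSE]
        }
      }
      df
    })
    interval_track(do.call(rbind, parts), label = label)
  })
}

#' All occurrences of a k-mer in the genome (overlapping included)
#'
#' @param sequences A `genome_seqs` object.
#' @param kmer Literal k-mer, e.g. `"GAATTC"` (EcoRI) or `"TTAA"`.
#' @return Data frame of 0-based half-open occurrence intervals of width
#'   `nchar(kmer)`, before any merging.
#' @export
kmer_occurrences <- function(sequences, kmer) {
  stopifnot(nchar(kmer) >= 1)
  parts <- lapply(names(sequences$strings), function(ctg) {
    m <- Biostrings::matchPattern(kmer,
                                  Biostrings::DNAString(sequences$strings[[ctg]]))
    if (!length(m)) return(iv_df())
    iv_df(ctg, Biostrings::start(m) - 1, Biostrings::end(m))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Track of k-mer occurrence intervals
#'
#' Overlapping occurrences (possible for self-overlapping k-mers such as
#' `AAA`) are merged by track construction.
#'
#' @inheritParams kmer_occurrences
#' @param label Track label (defaults to the k-mer).
#' @return An [interval_track()].
#' @export
kmer_track <- function(sequences, kmer, label = kmer) {
  occ <- kmer_occurrences(sequences, kmer)
  if (!nrow(occ)) stop("k-mer ", kmer, " not found in any contig")
  interval_track(occ, label = label)
}

#' Generate integration sites with known preferences
#'
#' Rejection sampler: a uniform base is proposed and accepted with
#' probability proportional to the product of the rate multipliers of all
#' covering preference tracks, times a motif indicator when a `motif`
#' k-mer is given (the site's window must spell the k-mer exactly, with
#' the same window anchoring as [build_pfm()]).  The returned ground
#' truth records, per preference track of realized coverage `f` and
#' multiplier `r`, the analytic expected in-fraction
#' `f r / (f r + 1 - f)`.
#'
#' @param assembly A [genome_assembly()].
#' @param n Number of sites.
#' @param prefs List of preferences, each `list(track =, r =)` with
#'   `r > 0` finite; may be empty for uniform sites.
#' @param motif Optional literal k-mer constraining every site's window.
#' @param sequences A `genome_seqs` object; required with `motif`.
#' @param seed Integer seed.
#' @param label Label for the site set.
#' @return List with `sites` (a [position_set()]) and `truth` (tracks,
#'   multipliers, realized coverages, expected in-fractions, motif).
#' @export
gen_sites <- function(assembly, n, prefs = list(), motif = NULL,
                      sequences = NULL, seed = 1, label = "synthetic sites") {
  stopifnot(n >= 1)
  r <- vapply(prefs, function(p) p$r, 0.0)
  if (length(r) && (any(!is.finite(r)) || any(r <= 0))) {
    stop("rate multipliers must be finite and > 0")
  }
  if (!is.null(motif) && is.null(sequences)) {
    stop("motif constraint requires genome sequences")
  }
  genome_size <- sum(assembly)
  with_op_seed(seed, "gen_sites", {
    # candidate universe: anchors of motif occurrences when a hard motif
    # constraint is given, otherwise all bases
    universe <- if (is.null(motif)) {
      full_track(assembly)$ivs
    } else {
      occ <- kmer_occurrences(sequences, motif)
      if (!nrow(occ)) stop("degenerate acceptance: motif absent from genome")
      anchor <- occ$start + floor((nchar(motif) - 1) / 2)
      iv_df(occ$contig, anchor, anchor + 1)
    }
    maxw <- prod(pmax(r, 1))
    contig <- character(0)
    coord <- numeric(0)
    while (length(coord) < n) {
      m <- max(2L * (n - length(coord)), 256L)
      cand <- uniform_from_intervals(universe, m)
      w <- rep(1, m)
      if (length(prefs)) {
        cs <- position_set(cand$contig, cand$coord)
        for (p in prefs) {
          inside <- membership_flags(cs, p$track)
          w <- w * ifelse(inside, p$r, 1)
        }
      }
      keep <- stats::runif(m) < w / maxw
      contig <- c(contig, cand$contig[keep])
      coord <- c(coord, cand$coord[keep])
    }
    sites <- position_set(contig[seq_len(n)], coord[seq_len(n)],
                          label = label)
    truth <- list(
      n = n, motif = motif,
      tracks = lapply(prefs, function(p) {
        f <- track_bases(p$track) / genome_size
        list(label = p$track$label, r = p$r, coverage = f,
             expected_in_fraction = f * p$r / (f * p$r + 1 - f))
      }))
    list(sites = sites, truth = truth)
  })
}

#' Generate a confounded track pair with sites preferring only one track
#'
#' Builds track A, derives track B overlapping A (Jaccard >= 0.3 by
#' construction: B shares a large portion of A's bases plus independent
#' extra intervals), and draws sites with a preference multiplier on A
#' only.  B's marginal enrichment is then entirely induced by the overlap:
#' matching the background on A must attenuate it.
#'
#' @param assembly A [genome_assembly()].
#' @param n Number of sites.
#' @param seed Integer seed.
#' @param r Preference multiplier on track A.
#' @param coverage Coverage of track A.
#' @return List with `track_a`, `track_b`, `sites`, `truth` (including
#'   the realized Jaccard index of A and B).
#' @export
gen_confounded_pair <- function(assembly, n = 5000, seed = 1, r = 3,
                                coverage = 0.1) {
  track_a <- gen_track(assembly, coverage = coverage, mean_len = 1000,
                       seed = derive_seed(seed, "confounded_a"), label = "track_A")
  # B = most of A, shifted into partial overlap, plus some independent cover
  with_op_seed(seed, "gen_confounded_pair", {
    iv <- track_a$ivs
    shift <- floor((iv$end - iv$start) * 0.3)
    lens <- contig_length(assembly, iv$contig)
    b_core <- iv_df(iv$contig, pmax(0, iv$start + shift),
                    pmin(lens, iv$end + shift))
    b_core <- b_core[b_core$start < b_core$end, , drop = FALSE]
    extra <- gen_track(assembly, coverage = coverage * 0.3, mean_len = 1000,
                       seed = derive_seed(seed, "confounded_extra"),
                       label = "extra")
    track_b <- interval_track(rbind(b_core, extra$ivs), label = "track_B")
    gs <- gen_sites(assembly, n, prefs = list(list(track = track_a, r = r)),
                    seed = derive_seed(seed, "confounded_sites"),
                    label = "confounded sites")
    inter <- blend_tracks(track_a, track_b, "intersection")
    uni <- blend_tracks(track_a, track_b, "union")
    jaccard <- track_bases(inter) / track_bases(uni)
    list(track_a = track_a, track_b = track_b, sites = gs$sites,
         truth = c(gs$truth,
                   list(jaccard_ab = jaccard,
                        induced_track = "track_B")))
  })
}

#' Write the ground-truth record of a synthetic scenario as JSON
#'
#' @param truth Ground-truth list from [gen_sites()] or
#'   [gen_confounded_pair()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
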