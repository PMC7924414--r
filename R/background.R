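# background: generation of control-site sets -- uniform sampling and the
# covariate-matching strategies (membership, distance, score, motif),
# singly or jointly, plus user-supplied backgrounds.
#
# Every public sampler draws from its own RNG stream derived from
# (seed, operation-name), so adding a covariate or changing one sampler
# never perturbs draws made elsewhere.

#' Declare a covariate for background matching
#'
#' A covariate describes how one annotation track (or sequence motif)
#' stratifies positions: control sites are then allocated across strata in
#' the signal's proportions, which cancels the covariate's effect out of
#' the enrichment comparison.
#'
#' @param kind `"membership"` (inside/outside a track), `"distance"`
#'   (distance to the nearest track feature, e.g. restriction sites),
#'   `"score"` (score of the covering interval), or `"motif"` (sequence
#'   context weighted by a position frequency matrix).
#' @param track An [interval_track()] (membership, distance) or
#'   [scored_track()] (score).
#' @param pfm A [build_pfm()] matrix, for `kind = "motif"`.
#' @param bins Number of equal-frequency bins for distance/score kinds.
#' @return A `covariate` object.
#' @export
covariate <- function(kind = c("membership", "distance", "score", "motif"),
                      track = NULL, pfm = NULL, bins = 10) {
  kind <- match.arg(kind)
  if (kind %in% c("membership", "distance")) {
    stopifnot(inherits(track, "interval_track"))
  } else if (kind == "score") {
    stopifnot(inherits(track, "scored_track"))
  } else {
    stopifnot(inherits(pfm, "pfm"))
  }
  stopifnot(bins >= 1)
  structure(list(kind = kind, track = track, pfm = pfm, bins = bins,
                 cb = NULL, signal_values = NULL),
            class = "covariate")
}

#' @export
print.covariate <- function(x, ...) {
  ref <- if (x$kind == "motif") "pfm" else x$track$label
  cat("covariate ", x$kind, "(", ref, ")",
      if (x$kind %in% c("distance", "score")) paste0(", ", x$bins, " bins"),
      "\n", sep = "")
  invisible(x)
}

# equal-frequency cutpoints from the signal's finite values
quantile_cutpoints <- function(v, bins) {
  v <- v[is.finite(v)]
  if (!length(v) || bins <= 1) return(numeric())
  sort(unique(stats::quantile(v, probs = seq_len(bins - 1) / bins,
                              type = 1, names = FALSE)))
}

bin_values <- function(v, cb) {
  if (!length(cb)) return(rep(1L, length(v)))
  findInterval(v, cb, left.open = TRUE) + 1L
}

# Attach signal-derived discretization (and cached signal values) to a
# covariate.  Breaks are computed from the signal and reused verbatim when
# labelling background candidates.
prepare_covariate <- function(cov, signal) {
  if (cov$kind == "distance") {
    d <- nearest_distance(signal, cov$track)
    cov$cb <- quantile_cutpoints(d, cov$bins)
    cov$signal_values <- d
  } else if (cov$kind == "score") {
    s <- score_at(signal, cov$track)
    cov$cb <- quantile_cutpoints(s, cov$bins)
    cov$signal_values <- s
  }
  cov
}

# Discrete label of each site under one prepared covariate.
covariate_labels <- function(cov, sites) {
  switch(cov$kind,
    membership = ifelse(membership_flags(sites, cov$track), "in", "out"),
    distance = {
      d <- nearest_distance(sites, cov$track)
      ifelse(is.infinite(d), "inf", paste0("d", bin_values(d, cov$cb)))
    },
    score = {
      s <- score_at(sites, cov$track)
      ifelse(is.na(s), "missing", paste0("s", bin_values(s, cov$cb)))
    },
    stop("motif covariates do not stratify"))
}

#' Stratify sites by the joint labels of covariates
#'
#' Every site receives exactly one joint label (one level per stratifying
#' covariate); distance and score covariates are discretized into
#' equal-frequency bins whose breaks are computed from these sites.
#' Motif covariates do not stratify and are ignored here.
#'
#' @param sites A [position_set()].
#' @param covariates List of [covariate()] objects, at least one of which
#'   stratifies (kind other than `"motif"`).
#' @return List with `labels` (joint label per site), `counts` (named
#'   count per stratum, summing to `length(sites)`), and `covariates`
#'   (the prepared covariates with their breaks attached).
#' @export
stratify <- function(sites, covariates) {
  if (inherits(covariates, "covariate")) covariates <- list(covariates)
  strat <- Filter(function(cv) cv$kind != "motif", covariates)
  if (!length(strat)) stop("need at least one stratifying covariate")
  strat <- lapply(strat, prepare_covariate, signal = sites)
  per_cov <- lapply(strat, covariate_labels, sites = sites)
  labels <- do.call(paste, c(per_cov, sep = "|"))
  counts <- table(labels)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(labels = labels, counts = counts, covariates = strat)
}

# --- uniform sampling ----------------------------------------------------

full_track <- function(assembly) {
  interval_track(iv_df(names(assembly), 0, as.numeric(assembly)),
                 label = "genome")
}

# uniform base draw from a union of intervals, using the current RNG stream
uniform_from_intervals <- function(ivs, k) {
  if (!nrow(ivs) || k == 0) {
    return(list(contig = character(), coord = numeric()))
  }
  w <- ivs$end - ivs$start
  i <- sample.int(nrow(ivs), k, replace = TRUE, prob = w)
  list(contig = ivs$contig[i],
       coord = ivs$start[i] + floor(stats::runif(k) * w[i]))
}

new_background <- function(contig, coord, label, provenance) {
  structure(list(sites = position_set(contig, coord, label = label),
                 provenance = provenance),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model: ", length(x$sites), " site(s), model = ",
      x$provenance$model, ", seed = ",
      x$provenance$seed %||% NA, "\n", sep = "")
  invisible(x)
}

#' @export
length.background_model <- function(x) length(x$sites)

#' Extract the position set of a background model
#'
#' @param x A `background_model` or [position_set()].
#' @return A [position_set()].
#' @export
background_sites <- function(x) {
  if (inherits(x, "background_model")) x$sites else x
}

#' Sample control sites uniformly from the genome
#'
#' Each base of the sampleable universe (the whole assembly, or the
#' `restrict` track, e.g. sequence contigs or a mappability mask) is
#' equally likely; sampling is with replacement and deterministic for a
#' fixed seed.
#'
#' @param assembly A [genome_assembly()].
#' @param n Number of control sites (default 10,000).
#' @param seed Integer seed.
#' @param restrict Optional [interval_track()] restricting the universe.
#' @param label Label for the control set.
#' @return A `background_model`.
#' @export
sample_uniform <- function(assembly, n = 10000, seed = 1, restrict = NULL,
                           label = "uniform background") {
  stopifnot(n >= 1)
  universe <- if (is.null(restrict)) full_track(assembly) else restrict
  if (!nrow(universe$ivs)) stop("empty sampling universe")
  draw <- with_op_seed(seed, "sample_uniform",
                       uniform_from_intervals(universe$ivs, n))
  new_background(draw$contig, draw$coord, label,
                 list(model = "uniform", n = n, seed = seed,
                      restricted = !is.null(restrict)))
}

# --- covariate-matched sampling ------------------------------------------

# Candidate universe (an interval data frame) for one set-type constraint:
# membership in/out, score bin/missing, or the feature-less-contig stratum
# of a distance covariate.  Returns NULL for finite distance bins, which
# are handled by feature-offset placement instead.
stratum_universe <- function(cov, level, assembly, restrict) {
  base <- switch(cov$kind,
    membership = if (level == "in") cov$track else
      complement_track(cov$track, assembly),
    score = if (level == "missing") {
      complement_track(
        interval_track(cov$track$ivs, label = cov$track$label), assembly)
    } else {
      b <- as.integer(sub("^s", "", level))
      keep <- bin_values(cov$track$ivs$score, cov$cb) == b
      interval_track(cov$track$ivs[keep, , drop = FALSE],
                     label = paste0(cov$track$label, ":bin", b))
    },
    distance = if (level == "inf") {
      ctgs <- setdiff(names(assembly), unique(cov$track$ivs$contig))
      if (!length(ctgs)) return(interval_track(iv_df(), label = "empty"))
      sub <- unclass(assembly)[ctgs]
      interval_track(iv_df(ctgs, 0, as.numeric(sub)), label = "featureless")
    } else {
      return(NULL)
    })
  blend_tracks(base, restrict, "intersection")
}

# Place k candidate sites at given distances from features of `track`:
# feature chosen uniformly, side uniformly, offset from the feature edge
# (offset 0 = uniform base within the feature).  Out-of-bounds placements
# are dropped (callers retry).
place_at_distance <- function(track, offsets, assembly) {
  k <- length(offsets)
  ivs <- track$ivs
  i <- sample.int(nrow(ivs), k, replace = TRUE)
  side <- stats::runif(k) < 0.5
  w <- ivs$end[i] - ivs$start[i]
  coord <- ifelse(offsets == 0,
                  ivs$start[i] + floor(stats::runif(k) * w),
                  ifelse(side, ivs$start[i] - offsets,
                         ivs$end[i] - 1 + offsets))
  contig <- ivs$contig[i]
  ok <- coord >= 0 & coord < contig_length(assembly, contig)
  list(contig = contig[ok], coord = coord[ok])
}

# Fill one stratum of a joint covariate combination with k control sites.
# Strategy: if the stratum pins a finite distance bin, propose sites by
# feature-offset placement (offsets resampled from the signal's distances
# in that bin) and reject against the remaining covariates; otherwise all
# constraints are base sets, so sample directly from their intersection.
fill_stratum <- function(levels, covs, k, assembly, restrict, target_label,
                         max_attempts_per_site = 10000) {
  kinds <- vapply(covs, `[[`, "", "kind")
  dist_finite <- which(kinds == "distance" & levels != "inf")
  universes <- list()
  for (j in seq_along(covs)) {
    if (j %in% dist_finite) next
    universes <- c(universes,
                   list(stratum_universe(covs[[j]], levels[j], assembly,
                                         restrict)))
  }
  universe <- Reduce(function(a, b) blend_tracks(a, b, "intersection"),
                     universes, accumulate = FALSE) %||% restrict

  if (!length(dist_finite)) {
    if (!nrow(universe$ivs)) {
      stop("unsatisfiable stratum '", target_label,
           "': no genomic base matches this covariate combination")
    }
    draw <- uniform_from_intervals(universe$ivs, k)
    # direct construction: the universe realises the label by definition
    return(draw)
  }

  dcov <- covs[[dist_finite[1]]]
  bin <- as.integer(sub("^d", "", levels[dist_finite[1]]))
  pool <- dcov$signal_values[
    is.finite(dcov$signal_values) &
      bin_values(dcov$signal_values, dcov$cb) == bin]
  if (!length(pool)) {
    stop("unsatisfiable stratum '", target_label, "': empty offset pool")
  }
  got_contig <- character()
  got_coord <- numeric()
  attempts <- 0
  cap <- max_attempts_per_site * k
  while (length(got_coord) < k) {
    need <- k - length(got_coord)
    m <- max(2L * need, 64L)
    if (attempts + m > cap) m <- cap - attempts
    if (m <= 0) {
      stop("unsatisfiable stratum '", target_label,
           "': retry cap exhausted after ", attempts, " attempts")
    }
    attempts <- attempts + m
    cand <- place_at_distance(
      dcov$track, pool[sample.int(length(pool), m, replace = TRUE)], assembly)
    if (!length(cand$coord)) next
    cs <- position_set(cand$contig, cand$coord)
    lab <- joint_labels(covs, cs)
    keep <- lab == target_label & membership_flags(cs, universe_or_full(
      universe, assembly))
    if (any(keep)) {
      take <- which(keep)[seq_len(min(need, sum(keep)))]
      got_contig <- c(got_contig, cand$contig[take])
      got_coord <- c(got_coord, cand$coord[take])
    }
  }
  list(contig = got_contig, coord = got_coord)
}

universe_or_full <- function(universe, assembly) {
  if (is.null(universe)) full_track(assembly) else universe
}

joint_labels <- function(covs, sites) {
  per_cov <- lapply(covs, covariate_labels, sites = sites)
  do.call(paste, c(per_cov, sep = "|"))
}

#' Sample control sites matched to the signal on covariates
#'
#' Stratifies the signal sites by the joint labels of the given covariates
#' and allocates the requested number of control sites across strata in
#' the signal's proportions (largest-remainder apportionment, so the match
#' is exact up to integer rounding).  Within a stratum, membership and
#' score constraints are sampled directly from the matching base sets;
#' finite distance bins are sampled by feature-offset placement with
#' rejection against the remaining covariates.  A motif covariate does not
#' stratify: the stratified sample (or a uniform sample, if the motif is
#' the only covariate) serves as the candidate pool for
#' [sample_motif_matched()].
#'
#' @param signal The signal [position_set()].
#' @param covariates A [covariate()] or list of covariates.
#' @param assembly A [genome_assembly()].
#' @param n Number of control sites (default 10,000).
#' @param seed Integer seed.
#' @param restrict Optional [interval_track()] restricting the universe.
#' @param sequences A `genome_seqs` object; required for motif covariates.
#' @param pool_size Candidate pool size for motif weighting
#'   (default `max(100 * n, 1e5)`).
#' @return A `background_model` whose provenance records the covariates,
#'   seed, requested size and per-stratum allocation.
#' @export
sample_matched <- function(signal, covariates, assembly, n = 10000, seed = 1,
                           restrict = NULL, sequences = NULL,
                           pool_size = NULL) {
  stopifnot(n >= 1, length(signal) >= 1)
  if (inherits(covariates, "covariate")) covariates <- list(covariates)
  restrict <- restrict %||% full_track(assembly)
  motif_covs <- Filter(function(cv) cv$kind == "motif", covariates)
  strat_covs <- Filter(function(cv) cv$kind != "motif", covariates)
  if (length(motif_covs) > 1) stop("at most one motif covariate is supported")
  has_motif <- length(motif_covs) == 1
  n_pool <- if (has_motif) max(pool_size %||% max(100 * n, 1e5), n) else n
  if (has_motif && is.null(sequences)) {
    stop("motif covariate requires genome sequences")
  }

  with_op_seed(seed, "sample_matched", {
    if (length(strat_covs)) {
      st <- stratify(signal, strat_covs)
      alloc <- largest_remainder(st$counts, n_pool)
      if (n < sum(st$counts > 0)) {
        warning("requested size ", n, " is below the number of non-empty ",
                "strata (", sum(st$counts > 0), ")")
      }
      parts <- lapply(names(alloc)[alloc > 0], function(lab) {
        levels <- strsplit(lab, "|", fixed = TRUE)[[1]]
        fill_stratum(levels, st$covariates, alloc[[lab]], assembly,
                     restrict, lab)
      })
      contig <- unlist(lapply(parts, `[[`, "contig"))
      coord <- unlist(lapply(parts, `[[`, "coord"))
      prov_alloc <- alloc
    } else {
      draw <- uniform_from_intervals(restrict$ivs, n_pool)
      contig <- draw$contig
      coord <- draw$coord
      prov_alloc <- NULL
    }

    if (has_motif) {
      pool <- position_set(contig, coord)
      w <- pfm_weights(motif_covs[[1]]$pfm, sequences, pool)
      if (all(w == 0)) stop("all motif weights are zero in the pool")
      pick <- sample.int(length(w), n, replace = TRUE, prob = w)
      contig <- pool$contig[pick]
      coord <- pool$coord[pick]
    }

    new_background(
      contig, coord, "matched background",
      list(model = "matched",
           covariates = vapply(covariates, function(cv) cv$kind, ""),
           n = n, seed = seed, allocation = prov_alloc,
           pool_size = if (has_motif) n_pool else NULL))
  })
}

#' Sample control sites matching the signal's distances to track features
#'
#' Reproduces the signal's empirical distribution of distances to the
#' nearest feature of `track` (e.g. enzyme restriction sites): each
#' control site is placed by drawing a distance from the signal's distance
#' multiset (with replacement, or the exact multiset when
#' `resample = FALSE` and `n = length(signal)`), choosing a feature and a
#' side uniformly at random, and stepping the drawn offset away from the
#' feature edge.  Placements whose realized nearest distance differs from
#' the drawn one (contig edge, interference from a nearer feature) are
#' retried, so realized control distances equal the drawn distances
#' exactly.
#'
#' @param signal The signal [position_set()].
#' @param track A non-empty [interval_track()] of features.
#' @param assembly A [genome_assembly()].
#' @param n Number of control sites.
#' @param seed Integer seed.
#' @param resample Draw distances with replacement (`TRUE`), or copy the
#'   signal's distance multiset exactly (requires `n = length(signal)`).
#' @param max_tries Retry cap per control site.
#' @return A `background_model`.
#' @export
sample_distance_matched <- function(signal, track, assembly,
                                    n = length(signal), seed = 1,
                                    resample = TRUE, max_tries = 10000) {
  if (!nrow(track$ivs)) stop("empty track")
  dsig <- nearest_distance(signal, track)
  if (!resample && n != length(signal)) {
    stop("resample = FALSE requires n = length(signal)")
  }
  with_op_seed(seed, "sample_distance_matched", {
    offsets <- if (resample) {
      dsig[sample.int(length(dsig), n, replace = TRUE)]
    } else dsig
    contig <- character(n)
    coord <- numeric(n)

    inf_idx <- which(is.infinite(offsets))
    if (length(inf_idx)) {
      ctgs <- setdiff(names(assembly), unique(track$ivs$contig))
      if (!length(ctgs)) {
        stop("cannot place infinite-distance sites: every contig has features")
      }
      sub <- unclass(assembly)[ctgs]
      draw <- uniform_from_intervals(iv_df(ctgs, 0, as.numeric(sub)),
                                     length(inf_idx))
      contig[inf_idx] <- draw$contig
      coord[inf_idx] <- draw$coord
    }

    pending <- which(is.finite(offsets))
    tries <- 0
    while (length(pending)) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("distance placement retry cap (", max_tries,
             ") exhausted for ", length(pending), " site(s)")
      }
      cand <- place_at_distance_keep(track, offsets[pending], assembly)
      ok <- !is.na(cand$coord)
      if (any(ok)) {
        cs <- position_set(cand$contig[ok], cand$coord[ok])
        realized <- nearest_distance(cs, track)
        good <- realized == offsets[pending][ok]
        idx <- pending[ok][good]
        contig[idx] <- cand$contig[ok][good]
        coord[idx] <- cand$coord[ok][good]
        pending <- setdiff(pending, idx)
      }
    }
    new_background(contig, coord, "distance-matched background",
                   list(model = "distance_matched", n = n, seed = seed,
                        resample = resample, track = track$label))
  })
}

# like place_at_distance but keeps alignment with its input (NA coord for
# out-of-bounds placements)
place_at_distance_keep <- function(track, offsets, assembly) {
  k <- length(offsets)
  ivs <- track$ivs
  i <- sample.int(nrow(ivs), k, replace = TRUE)
  side <- stats::runif(k) < 0.5
  w <- ivs$end[i] - ivs$start[i]
  coord <- ifelse(offsets == 0,
                  ivs$start[i] + floor(stats::runif(k) * w),
                  ifelse(side, ivs$start[i] - offsets,
                         ivs$end[i] - 1 + offsets))
  contig <- ivs$contig[i]
  bad <- coord < 0 | coord >= contig_length(assembly, contig)
  coord[bad] <- NA
  list(contig = contig, coord = coord)
}

#' Load a user-supplied background from a BED file
#'
#' @param path BED file of control sites.
#' @param assembly A [genome_assembly()].
#' @param drop_unknown Drop (rather than fail on) unknown-contig records.
#' @return A `background_model` with user-supplied provenance.
#' @export
load_background <- function(path, assembly, drop_unknown = FALSE) {
  ps <- read_bed_positions(path, assembly, drop_unknown = drop_unknown)
  structure(list(sites = ps,
                 provenance = list(model = "user_supplied", path = path,
                                   n = length(ps))),
            class = "background_model")
}

#' Write a background model as BED plus a provenance sidecar
#'
#' @param bg A `background_model`.
#' @param bed_path Output BED path; the provenance JSON is written next to
#'   it as `<bed_path>.json`.
#' @return Invisibly, `bed_path`.
#' @export
write_background <- function(bg, bed_path) {
  write_bed(background_sites(bg), bed_path)
  prov <- bg$provenance
  if (!is.null(prov$allocation)) {
    prov$allocation <- as.list(prov$allocation)
  }
  jsonlite::write_json(prov, paste0(bed_path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(bed_path)
}
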