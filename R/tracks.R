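# Annotation tracks: sorted interval lists per contig, plain or scored.
# IRanges provides the merge/complement/set-algebra machinery; coordinates
# at the package surface stay 0-based half-open.

iv_df <- function(contig = character(), start = numeric(), end = numeric(),
                  name = NULL, score = NULL) {
  df <- data.frame(contig = as.character(contig), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  df
}

# 0-based half-open -> IRanges (1-based closed) and back
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)
from_iranges <- function(ir) {
  list(start = as.numeric(IRanges::start(ir)) - 1,
       end = as.numeric(IRanges::end(ir)))
}

merge_intervals <- function(df) {
  if (!nrow(df)) return(iv_df())
  out <- lapply(split(df, df$contig), function(d) {
    r <- from_iranges(IRanges::reduce(to_iranges(d$start, d$end)))
    iv_df(d$contig[1], r$start, r$end)
  })
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Annotation track of genomic intervals
#'
#' Intervals are sorted by (contig, start); overlapping or adjacent
#' intervals are merged on construction, so a track is a plain base set.
#'
#' @param intervals Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param label Track label used in reports.
#' @param assembly Optional [genome_assembly()]; intervals are clipped to
#'   contig bounds when given.
#' @return An `interval_track` object.
#' @export
interval_track <- function(intervals, label = "track", assembly = NULL) {
  df <- iv_df(intervals$contig, intervals$start, intervals$end)
  if (nrow(df) && any(df$start >= df$end)) {
    stop("interval with start >= end")
  }
  if (!is.null(assembly)) df <- clip_to_assembly(df, assembly)
  structure(list(label = label, ivs = merge_intervals(df)),
            class = "interval_track")
}

#' Scored annotation track
#'
#' Like [interval_track()] but every interval carries a finite numeric
#' score.  Scored intervals must not overlap (each base has at most one
#' score); adjacency is allowed and intervals are never merged.
#'
#' @param intervals Data frame with columns `contig`, `start`, `end`,
#'   `score` and optionally `name`.
#' @inheritParams interval_track
#' @return A `scored_track` object (inherits `interval_track`).
#' @export
scored_track <- function(intervals, label = "track", assembly = NULL) {
  df <- iv_df(intervals$contig, intervals$start, intervals$end,
              name = intervals$name, score = intervals$score)
  if (!nrow(df)) stop("scored track must contain at least one interval")
  if (any(df$start >= df$end)) stop("interval with start >= end")
  if (any(!is.finite(df$score))) stop("scored track requires finite scores")
  if (!is.null(assembly)) df <- clip_to_assembly(df, assembly)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_contig <- split(df, df$contig)
  for (d in by_contig) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping intervals in scored track '", label,
           "' on contig ", d$contig[1])
    }
  }
  structure(list(label = label, ivs = df),
            class = c("scored_track", "interval_track"))
}

#' @export
print.interval_track <- function(x, ...) {
  cat(if (inherits(x, "scored_track")) "scored_track '" else "interval_track '",
      x$label, "': ", nrow(x$ivs), " interval(s), ",
      format(sum(x$ivs$end - x$ivs$start), big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

track_bases <- function(track) sum(track$ivs$end - track$ivs$start)

clip_to_assembly <- function(df, assembly) {
  unknown <- setdiff(unique(df$contig), names(assembly))
  if (length(unknown)) stop("interval on contig absent from assembly: ", unknown[1])
  lens <- contig_length(assembly, df$contig)
  df$start <- pmax(df$start, 0)
  df$end <- pmin(df$end, lens)
  df[df$start < df$end, , drop = FALSE]
}

#' Read an annotation track from a BED file
#'
#' Plain tracks (BED3) are clipped to contig bounds and merged.  Scored
#' tracks are auto-detected: 5+ columns with a numeric column 5 are read as
#' BED5 (name in column 4, score in column 5); exactly 4 columns with a
#' numeric column 4 as bedGraph.  Ambiguity can be resolved with an explicit
#' `format`.
#'
#' @param path BED file.
#' @param assembly A [genome_assembly()].
#' @param scored Read as a scored track?
#' @param label Track label (defaults to the file name).
#' @param format One of `"auto"`, `"bed5"`, `"bedgraph"`; only consulted
#'   when `scored = TRUE`.
#' @param drop_unknown Drop (rather than fail on) unknown-contig records.
#' @return An [interval_track()] or [scored_track()].
#' @export
read_bed_track <- function(path, assembly, scored = FALSE, label = NULL,
                           format = c("auto", "bed5", "bedgraph"),
                           drop_unknown = FALSE) {
  format <- match.arg(format)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  fields <- bed_fields(path)
  if (!length(fields)) {
    if (scored) stop("empty BED file for scored track: ", path)
    return(interval_track(iv_df(), label = label, assembly = assembly))
  }
  rec <- parse_bed_core(fields, path)
  rec <- filter_unknown(rec, assembly, drop_unknown, "interval")
  if (!scored) {
    return(interval_track(
      iv_df(rec$contig, rec$start, rec$end), label = label,
      assembly = assembly))
  }
  ncol <- rec$ncol
  col_or_na <- function(i) {
    vapply(seq_along(rec$fields), function(j) {
      if (ncol[j] >= i) rec$fields[[j]][[i]] else NA_character_
    }, "")
  }
  c4 <- col_or_na(4L)
  c5 <- col_or_na(5L)
  numeric_col <- function(x) length(x) > 0 && !any(is.na(suppressWarnings(as.numeric(x))))
  dialect <- if (format != "auto") {
    format
  } else if (all(ncol >= 5L) && numeric_col(c5)) {
    "bed5"
  } else if (all(ncol == 4L) && numeric_col(c4)) {
    "bedgraph"
  } else {
    stop("cannot detect a numeric score column in ", path,
         "; pass format = \"bed5\" or \"bedgraph\"")
  }
  if (dialect == "bed5") {
    if (any(ncol < 5L)) stop("BED5 record with fewer than 5 columns in ", path)
    score <- suppressWarnings(as.numeric(c5))
    name <- c4
  } else {
    if (any(ncol < 4L)) stop("bedGraph record with fewer than 4 columns in ", path)
    score <- suppressWarnings(as.numeric(c4))
    name <- NULL
  }
  if (any(is.na(score))) stop("non-numeric score in ", path)
  scored_track(iv_df(rec$contig, rec$start, rec$end, name = name, score = score),
               label = label, assembly = assembly)
}
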