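# analysis: orchestration of enrichment runs -- single-set analysis,
# multi-set batches, background-model comparison, hotspot detection,
# per-chromosome positional enrichment, CSV export.

#' Enrichment analysis of a signal set against a background
#'
#' For every track, counts signal and background membership, builds the
#' 2x2 contingency table, and computes fold change, the Pearson chi-square
#' test and Bonferroni-adjusted p-values (`m` = number of tracks tested in
#' this run).  Scored tracks additionally get a two-sample
#' Kolmogorov-Smirnov test comparing the signal's and background's score
#' distributions.  Rows are ranked by effect strength (absolute log2 fold
#' change).
#'
#' @param signal The signal [position_set()].
#' @param background A `background_model` or [position_set()] of control
#'   sites.
#' @param tracks A single track or list of [interval_track()] /
#'   [scored_track()] objects.
#' @param alpha Significance level applied to adjusted p-values.
#' @return A `result_table`: a data frame with one row per track (columns
#'   `track`, `s_in`, `s_out`, `b_in`, `b_out`, `fold_change`, `log2_fc`,
#'   `chi2`, `p_raw`, `p_adj`, `ks_D`, `ks_p`, `significant`) plus run
#'   metadata attributes.
#' @export
analyze <- function(signal, background, tracks, alpha = 0.05) {
  if (inherits(tracks, "interval_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1)
  bg <- background_sites(background)
  if (!length(signal)) stop("empty signal set")
  if (!length(bg)) stop("empty background set")
  m <- length(tracks)
  rows <- lapply(tracks, function(tr) {
    cs <- count_membership(signal, tr)
    cb <- count_membership(bg, tr)
    ct <- contingency_table(cs$n_in, cs$n_out, cb$n_in, cb$n_out)
    fc <- fold_change(ct)
    chi <- chi2_test(ct)
    row <- data.frame(track = tr$label, s_in = cs$n_in, s_out = cs$n_out,
                      b_in = cb$n_in, b_out = cb$n_out,
                      fold_change = fc$fc, log2_fc = fc$log2_fc,
                      chi2 = chi$stat, p_raw = chi$p,
                      ks_D = NA_real_, ks_p = NA_real_,
                      stringsAsFactors = FALSE)
    if (inherits(tr, "scored_track")) {
      ss <- score_at(signal, tr)
      sb <- score_at(bg, tr)
      if (any(!is.na(ss)) && any(!is.na(sb))) {
        ks <- suppressMessages(ks_test(ss, sb))
        row$ks_D <- ks$D
        row$ks_p <- ks$p
      }
    }
    row
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bonferroni(res$p_raw, m)
  res$significant <- res$p_adj < alpha
  res <- rank_results(res)
  res <- res[, c("track", "s_in", "s_out", "b_in", "b_out", "fold_change",
                 "log2_fc", "chi2", "p_raw", "p_adj", "ks_D", "ks_p",
                 "significant")]
  structure(res,
            class = c("result_table", "data.frame"),
            signal_label = signal$label,
            background_provenance =
              if (inherits(background, "background_model"))
                background$provenance else list(model = "position_set"),
            m = m, alpha = alpha)
}

#' Batch analysis of several signal sets against one shared background
#'
#' Every signal set is analyzed against the same background and tracks;
#' the result is a matrix of log2 fold changes with significance flags.
#' Bonferroni correction here spans the whole matrix
#' (`m` = sets x tracks), the conservative choice for a heatmap of many
#' simultaneous comparisons.
#'
#' @param signals List of [position_set()] objects.
#' @param background Shared `background_model` or [position_set()].
#' @param tracks List of tracks.
#' @param alpha Significance level on adjusted p-values.
#' @return A `batch_matrix`: list with matrices `log2_fc` and
#'   `significant` (rows = signal sets, columns = tracks) and `alpha`.
#' @export
batch <- function(signals, background, tracks, alpha = 0.05) {
  if (inherits(signals, "position_set")) signals <- list(signals)
  if (inherits(tracks, "interval_track")) tracks <- list(tracks)
  stopifnot(length(signals) >= 1)
  m <- length(signals) * length(tracks)
  row_names <- vapply(signals, function(s) s$label, "")
  col_names <- vapply(tracks, function(tr) tr$label, "")
  lfc <- matrix(NA_real_, length(signals), length(tracks),
                dimnames = list(row_names, col_names))
  sig <- matrix(NA, length(signals), length(tracks),
                dimnames = list(row_names, col_names))
  for (i in seq_along(signals)) {
    res <- analyze(signals[[i]], background, tracks, alpha = alpha)
    res$p_adj <- bonferroni(res$p_raw, m)   # matrix-wide correction
    for (j in seq_along(tracks)) {
      r <- res[res$track == col_names[j], ]
      lfc[i, j] <- r$log2_fc[1]
      sig[i, j] <- r$p_adj[1] < alpha
    }
  }
  structure(list(log2_fc = lfc, significant = sig, alpha = alpha,
                 kind = "signals"),
            class = "batch_matrix")
}

#' Compare the effect of different background models on one signal set
#'
#' Rows are background models, columns tracks; cells as in [batch()].
#' Adding a covariate that matches the background to the signal on a track
#' moves that track's cell toward 0 (the neutralization mechanism).
#'
#' @param signal The signal [position_set()].
#' @param backgrounds List of at least two `background_model`s.
#' @param tracks List of tracks.
#' @param alpha Significance level.
#' @return A `batch_matrix` with one row per background model.
#' @export
compare_backgrounds <- function(signal, backgrounds, tracks, alpha = 0.05) {
  stopifnot(length(backgrounds) >= 2)
  if (inherits(tracks, "interval_track")) tracks <- list(tracks)
  m <- length(backgrounds) * length(tracks)
  row_names <- vapply(seq_along(backgrounds), function(i) {
    bg <- backgrounds[[i]]
    if (inherits(bg, "background_model")) {
      paste0(bg$provenance$model, "_", i)
    } else paste0("background_", i)
  }, "")
  col_names <- vapply(tracks, function(tr) tr$label, "")
  lfc <- matrix(NA_real_, length(backgrounds), length(tracks),
                dimnames = list(row_names, col_names))
  sig <- matrix(NA, length(backgrounds), length(tracks),
                dimnames = list(row_names, col_names))
  for (i in seq_along(backgrounds)) {
    res <- analyze(signal, backgrounds[[i]], tracks, alpha = alpha)
    res$p_adj <- bonferroni(res$p_raw, m)
    for (j in seq_along(tracks)) {
      r <- res[res$track == col_names[j], ]
      lfc[i, j] <- r$log2_fc[1]
      sig[i, j] <- r$p_adj[1] < alpha
    }
  }
  structure(list(log2_fc = lfc, significant = sig, alpha = alpha,
                 kind = "backgrounds"),
            class = "batch_matrix")
}

#' Hotspot detection: windows with a disproportionate share of sites
#'
#' Tiles every contig with non-overlapping windows starting at 0 (the last
#' window of a contig is truncated), counts the signal sites per window,
#' and reports the integration ratio `count / length(signal)`.  Windows
#' are sorted by count descending, ties in genomic order.
#'
#' @param signal A [position_set()].
#' @param assembly A [genome_assembly()].
#' @param window Window width in bases (default 1 Mb).
#' @return Data frame with columns `contig`, `start`, `end`, `count`,
#'   `ratio`; counts sum to `length(signal)`.
#' @export
hotspots <- function(signal, assembly, window = 1e6) {
  stopifnot(window >= 1)
  parts <- lapply(names(assembly), function(ctg) {
    len <- contig_length(assembly, ctg)
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    cnt <- integer(length(starts))
    p <- signal$coord[signal$contig == ctg]
    if (length(p)) {
      bin <- floor(p / window) + 1
      tab <- tabulate(bin, nbins = length(starts))
      cnt <- tab
    }
    data.frame(contig = ctg, start = starts, end = ends, count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out$ratio <- out$count / length(signal)
  out <- out[order(-out$count, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional enrichment of signal vs background along each contig
#'
#' Tiles contigs into bins and reports the pseudocounted log2 rate ratio
#' `log2(((s_i + 0.5) / (|S| + 0.5 k)) / ((b_i + 0.5) / (|B| + 0.5 k)))`
#' per bin, with `k` the total number of bins.
#'
#' @param signal A [position_set()].
#' @param background A `background_model` or [position_set()].
#' @param assembly A [genome_assembly()].
#' @param bin Bin width in bases (default 1 Mb).
#' @return Data frame with columns `contig`, `start`, `end`, `s_count`,
#'   `b_count`, `log2_enrichment`.
#' @export
positional_enrichment <- function(signal, background, assembly, bin = 1e6) {
  stopifnot(bin >= 1)
  bg <- background_sites(background)
  parts <- lapply(names(assembly), function(ctg) {
    len <- contig_length(assembly, ctg)
    starts <- seq(0, len - 1, by = bin)
    ends <- pmin(starts + bin, len)
    count_in <- function(ps) {
      p <- ps$coord[ps$contig == ctg]
      if (length(p)) tabulate(floor(p / bin) + 1, nbins = length(starts))
      else integer(length(starts))
    }
    data.frame(contig = ctg, start = starts, end = ends,
               s_count = count_in(signal), b_count = count_in(bg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  k <- nrow(out)
  s_rate <- (out$s_count + 0.5) / (length(signal) + 0.5 * k)
  b_rate <- (out$b_count + 0.5) / (length(bg) + 0.5 * k)
  out$log2_enrichment <- log2(s_rate / b_rate)
  rownames(out) <- NULL
  out
}

#' Export results as CSV
#'
#' Result tables are written with the fixed column set `track, s_in,
#' s_out, b_in, b_out, fold_change, log2_fc, chi2, p_raw, p_adj,
#' significant` (KS columns appended when any scored track was tested);
#' reals carry 6 significant digits and infinite fold changes print as
#' `inf`.  Batch matrices are written with the signal (or background)
#' label in the first column and one column per track, each cell the log2
#' fold change with a `*` suffix when significant.
#'
#' @param x A `result_table` or `batch_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(x, path) UseMethod("export_csv")

#' @export
export_csv.result_table <- function(x, path) {
  cols <- c("track", "s_in", "s_out", "b_in", "b_out", "fold_change",
            "log2_fc", "chi2", "p_raw", "p_adj", "significant")
  has_ks <- any(!is.na(x$ks_D))
  if (has_ks) cols <- append(cols, c("ks_D", "ks_p"), after = 10)
  header <- paste(cols, collapse = ",")
  fmt_cell <- function(col, v) {
    if (col %in% c("track")) as.character(v)
    else if (col %in% c("s_in", "s_out", "b_in", "b_out")) {
      as.character(as.integer(v))
    } else if (col == "significant") tolower(as.character(v))
    else fmt_num(v)
  }
  lines <- if (nrow(x)) {
    cells <- vapply(cols, function(cl) fmt_cell(cl, x[[cl]]),
                    character(nrow(x)))
    if (nrow(x) == 1) cells <- matrix(cells, nrow = 1)
    apply(cells, 1, paste, collapse = ",")
  } else character()
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @export
export_csv.batch_matrix <- function(x, path) {
  first <- if (x$kind == "backgrounds") "background" else "signal"
  header <- paste(c(first, colnames(x$log2_fc)), collapse = ",")
  lines <- vapply(seq_len(nrow(x$log2_fc)), function(i) {
    cells <- paste0(fmt_num(x$log2_fc[i, ]),
                    ifelse(x$significant[i, ], "*", ""))
    paste(c(rownames(x$log2_fc)[i], cells), collapse = ",")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Dump a batch matrix as JSON
#'
#' @param x A `batch_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_json <- function(x, path) {
  stopifnot(inherits(x, "batch_matrix"))
  obj <- list(kind = x$kind, alpha = x$alpha,
              rows = rownames(x$log2_fc), columns = colnames(x$log2_fc),
              log2_fc = unname(apply(x$log2_fc, 1, as.list)),
              significant = unname(apply(x$significant, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
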