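# genome_io: domain types (assembly, position sets) and text readers/writers
# for chrom.sizes, BED and FASTA.  All coordinates are 0-based, half-open
# (BED native) throughout the package.

#' Genome assembly: named contig lengths
#'
#' Defines the sampleable universe for background generation: an ordered set
#' of contig names with their lengths in bases.
#'
#' @param lengths Named numeric vector of contig lengths (bases, >= 1).
#' @return A `genome_assembly` object.
#' @examples
#' genome_assembly(c(chr1 = 1000, chr2 = 500))
#' @export
genome_assembly <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("contig names must be non-empty")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig name: ", nm[duplicated(nm)][1])
  }
  if (any(is.na(lengths)) || any(lengths != floor(lengths)) || any(lengths < 1)) {
    stop("contig lengths must be integers >= 1")
  }
  v <- as.numeric(lengths)
  names(v) <- nm
  structure(v, class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x), "contig(s),",
      format(sum(x), big.mark = ","), "bases\n")
  invisible(x)
}

contig_length <- function(assembly, contig) {
  unname(unclass(assembly)[contig])
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: contig name and length.  Extra columns are
#' ignored.  Duplicate contigs, non-integer or non-positive lengths, and
#' empty files are errors.
#'
#' @param path Path to a chrom.sizes TSV.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty chrom.sizes file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) stop("chrom.sizes line ", bad[1], " has fewer than 2 columns")
  nm <- vapply(fields, `[[`, "", 1L)
  lenstr <- vapply(fields, `[[`, "", 2L)
  len <- suppressWarnings(as.numeric(lenstr))
  if (any(is.na(len)) || any(len != floor(len))) {
    stop("non-integer contig length in ", path, ": ",
         lenstr[is.na(len) | len != floor(len)][1])
  }
  genome_assembly(stats::setNames(len, nm))
}

#' Position set: a named multiset of single-base genomic sites
#'
#' Duplicate positions are permitted (independent integration events may
#' coincide at one base).
#'
#' @param contig Character vector of contig names.
#' @param coord Numeric vector of 0-based base offsets.
#' @param label Set label used in reports.
#' @param assembly Optional [genome_assembly()]; when given, coordinates are
#'   validated against contig bounds.
#' @return A `position_set` object.
#' @export
position_set <- function(contig, coord, label = "sites", assembly = NULL) {
  stopifnot(length(contig) == length(coord))
  coord <- as.numeric(coord)
  if (length(coord) && (any(is.na(coord)) || any(coord != floor(coord)) || any(coord < 0))) {
    stop("coordinates must be non-negative integers")
  }
  if (!is.null(assembly)) {
    unknown <- setdiff(unique(contig), names(assembly))
    if (length(unknown)) stop("unknown contig: ", unknown[1])
    lens <- contig_length(assembly, contig)
    if (any(coord >= lens)) {
      i <- which(coord >= lens)[1]
      stop("coordinate ", coord[i], " outside contig ", contig[i],
           " (length ", lens[i], ")")
    }
  }
  structure(list(label = label, contig = as.character(contig), coord = coord),
            class = "position_set")
}

#' @export
length.position_set <- function(x) length(x$coord)

#' @export
print.position_set <- function(x, ...) {
  cat("position_set '", x$label, "': ", length(x), " site(s) on ",
      length(unique(x$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

# canonical (contig, coord) sort used for multiset comparisons and BED export
sort_positions <- function(ps) {
  o <- order(ps$contig, ps$coord)
  position_set(ps$contig[o], ps$coord[o], label = ps$label)
}

# --- BED parsing ---------------------------------------------------------

bed_fields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(list())
  strsplit(lines, "\t", fixed = TRUE)
}

parse_bed_core <- function(fields, path) {
  ncol <- vapply(fields, length, 0L)
  if (any(ncol < 3L)) {
    stop("malformed BED line (fewer than 3 columns) in ", path)
  }
  contig <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)) ||
      any(start != floor(start)) || any(end != floor(end))) {
    stop("malformed BED line (non-integer coordinates) in ", path)
  }
  if (any(start < 0)) stop("negative start coordinate in ", path)
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop("BED record with start >= end in ", path, ": ",
         contig[i], ":", start[i], "-", end[i])
  }
  list(contig = contig, start = start, end = end, ncol = ncol, fields = fields)
}

# unknown-contig policy shared by position/track readers
filter_unknown <- function(rec, assembly, drop_unknown, what) {
  known <- rec$contig %in% names(assembly)
  if (all(known)) return(rec)
  if (!drop_unknown) {
    stop("record on contig absent from assembly: ",
         unique(rec$contig[!known])[1],
         " (use drop_unknown = TRUE to drop such records)")
  }
  message("dropped ", sum(!known), " ", what, " record(s) on unknown contig(s)")
  rec$contig <- rec$contig[known]
  rec$start <- rec$start[known]
  rec$end <- rec$end[known]
  rec$ncol <- rec$ncol[known]
  rec$fields <- rec$fields[known]
  rec
}

#' Read signal/background positions from a BED file
#'
#' Each BED record is collapsed to a single base at the midpoint
#' `floor((start + end) / 2)` of the half-open interval; width-1 records are
#' their own midpoint.  `track`, `browser` and `#` lines are skipped.
#' Records on contigs absent from `assembly` are an error by default and are
#' dropped with a logged count when `drop_unknown = TRUE`.
#'
#' @param path BED3+ file.
#' @param assembly A [genome_assembly()].
#' @param label Label for the resulting set (defaults to the file name).
#' @param drop_unknown Drop (rather than fail on) unknown-contig records.
#' @return A [position_set()].
#' @export
read_bed_positions <- function(path, assembly, label = NULL,
                               drop_unknown = FALSE) {
  fields <- bed_fields(path)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  if (!length(fields)) {
    return(position_set(character(), numeric(), label = label))
  }
  rec <- parse_bed_core(fields, path)
  rec <- filter_unknown(rec, assembly, drop_unknown, "position")
  mid <- floor((rec$start + rec$end) / 2)
  position_set(rec$contig, mid, label = label, assembly = assembly)
}

#' Write positions or a track to a BED file
#'
#' Positions are emitted as width-1 records (`start = coord`,
#' `end = coord + 1`); tracks as BED3 (plus name/score columns when present).
#' Reading the written file back reproduces the object exactly.
#'
#' @param x A [position_set()] or [interval_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) UseMethod("write_bed")

#' @export
write_bed.position_set <- function(x, path) {
  s <- sort_positions(x)
  lines <- if (length(s)) {
    sprintf("%s\t%d\t%d", s$contig, as.integer(s$coord), as.integer(s$coord) + 1L)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' @export
write_bed.interval_track <- function(x, path) {
  iv <- x$ivs
  lines <- if (nrow(iv)) {
    if (!is.null(iv$score)) {
      sprintf("%s\t%d\t%d\t%s\t%s", iv$contig, as.integer(iv$start),
              as.integer(iv$end),
              if (is.null(iv$name)) "." else iv$name, fmt_num(iv$score))
    } else {
      sprintf("%s\t%d\t%d", iv$contig, as.integer(iv$start), as.integer(iv$end))
    }
  } else character()
  writeLines(lines, path)
  invisible(path)
}

# --- FASTA ---------------------------------------------------------------

#' Read genome sequence from a FASTA file
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' Bases are uppercased and any character outside A/C/G/T becomes `N`.
#' Required only for motif covariates and k-mer track extraction.
#'
#' @param path FASTA file.
#' @return A `genome_seqs` object (contig name -> base string).
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  strings <- toupper(as.character(dss))
  names(strings) <- vapply(strsplit(names(dss), "\\s+"), `[[`, "", 1L)
  strings <- vapply(strings, function(s) gsub("[^ACGT]", "N", s), "",
                    USE.NAMES = TRUE)
  genome_seqs(strings)
}

#' Construct a sequence store from named base strings
#'
#' @param strings Named character vector, one base string per contig.
#' @return A `genome_seqs` object.
#' @export
genome_seqs <- function(strings) {
  stopifnot(is.character(strings), !is.null(names(strings)))
  strings <- toupper(strings)
  strings <- vapply(strings, function(s) gsub("[^ACGT]", "N", s), "",
                    USE.NAMES = TRUE)
  env <- new.env(parent = emptyenv())
  env$strings <- strings
  env$codes <- new.env(parent = emptyenv())
  structure(env, class = "genome_seqs")
}

#' @export
print.genome_seqs <- function(x, ...) {
  cat("genome_seqs:", length(x$strings), "contig(s),",
      format(sum(nchar(x$strings)), big.mark = ","), "bases\n")
  invisible(x)
}

#' Extract a subsequence
#'
#' @param seqs A `genome_seqs` object.
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return Base string of length `end - start`.
#' @export
get_sequence <- function(seqs, contig, start, end) {
  if (!contig %in% names(seqs$strings)) {
    stop("contig absent from FASTA: ", contig)
  }
  s <- seqs$strings[[contig]]
  stopifnot(start >= 0, end <= nchar(s), start < end)
  substr(s, start + 1, end)
}

# Integer-coded view of a contig (A=1, C=2, G=3, T=4, N/other=0), cached.
seq_codes <- function(seqs, contig) {
  cached <- seqs$codes[[contig]]
  if (!is.null(cached)) return(cached)
  if (!contig %in% names(seqs$strings)) {
    stop("contig absent from FASTA: ", contig)
  }
  s <- seqs$strings[[contig]]
  raw <- utf8ToInt(s)
  code <- integer(length(raw))
  code[raw == utf8ToInt("A")] <- 1L
  code[raw == utf8ToInt("C")] <- 2L
  code[raw == utf8ToInt("G")] <- 3L
  code[raw == utf8ToInt("T")] <- 4L
  assign(contig, code, envir = seqs$codes)
  code
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `genome_seqs` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs$strings)) {
    writeLines(paste0(">", nm), con)
    s <- seqs$strings[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a chrom.sizes file
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(assembly, path) {
  writeLines(sprintf("%s\t%d", names(assembly), as.integer(assembly)), path)
  invisible(path)
}
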