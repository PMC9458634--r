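## Readers/writers for the BED-family text formats the pipeline touches.
## Parsing is deliberately strict: coordinates are taken verbatim as 0-based
## half-open and malformed lines are reported with their line number.

read_genomic_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_coord <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad))
    stop("non-integer ", what, " at line ", lineno[which(bad)[1L]],
         call. = FALSE)
  v
}

#' Read ChIP-seq peak calls
#'
#' Reads ENCODE narrowPeak (BED6+4), broadPeak (BED6+3) or plain BED peak
#' files. Coordinates are taken verbatim as 0-based half-open. Track and
#' comment lines are skipped; the result is sorted by `(chrom, start)`.
#'
#' @param path path to the peak file.
#' @param format one of `"auto"`, `"narrowPeak"`, `"broadPeak"`, `"bed"`.
#'   `"auto"` infers the format from the file extension and column count.
#' @param sample_id optional sample identifier stored as an attribute.
#' @return A sorted `data.frame` of peaks with columns `chrom`, `start`,
#'   `end` and, when present in the input, `name`, `score`, `strand`,
#'   `signal`, `pvalue`, `qvalue`, `summit`. Attributes `sample_id` and
#'   `format` record provenance. The `summit` column is preserved but not
#'   used by the density computation, which works from peak midpoints.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines(c("chrT\t0\t100", "chrT\t500\t900"), p)
#' read_peaks(p)
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "broadPeak", "bed"),
                       sample_id = NULL) {
  format <- match.arg(format)
  lr <- read_genomic_lines(path)
  fields <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf < 3L))
    stop("line ", lr$lineno[which(nf < 3L)[1L]], ": fewer than 3 fields",
         call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path) || (length(nf) && all(nf == 10L)))
      "narrowPeak"
    else if (grepl("\\.broadPeak$", path) || (length(nf) && all(nf == 9L)))
      "broadPeak"
    else "bed"
  }
  want <- switch(format, narrowPeak = 10L, broadPeak = 9L, bed = NA_integer_)
  if (!is.na(want) && length(nf) && any(nf != want))
    stop("line ", lr$lineno[which(nf != want)[1L]], ": expected ", want,
         " fields for ", format, call. = FALSE)
  if (!length(fields)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
    df <- data.frame(chrom = get(1L),
                     start = parse_coord(get(2L), lr$lineno, "start"),
                     end = parse_coord(get(3L), lr$lineno, "end"),
                     stringsAsFactors = FALSE)
    if (all(nf >= 4L)) df$name <- get(4L)
    if (all(nf >= 5L)) df$score <- suppressWarnings(as.numeric(get(5L)))
    if (all(nf >= 6L)) df$strand <- get(6L)
    if (format %in% c("narrowPeak", "broadPeak")) {
      df$signal <- as.numeric(get(7L))
      df$pvalue <- as.numeric(get(8L))
      df$qvalue <- as.numeric(get(9L))
      if (format == "narrowPeak") df$summit <- as.numeric(get(10L))
    }
    bad <- which(df$start >= df$end)
    if (length(bad))
      stop("line ", lr$lineno[bad[1L]], ": start >= end", call. = FALSE)
    if (any(df$start < 0))
      stop("line ", lr$lineno[which(df$start < 0)[1L]], ": negative start",
           call. = FALSE)
  }
  df <- sort_intervals(df)
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  attr(df, "format") <- format
  df
}

#' Read chromosome sizes
#'
#' @param path two-column whitespace-separated text file: chromosome name,
#'   length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom.sizes needs two columns", call. = FALSE)
  nm <- as.character(tab[[1L]])
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyDuplicated(nm))
    stop("duplicate chromosome: ", nm[duplicated(nm)][1L], call. = FALSE)
  if (any(is.na(len)) || any(len <= 0))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  stats::setNames(len, nm)
}

chrom_length <- function(chrom_sizes, chrom) {
  if (!chrom %in% names(chrom_sizes))
    stop("chromosome not in chrom.sizes: ", chrom, call. = FALSE)
  unname(chrom_sizes[[chrom]])
}

#' Write intervals as BED
#'
#' @param intervals interval `data.frame` (`chrom`, `start`, `end`,
#'   optional `name`); overlaps are permitted (e.g. peak sets).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  intervals <- sort_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals)) cols <- c(cols, "name")
  lines <- do.call(paste, c(lapply(cols, function(cn) {
    v <- intervals[[cn]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a domain or boundary set as BED
#'
#' @param domains sorted, non-overlapping interval `data.frame`
#'   (`chrom`, `start`, `end`, optional `name`).
#' @param path output path.
#' @return `path`, invisibly. Round-tripping through [read_bed()] returns
#'   the identical intervals.
#' @export
write_domains <- function(domains, path) {
  validate_intervals(domains, "domain")
  domains <- sort_intervals(domains)
  if (intervals_overlap_within(domains))
    stop("domains overlap; refusing to write", call. = FALSE)
  write_bed(domains, path)
}

#' Read a plain BED3(+name) file
#'
#' @param path path to BED file.
#' @return Sorted interval `data.frame` (`chrom`, `start`, `end`, and
#'   `name` when a 4th column is present).
#' @export
read_bed <- function(path) {
  df <- read_peaks(path, format = "bed")
  attr(df, "sample_id") <- NULL
  attr(df, "format") <- NULL
  df
}

#' Read point variants from BED
#'
#' Each record contributes one point coordinate (its start). Used for
#' pre-converted VCF positions (SNVs or indels).
#'
#' @param path BED file of variant positions.
#' @param class_label `"SNV"` or `"indel"`, stored as attribute.
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
read_variants <- function(path, class_label = "SNV") {
  df <- read_bed(path)
  out <- data.frame(chrom = df$chrom, pos = df$start, stringsAsFactors = FALSE)
  attr(out, "class_label") <- class_label
  out
}

#' Read anchor pairs (BEDPE-like)
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, and optionally
#' gene id plus foreground/background expression values.
#'
#' @param path path to the pair file.
#' @return `data.frame` with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, and when present `gene`, `expr_fg`, `expr_bg`.
#' @export
read_pairs <- function(path) {
  lr <- read_genomic_lines(path)
  fields <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf < 6L))
    stop("line ", lr$lineno[which(nf < 6L)[1L]],
         ": pair records need >= 6 columns", call. = FALSE)
  if (!length(fields))
    return(data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                      chrom2 = character(), start2 = numeric(), end2 = numeric()))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  df <- data.frame(chrom1 = get(1L),
                   start1 = parse_coord(get(2L), lr$lineno, "start1"),
                   end1 = parse_coord(get(3L), lr$lineno, "end1"),
                   chrom2 = get(4L),
                   start2 = parse_coord(get(5L), lr$lineno, "start2"),
                   end2 = parse_coord(get(6L), lr$lineno, "end2"),
                   stringsAsFactors = FALSE)
  if (all(nf >= 7L)) df$gene <- get(7L)
  if (all(nf >= 8L)) df$expr_fg <- suppressWarnings(as.numeric(get(8L)))
  if (all(nf >= 9L)) df$expr_bg <- suppressWarnings(as.numeric(get(9L)))
  bad <- which(df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad))
    stop("line ", lr$lineno[bad[1L]], ": start >= end", call. = FALSE)
  df
}

#' Read a Hi-C contact list
#'
#' Tab-separated records: chrom, bin_i start, bin_j start, observed,
#' expected (and optionally a precomputed log10 p column).
#'
#' @param path path to the contact list.
#' @return `data.frame` with columns `chrom`, `bin_i`, `bin_j`, `observed`,
#'   `expected` (and `log10_p` when present). Bins are normalized so that
#'   `bin_i <= bin_j`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) stop("contact list needs >= 5 columns", call. = FALSE)
  df <- data.frame(chrom = as.character(tab[[1L]]),
                   bin_i = as.numeric(tab[[2L]]), bin_j = as.numeric(tab[[3L]]),
                   observed = as.numeric(tab[[4L]]),
                   expected = as.numeric(tab[[5L]]),
                   stringsAsFactors = FALSE)
  if (ncol(tab) >= 6L) df$log10_p <- as.numeric(tab[[6L]])
  flip <- df$bin_i > df$bin_j
  tmp <- df$bin_i[flip]; df$bin_i[flip] <- df$bin_j[flip]; df$bin_j[flip] <- tmp
  if (any(df$observed < 0)) stop("negative observed count", call. = FALSE)
  df
}
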