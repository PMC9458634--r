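## Internal interval helpers. All coordinates in this package are 0-based
## half-open [start, end), the BED convention; 1-based sources must be
## converted before entering the package.

#' Construct a genomic interval table
#'
#' Builds and validates the plain `data.frame` representation of genomic
#' intervals used throughout the package: columns `chrom`, `start`, `end`
#' in 0-based half-open coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued vectors; `0 <= start < end`.
#' @param ... further equal-length columns carried along (e.g. `name`).
#' @return A `data.frame` with at least columns `chrom`, `start`, `end`,
#'   sorted by `(chrom, start)`.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop(what, ": non-numeric coordinates", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start coordinate", call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, ": start >= end at row ", bad[1L], call. = FALSE)
  invisible(df)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

## TRUE if any two intervals on the same chromosome overlap (assumes sorted)
intervals_overlap_within <- function(df) {
  if (nrow(df) < 2L) return(FALSE)
  df <- sort_intervals(df)
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  any(same & df$start[-1L] < df$end[-nrow(df)])
}

## Union of possibly-overlapping intervals, per chromosome
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- sort_intervals(df)
  out <- vector("list", length(unique(df$chrom)))
  k <- 0L
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    s <- d$start; e <- d$end
    keep_s <- s[1L]; keep_e <- e[1L]
    ms <- numeric(0); me <- numeric(0)
    if (nrow(d) > 1L) for (i in 2:nrow(d)) {
      if (s[i] <= keep_e) keep_e <- max(keep_e, e[i])
      else { ms <- c(ms, keep_s); me <- c(me, keep_e); keep_s <- s[i]; keep_e <- e[i] }
    }
    ms <- c(ms, keep_s); me <- c(me, keep_e)
    k <- k + 1L
    out[[k]] <- data.frame(chrom = chr, start = ms, end = me,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## For each point (chrom, pos), TRUE if it lies inside any interval of the
## (merged) set. Half-open: pos in [start, end).
points_in_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  if (nrow(intervals) == 0L) return(hit)
  m <- merge_intervals(intervals)
  for (chr in unique(m$chrom)) {
    sel <- chrom == chr
    if (!any(sel)) next
    d <- m[m$chrom == chr, , drop = FALSE]
    idx <- findInterval(pos[sel], d$start)
    ok <- idx > 0L
    ok[ok] <- pos[sel][ok] < d$end[idx[ok]]
    hit[sel] <- ok
  }
  hit
}

## For each query interval, TRUE if it intersects (>= 1 bp) any interval of
## the subject set.
intervals_overlap_any <- function(query, subject) {
  hit <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(hit)
  m <- merge_intervals(subject)
  for (chr in unique(m$chrom)) {
    sel <- query$chrom == chr
    if (!any(sel)) next
    d <- m[m$chrom == chr, , drop = FALSE]
    qs <- query$start[sel]; qe <- query$end[sel]
    ## overlap iff some subject with start < qe and end > qs; subjects are
    ## disjoint sorted so locate the first subject with end > qs
    idx <- findInterval(qs, d$end) + 1L   # d$end strictly > qs from here on
    ok <- idx <= nrow(d)
    ok[ok] <- d$start[idx[ok]] < qe[ok]
    hit[sel] <- ok
  }
  hit
}

## Complement of a sorted disjoint interval set within [0, chrom_length)
complement_intervals <- function(df, chrom, chrom_length) {
  d <- df[df$chrom == chrom, , drop = FALSE]
  d <- sort_intervals(d)
  starts <- c(0, d$end)
  ends <- c(d$start, chrom_length)
  keep <- ends > starts
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}
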