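## Sliding-window peak density, local polynomial smoothing and extrema
## detection -- the primitives behind the RAM caller.

#' Sliding-window peak density profile
#'
#' Counts peak midpoints in a sliding window of half-width `flank` evaluated
#' on a fixed grid of step `step` along each chromosome. The midpoint of a
#' peak `[start, end)` is `floor((start + end) / 2)`; a midpoint is counted
#' at bin center `c` when it lies in `[c - flank, c + flank)`. Windows are
#' truncated at chromosome ends and counts are not length-normalized.
#'
#' @param peaks sorted peak `data.frame` (see [read_peaks()]).
#' @param chrom_sizes named vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @param step grid step in bp (the paper's operating point is 250 kb).
#' @param flank window half-width in bp (default 500 kb).
#' @return A `density_profile`: `data.frame` with columns `chrom`, `bin`
#'   (bin index within chromosome, 1-based), `center` (bp) and `count`,
#'   with attributes `step` and `flank`. Each chromosome has
#'   `floor(length / step) + 1` bins at centers `0, step, 2*step, ...`.
#' @examples
#' cs <- c(chrT = 2e6)
#' pk <- genomic_intervals("chrT", 1000, 1200)
#' compute_density(pk, cs, step = 250e3, flank = 500e3)
#' @export
compute_density <- function(peaks, chrom_sizes, step = 250000, flank = 500000) {
  stopifnot(step > 0, flank > 0)
  validate_intervals(peaks, "peak")
  unknown <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("peaks on chromosome absent from chrom.sizes: ", unknown[1L],
         call. = FALSE)
  out <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_length(chrom_sizes, chr)
    centers <- seq(0, by = step, length.out = floor(L / step) + 1)
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    mids <- sort(floor((p$start + p$end) / 2))
    ## midpoints in [c - flank, c + flank): cumulative counts at window edges
    n_le <- function(x) findInterval(x, mids)
    counts <- n_le(centers + flank - 1) - n_le(centers - flank - 1)
    data.frame(chrom = chr, bin = seq_along(centers), center = centers,
               count = as.numeric(counts), stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, out)
  attr(prof, "step") <- step
  attr(prof, "flank") <- flank
  class(prof) <- c("density_profile", "data.frame")
  prof
}

## Tricube-weighted local polynomial fit of y on an equally spaced grid,
## evaluated at every grid point from its q nearest neighbours.
local_poly_fit <- function(y, q, degree = 2L) {
  n <- length(y)
  x <- seq_len(n)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - i)
    idx <- order(d, x)[seq_len(q)]
    dmax <- max(d[idx])
    w <- if (dmax == 0) rep(1, q) else (1 - (d[idx] / dmax)^3)^3
    xs <- x[idx] - i
    X <- outer(xs, 0:degree, `^`)
    sw <- sqrt(w)
    beta <- qr.coef(qr(X * sw), y[idx] * sw)
    beta[is.na(beta)] <- 0
    fit[i] <- beta[1L]
  }
  fit
}

#' Smooth a density profile by local polynomial regression
#'
#' Per-bin tricube-weighted least-squares fit of a degree-2 polynomial on
#' the `ceiling(span * n)` nearest bins (classic loess weights, no
#' robustness iterations), evaluated at every bin of every chromosome.
#' Constant and linear profiles are reproduced exactly.
#'
#' @param profile a `density_profile` from [compute_density()].
#' @param span fraction of the chromosome's bins used per local fit, in
#'   (0, 1]. The default uses the bins spanning 2 Mb of genome
#'   (`span = min(1, 2e6 / (step * n))`), floored so at least 4 bins enter
#'   each fit; it must resolve modules a few Mb long while averaging over
#'   bin-level peak noise.
#' @param degree polynomial degree (default 2).
#' @return The profile with an added `smoothed` column.
#' @export
smooth_profile <- function(profile, span = NULL, degree = 2L) {
  stopifnot(inherits(profile, "density_profile"))
  step <- attr(profile, "step")
  if (!is.null(span) && (span <= 0 || span > 1))
    stop("span must be in (0, 1]", call. = FALSE)
  profile$smoothed <- NA_real_
  for (chr in unique(profile$chrom)) {
    sel <- profile$chrom == chr
    y <- profile$count[sel]
    n <- length(y)
    if (n < 10L)
      stop("chromosome ", chr, " has ", n,
           " bins (< 10); increase chromosome size or decrease step",
           call. = FALSE)
    sp <- if (is.null(span)) min(1, max(4 / n, 2e6 / (step * n))) else span
    q <- min(n, ceiling(sp * n))
    if (q < degree + 2L)
      stop("span ", signif(sp, 3), " gives only ", q, " bins per fit on ",
           chr, "; use a larger span or step", call. = FALSE)
    profile$smoothed[sel] <- local_poly_fit(y, q, degree)
  }
  attr(profile, "span") <- span
  profile
}

## Extrema of one smoothed vector under the plateau rule: a run of equal
## values is a summit (valley) when strictly above (below) both flanking
## runs; the extremum is placed at the run's middle bin, lower index on even
## ties. Runs touching either chromosome end are never extrema.
find_extrema_vector <- function(s) {
  r <- rle(s)
  k <- length(r$values)
  valleys <- integer(0)
  summits <- integer(0)
  if (k >= 3L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in 2:(k - 1L)) {
      mid <- as.integer(floor((starts[j] + ends[j]) / 2))
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        summits <- c(summits, mid)
      else if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
        valleys <- c(valleys, mid)
    }
  }
  list(valleys = valleys, summits = summits)
}

#' Locate valleys and summits of a smoothed profile
#'
#' Valleys (local minima of the smoothed curve) mark candidate module
#' boundaries; summits are local maxima. Plateaus collapse to their middle
#' bin (lower index when the plateau length is even); the first and last
#' bin of a chromosome are never extrema; an all-equal profile has none.
#'
#' With `prominence > 0`, shallow valleys are dropped: a valley is kept
#' only when its depth below the lower of its two flanking maxima (taken
#' between the neighbouring valleys, or the chromosome ends) is at least
#' `prominence` times the chromosome's median smoothed density. Module
#' boundaries are deep depletions of peak density, so a depth criterion
#' separates them from the shallow local minima any noisy profile has in
#' flat stretches.
#'
#' @param profile a smoothed `density_profile` (see [smooth_profile()]).
#' @param prominence minimum valley depth as a fraction of the
#'   chromosome's median smoothed density; 0 (default) keeps every strict
#'   local minimum.
#' @return `data.frame` with columns `chrom`, `bin` (1-based index),
#'   `center` (bp), `type` (`"valley"` or `"summit"`).
#' @export
find_extrema <- function(profile, prominence = 0) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.null(profile$smoothed))
    stop("profile has no smoothed values; run smooth_profile() first",
         call. = FALSE)
  step <- attr(profile, "step")
  out <- lapply(unique(profile$chrom), function(chr) {
    s <- profile$smoothed[profile$chrom == chr]
    ex <- find_extrema_vector(s)
    if (prominence > 0 && length(ex$valleys)) {
      thr <- prominence * stats::median(s)
      v <- ex$valleys
      keep <- vapply(seq_along(v), function(k) {
        lo <- if (k > 1L) v[k - 1L] else 1L
        hi <- if (k < length(v)) v[k + 1L] else length(s)
        depth <- min(max(s[lo:v[k]]), max(s[v[k]:hi])) - s[v[k]]
        depth >= thr
      }, logical(1L))
      ex$valleys <- v[keep]
    }
    bins <- c(ex$valleys, ex$summits)
    if (!length(bins))
      return(data.frame(chrom = character(), bin = integer(),
                        center = numeric(), type = character()))
    data.frame(chrom = chr, bin = bins, center = (bins - 1) * step,
               type = rep(c("valley", "summit"),
                          c(length(ex$valleys), length(ex$summits))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$bin), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "step") <- step
  res
}
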