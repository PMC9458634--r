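## Enrichment tests: hypergeometric upper tail for upregulated genes among
## foreground-only intra-module pairs, and the pooled two-sample proportion
## test for variant density in boundary sets.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= m)` for the number of successes in a sample of size `n` drawn
#' without replacement from a population of `N` items of which `M` are
#' successes. Exact tail sum, evaluated in log space for large `N` via
#' [stats::phyper()].
#'
#' @param N population size (e.g. all genes in the comparison).
#' @param M population successes (e.g. upregulated genes).
#' @param n sample size (e.g. genes in foreground-only intra-module
#'   pairs).
#' @param m sample successes.
#' @return The p-value `P(X >= m)`.
#' @examples
#' hypergeom_upper_tail(N = 10, M = 5, n = 4, m = 4)  # 5/210
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(M, n))
    stop("invalid hypergeometric specification: need 0 <= m <= min(M, n), ",
         "M <= N, n <= N", call. = FALSE)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Pooled two-sample proportion test
#'
#' Tests equality of two proportions `x1/n1` and `x2/n2` with the pooled
#' variance z statistic
#' `z = (x1/n1 - x2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))`,
#' `phat = (x1 + x2)/(n1 + n2)`, and no continuity correction. The
#' intended regime is counts in the thousands and up (variants over
#' boundary base pairs); for small samples the uncorrected normal
#' approximation is anticonservative.
#'
#' @param x1,x2 success counts (e.g. variants in each boundary set).
#' @param n1,n2 totals (e.g. boundary lengths in bp); must be positive.
#' @param sides 1 or 2 (default two-sided).
#' @return `list(z, p_value, p1, p2, pooled)`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, sides = 2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be > 0", call. = FALSE)
  if (x1 < 0 || x2 < 0) stop("counts must be >= 0", call. = FALSE)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    stop("degenerate pooled proportion (0 or 1)", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  z <- (p1 - p2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  p <- if (sides == 2) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  list(z = z, p_value = min(p, 1), p1 = p1, p2 = p2, pooled = phat)
}

#' Variant coverage of boundary sets
#'
#' Fraction of the genome covered by a boundary set and fraction of
#' variants falling inside it; optionally builds the two-sample proportion
#' comparison against a second boundary set (variant count over boundary
#' length, the enrichment contrast used for somatic SNVs/indels in module
#' boundaries versus TAD boundaries).
#'
#' @param variants `data.frame` with columns `chrom`, `pos`.
#' @param boundaries sorted non-overlapping boundary intervals.
#' @param genome_length total genome length in bp (explicit, never
#'   hard-coded).
#' @param boundaries2 optional second boundary set for the comparison.
#' @return `list(genome_fraction, variant_fraction, n_variants,
#'   boundary_bp)`; with `boundaries2`, also `spec` (the x1/n1/x2/n2
#'   inputs) and `test` (the [two_proportion_test()] result).
#' @export
variant_boundary_coverage <- function(variants, boundaries, genome_length,
                                      boundaries2 = NULL) {
  validate_intervals(boundaries, "boundary")
  boundaries <- sort_intervals(boundaries)
  if (intervals_overlap_within(boundaries))
    stop("overlapping boundaries", call. = FALSE)
  if (nrow(variants) == 0L)
    stop("empty variant set: fractions undefined", call. = FALSE)
  bp1 <- sum(boundaries$end - boundaries$start)
  in1 <- points_in_intervals(variants$chrom, variants$pos, boundaries)
  out <- list(genome_fraction = bp1 / genome_length,
              variant_fraction = mean(in1),
              n_variants = nrow(variants), boundary_bp = bp1)
  if (!is.null(boundaries2)) {
    validate_intervals(boundaries2, "boundary")
    boundaries2 <- sort_intervals(boundaries2)
    if (intervals_overlap_within(boundaries2))
      stop("overlapping boundaries", call. = FALSE)
    bp2 <- sum(boundaries2$end - boundaries2$start)
    in2 <- points_in_intervals(variants$chrom, variants$pos, boundaries2)
    spec <- list(x1 = sum(in1), n1 = bp1, x2 = sum(in2), n2 = bp2)
    out$spec <- spec
    out$test <- two_proportion_test(spec$x1, spec$n1, spec$x2, spec$n2)
  }
  out
}
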