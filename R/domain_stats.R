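## Interval-level statistics over domain sets: intra-domain fractions,
## boundary overlap/recall, density contrast and compartment composition.

## index of the containing domain for each point, 0 when none
domain_index_of_points <- function(chrom, pos, domains) {
  domains <- sort_intervals(domains)
  key <- paste0(domains$chrom, ":", domains$start)
  idx_out <- integer(length(pos))
  for (chr in unique(domains$chrom)) {
    sel <- chrom == chr
    if (!any(sel)) next
    d <- domains[domains$chrom == chr, , drop = FALSE]
    i <- findInterval(pos[sel], d$start)
    ok <- i > 0L
    ok[ok] <- pos[sel][ok] < d$end[i[ok]]
    res <- integer(sum(sel))
    res[ok] <- match(paste0(chr, ":", d$start[i[ok]]), key)
    idx_out[sel] <- res
  }
  idx_out
}

#' Classify anchor pairs as intra- or inter-domain
#'
#' A pair is intra-domain when both anchor midpoints fall inside one and
#' the same domain interval. Pairs with anchors on different chromosomes,
#' or with either midpoint in a boundary/gap between domains, are
#' inter-domain.
#'
#' @param pairs anchor-pair `data.frame` (see [read_pairs()]).
#' @param domains sorted non-overlapping domain intervals.
#' @return `list` of class `intra_report`: `n_total`, `n_intra`, `n_inter`,
#'   `fraction_intra` (`NA` when `n_total == 0`) and a per-pair `label`
#'   vector (`"intra"`/`"inter"`).
#' @export
classify_pairs <- function(pairs, domains) {
  validate_intervals(domains, "domain")
  domains <- sort_intervals(domains)
  if (intervals_overlap_within(domains))
    stop("domains overlap", call. = FALSE)
  n <- nrow(pairs)
  if (n == 0L) {
    out <- list(n_total = 0L, n_intra = 0L, n_inter = 0L,
                fraction_intra = NA_real_, label = character(0),
                empty = TRUE)
    class(out) <- "intra_report"
    return(out)
  }
  mid1 <- floor((pairs$start1 + pairs$end1) / 2)
  mid2 <- floor((pairs$start2 + pairs$end2) / 2)
  i1 <- domain_index_of_points(pairs$chrom1, mid1, domains)
  i2 <- domain_index_of_points(pairs$chrom2, mid2, domains)
  intra <- pairs$chrom1 == pairs$chrom2 & i1 > 0L & i1 == i2
  out <- list(n_total = n, n_intra = sum(intra), n_inter = sum(!intra),
              fraction_intra = mean(intra),
              label = ifelse(intra, "intra", "inter"), empty = FALSE)
  class(out) <- "intra_report"
  out
}

#' @export
print.intra_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("intra-domain report: no items\n")
  } else {
    cat(sprintf("intra-domain report: %d/%d intra (%.1f%%)\n",
                x$n_intra, x$n_total, 100 * x$fraction_intra))
    if (!is.null(x$cutoff))
      cat(sprintf("  size filter: < %s bp (%d of %d items dropped)\n",
                  format(x$cutoff, big.mark = ","), x$n_dropped,
                  x$n_total + x$n_dropped))
  }
  invisible(x)
}

#' Compare pair classification between two domain sets
#'
#' Partitions pairs into intra in both sets, intra only in the foreground,
#' intra only in the background, and inter in both. The foreground-only
#' count is the sampling input to the hypergeometric enrichment of
#' upregulated genes ([hypergeom_upper_tail()]).
#'
#' @param pairs anchor pairs.
#' @param domains_fg,domains_bg foreground and background domain sets.
#' @return `list` with the four counts (`intra_both`, `intra_fg_only`,
#'   `intra_bg_only`, `inter_both`), `n_total`, and the per-pair `label`.
#' @export
pair_set_comparison <- function(pairs, domains_fg, domains_bg) {
  fg <- classify_pairs(pairs, domains_fg)
  bg <- classify_pairs(pairs, domains_bg)
  lab <- character(nrow(pairs))
  f <- fg$label == "intra"; b <- bg$label == "intra"
  lab[f & b] <- "intra_both"
  lab[f & !b] <- "intra_fg_only"
  lab[!f & b] <- "intra_bg_only"
  lab[!f & !b] <- "inter_both"
  list(n_total = nrow(pairs),
       intra_both = sum(f & b), intra_fg_only = sum(f & !b),
       intra_bg_only = sum(!f & b), inter_both = sum(!f & !b),
       label = lab)
}

#' Intra-domain fraction of an interval set
#'
#' An interval is intra-domain when it is fully contained
#' (`[start, end) ⊆ domain`) in a single domain. With
#' `size_filter = "median"` the cutoff is the median domain length and
#' intervals at least that long are dropped before classification — the
#' rule used for ecDNAs, where only elements smaller than the median cRAM
#' are informative about module containment.
#'
#' @param intervals interval `data.frame`.
#' @param domains non-empty sorted non-overlapping domain set.
#' @param size_filter `"median"`, `"none"`, or an explicit cutoff in bp.
#' @return `intra_report` with additional `cutoff` and `n_dropped` fields.
#' @export
interval_intra_fraction <- function(intervals, domains,
                                    size_filter = c("median", "none")) {
  validate_intervals(domains, "domain")
  if (nrow(domains) == 0L) stop("empty domain set", call. = FALSE)
  domains <- sort_intervals(domains)
  if (intervals_overlap_within(domains)) stop("domains overlap", call. = FALSE)
  cutoff <- if (is.numeric(size_filter)) {
    size_filter
  } else {
    switch(match.arg(size_filter),
           median = stats::median(domains$end - domains$start),
           none = Inf)
  }
  len <- intervals$end - intervals$start
  keep <- len < cutoff
  kept <- intervals[keep, , drop = FALSE]
  n <- nrow(kept)
  if (n) {
    ## contained iff the domain holding the start also holds end - 1
    i1 <- domain_index_of_points(kept$chrom, kept$start, domains)
    i2 <- domain_index_of_points(kept$chrom, kept$end - 1, domains)
    intra <- i1 > 0L & i1 == i2
  } else intra <- logical(0)
  out <- list(n_total = n, n_intra = sum(intra), n_inter = sum(!intra),
              fraction_intra = if (n) mean(intra) else NA_real_,
              label = ifelse(intra, "intra", "inter"),
              cutoff = cutoff, n_dropped = sum(!keep), empty = n == 0L)
  class(out) <- "intra_report"
  out
}

#' Reciprocal overlap fractions of two interval sets
#'
#' Overlap criterion is at least 1 bp of intersection; both directions are
#' reported (e.g. fraction of consensus boundaries overlapping LADs, and
#' fraction of LADs overlapping consensus boundaries).
#'
#' @param boundaries,track interval `data.frame`s.
#' @return `list(fraction_boundaries_in_track, fraction_track_in_boundaries,
#'   n_boundaries, n_track)`.
#' @export
boundary_track_overlap <- function(boundaries, track) {
  validate_intervals(boundaries, "boundary")
  validate_intervals(track, "track")
  fb <- if (nrow(boundaries)) mean(intervals_overlap_any(boundaries, track)) else 0
  ft <- if (nrow(track)) mean(intervals_overlap_any(track, boundaries)) else 0
  list(fraction_boundaries_in_track = fb,
       fraction_track_in_boundaries = ft,
       n_boundaries = nrow(boundaries), n_track = nrow(track))
}

#' Boundary recall between two calls
#'
#' A reference boundary is recalled when some query boundary center lies
#' within `tolerance` of its center. Boundary positions are only defined
#' to grid resolution, so the natural tolerance is one step.
#'
#' @param reference,query boundary interval `data.frame`s.
#' @param tolerance maximum center-to-center distance in bp (default
#'   250 kb, one step at the default grid).
#' @return `list(n_reference, n_matched, recall)`.
#' @export
boundary_recall <- function(reference, query, tolerance = 250000) {
  validate_intervals(reference, "reference boundary")
  validate_intervals(query, "query boundary")
  if (nrow(reference) == 0L)
    stop("empty reference boundary set: recall undefined", call. = FALSE)
  matched <- logical(nrow(reference))
  rc <- (reference$start + reference$end) / 2
  qc <- (query$start + query$end) / 2
  for (chr in unique(reference$chrom)) {
    sel <- reference$chrom == chr
    q <- sort(qc[query$chrom == chr])
    if (!length(q)) next
    r <- rc[sel]
    i <- findInterval(r, q)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(q))
    dmin <- pmin(abs(r - q[lo]), abs(r - q[hi]))
    matched[sel] <- dmin <= tolerance
  }
  list(n_reference = nrow(reference), n_matched = sum(matched),
       recall = mean(matched), matched = matched)
}

#' Rank-sum density contrast at boundaries
#'
#' Per-sample two-sided Wilcoxon rank-sum test comparing density values at
#' boundary bins against all other bins. Midrank tie handling with the
#' continuity-corrected normal approximation when both groups have at
#' least 10 values (or ties are present); exact enumeration otherwise.
#'
#' @param profiles a `density_profile` or list of them (one per sample).
#' @param boundaries consensus boundary intervals on the same grid.
#' @param value which profile column to compare (`"count"` or
#'   `"smoothed"`).
#' @return `data.frame` with one row per sample: `sample`, `n_boundary`,
#'   `n_other`, `statistic` (rank-sum W), `p_value`, and the median of
#'   each group.
#' @export
density_contrast <- function(profiles, boundaries, value = c("count", "smoothed")) {
  value <- match.arg(value)
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  validate_intervals(boundaries, "boundary")
  out <- lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    v <- p[[value]]
    if (is.null(v)) stop("profile lacks column ", value, call. = FALSE)
    inb <- points_in_intervals(p$chrom, p$center, boundaries)
    x <- v[inb]; y <- v[!inb]
    if (!length(x) || !length(y))
      stop("a comparison group is empty", call. = FALSE)
    wt <- rank_sum_test(x, y)
    data.frame(sample = if (!is.null(names(profiles))) names(profiles)[k] else k,
               n_boundary = length(x), n_other = length(y),
               statistic = wt$statistic, p_value = wt$p_value,
               median_boundary = stats::median(x),
               median_other = stats::median(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] fixing this package's
#' convention: exact enumeration when either group has fewer than 10
#' values and there are no ties; continuity-corrected normal approximation
#' with midranks otherwise.
#'
#' @param x,y numeric vectors.
#' @return `list(statistic, p_value)`.
#' @export
rank_sum_test <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) < 10L || length(y) < 10L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' A/B compartment composition of domains
#'
#' For each domain, the fraction of A- and B-labeled compartment bins whose
#' centers fall inside it. Unlabeled (NA) bins are excluded from the
#' fractions and counted separately; domains with no labeled bin are
#' flagged and get `NA` fractions.
#'
#' @param domains sorted non-overlapping domain intervals.
#' @param bin_labels `data.frame` with columns `chrom`, `start` (bin start
#'   on the compartment grid) and `label` (`"A"`, `"B"` or `NA`).
#' @param resolution compartment bin size in bp (default 250 kb).
#' @return `data.frame`: one row per domain with `n_A`, `n_B`,
#'   `n_unlabeled`, `frac_A`, `frac_B`.
#' @export
compartment_composition <- function(domains, bin_labels, resolution = 250000) {
  validate_intervals(domains, "domain")
  domains <- sort_intervals(domains)
  centers <- bin_labels$start + resolution / 2
  idx <- domain_index_of_points(bin_labels$chrom, centers, domains)
  nd <- nrow(domains)
  nA <- nB <- nU <- integer(nd)
  for (d in seq_len(nd)) {
    lab <- bin_labels$label[idx == d]
    nA[d] <- sum(lab == "A", na.rm = TRUE)
    nB[d] <- sum(lab == "B", na.rm = TRUE)
    nU[d] <- sum(is.na(lab))
  }
  tot <- nA + nB
  data.frame(chrom = domains$chrom, start = domains$start, end = domains$end,
             n_A = nA, n_B = nB, n_unlabeled = nU,
             frac_A = ifelse(tot > 0, nA / tot, NA_real_),
             frac_B = ifelse(tot > 0, nB / tot, NA_real_),
             stringsAsFactors = FALSE)
}
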