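## Cohort consensus: occurrence of boundary calls on a shared grid, the
## >= 25% consensus rule, merging of nearby boundary regions and absorption
## of sub-threshold inter-boundary islands.

#' Per-bin boundary occurrence across a cohort
#'
#' For each grid bin, the fraction of samples whose boundary set covers the
#' bin center. All boundary sets must come from calls at the same step.
#'
#' @param boundary_sets list of per-sample boundary tables
#'   (`chrom`/`start`/`end` `data.frame`s, or `ram_fit` objects).
#' @param step grid step in bp.
#' @param chrom_sizes named chromosome lengths.
#' @return An `occurrence_grid`: `data.frame` with columns `chrom`, `bin`,
#'   `center`, `frac`; attributes `step` and `n_samples`.
#' @export
boundary_occurrence <- function(boundary_sets, step, chrom_sizes) {
  stopifnot(length(boundary_sets) >= 1L, step > 0)
  sets <- lapply(boundary_sets, function(b) {
    if (inherits(b, "ram_fit")) {
      if (!isTRUE(all.equal(b$step, step)))
        stop("boundary set called at step ", b$step,
             ", expected ", step, call. = FALSE)
      b <- b$boundaries
    }
    bstep <- attr(b, "step")
    if (!is.null(bstep) && !isTRUE(all.equal(bstep, step)))
      stop("boundary set called at step ", bstep, ", expected ", step,
           call. = FALSE)
    validate_intervals(b, "boundary")
    b
  })
  n <- length(sets)
  out <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_length(chrom_sizes, chr)
    centers <- seq(0, by = step, length.out = floor(L / step) + 1)
    hits <- numeric(length(centers))
    for (b in sets) {
      cov <- points_in_intervals(rep(chr, length(centers)), centers, b)
      hits <- hits + cov
    }
    data.frame(chrom = chr, bin = seq_along(centers), center = centers,
               frac = hits / n, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  attr(grid, "step") <- step
  attr(grid, "n_samples") <- n
  class(grid) <- c("occurrence_grid", "data.frame")
  grid
}

## Group consecutive consensus bin indices into regions, merge regions with
## gaps < merge_dist (single linkage), absorb islands <= min_domain.
consensus_regions_chrom <- function(bins, centers, step, L, frac,
                                    merge_dist, min_domain) {
  if (!length(bins))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      occurrence = numeric()))
  grp <- cumsum(c(1L, diff(bins) > 1L))
  starts <- ends <- occ <- numeric(max(grp))
  for (g in seq_len(max(grp))) {
    bb <- bins[grp == g]
    starts[g] <- max(0, centers[bb[1L]] - step / 2)
    ends[g] <- min(L, centers[bb[length(bb)]] + step / 2)
    occ[g] <- max(frac[bb])
  }
  ## single-linkage merge of regions closer than merge_dist
  i <- 1L
  ms <- numeric(0); me <- numeric(0); mo <- numeric(0)
  cs <- starts[1L]; ce <- ends[1L]; co <- occ[1L]
  if (length(starts) > 1L) for (j in 2:length(starts)) {
    if (starts[j] - ce < merge_dist) {
      ce <- ends[j]; co <- max(co, occ[j])
    } else {
      ms <- c(ms, cs); me <- c(me, ce); mo <- c(mo, co)
      cs <- starts[j]; ce <- ends[j]; co <- occ[j]
    }
  }
  ms <- c(ms, cs); me <- c(me, ce); mo <- c(mo, co)
  ## absorb inter-boundary islands <= min_domain (merge across); also
  ## absorb short chromosome-end segments into the flanking boundary
  k <- length(ms)
  keep_s <- ms[1L]; keep_e <- me[1L]; keep_o <- mo[1L]
  fs <- numeric(0); fe <- numeric(0); fo <- numeric(0)
  if (k > 1L) for (j in 2:k) {
    if (ms[j] - keep_e <= min_domain) {
      keep_e <- me[j]; keep_o <- max(keep_o, mo[j])
    } else {
      fs <- c(fs, keep_s); fe <- c(fe, keep_e); fo <- c(fo, keep_o)
      keep_s <- ms[j]; keep_e <- me[j]; keep_o <- mo[j]
    }
  }
  fs <- c(fs, keep_s); fe <- c(fe, keep_e); fo <- c(fo, keep_o)
  if (fs[1L] > 0 && fs[1L] <= min_domain) fs[1L] <- 0
  nlast <- length(fe)
  if (fe[nlast] < L && L - fe[nlast] <= min_domain) fe[nlast] <- L
  data.frame(start = fs, end = fe, occurrence = fo)
}

#' Call consensus boundaries and cRAMs from an occurrence grid
#'
#' Three-step rule: (1) bins whose occurrence fraction is `>= threshold`
#' are consensus bins; (2) runs of consensus bins become boundary regions,
#' and regions `< merge_dist` apart are merged (single linkage, so chained
#' merges are allowed); (3) inter-boundary intervals of length
#' `<= min_domain` are absorbed into the flanking boundaries; the remaining
#' intervals are the consensus modules (cRAMs). Boundaries and cRAMs tile
#' each chromosome.
#'
#' @param grid an `occurrence_grid` from [boundary_occurrence()].
#' @param chrom_sizes named chromosome lengths.
#' @param threshold consensus occurrence threshold, inclusive (default
#'   0.25: a region is consensus when flagged in at least a quarter of the
#'   cohort).
#' @param merge_dist merge boundary regions closer than this (default
#'   250 kb).
#' @param min_domain minimum cRAM size in bp; smaller islands are absorbed
#'   (default 250 kb).
#' @return `list(boundaries, domains)`: consensus boundary regions (with a
#'   peak `occurrence` fraction per region) and the cRAM intervals.
#' @export
call_consensus <- function(grid, chrom_sizes, threshold = 0.25,
                           merge_dist = 250000, min_domain = 250000) {
  stopifnot(inherits(grid, "occurrence_grid"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  step <- attr(grid, "step")
  bl <- list(); dl <- list()
  for (chr in unique(grid$chrom)) {
    g <- grid[grid$chrom == chr, , drop = FALSE]
    L <- chrom_length(chrom_sizes, chr)
    bins <- which(g$frac >= threshold)
    reg <- consensus_regions_chrom(bins, g$center, step, L, g$frac,
                                   merge_dist, min_domain)
    b <- if (nrow(reg))
      data.frame(chrom = chr, start = reg$start, end = reg$end,
                 occurrence = reg$occurrence, stringsAsFactors = FALSE)
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    occurrence = numeric())
    bl[[chr]] <- b
    dl[[chr]] <- complement_intervals(b, chr, L)
  }
  boundaries <- do.call(rbind, bl)
  domains <- do.call(rbind, dl)
  rownames(boundaries) <- rownames(domains) <- NULL
  attr(boundaries, "step") <- step
  list(boundaries = boundaries, domains = domains)
}

#' Consensus-RAM (cRAM) calling across a cohort
#'
#' Aggregates per-sample RAM boundary calls into cohort consensus modules:
#' boundary occurrence on the shared grid ([boundary_occurrence()])
#' followed by the consensus rule ([call_consensus()]).
#'
#' @param fits list of `ram_fit` objects or boundary tables, one per
#'   sample.
#' @param chrom_sizes named chromosome lengths.
#' @param step grid step in bp (must match the per-sample calls).
#' @param threshold,merge_dist,min_domain see [call_consensus()].
#' @param cohort optional cohort label (e.g. `"normal"` or `"cancer"`).
#' @return An object of class `cram_fit` with components `grid`,
#'   `boundaries`, `domains`, the parameters and `n_samples`.
#' @export
consensus_ram <- function(fits, chrom_sizes, step = 250000, threshold = 0.25,
                          merge_dist = 250000, min_domain = 250000,
                          cohort = NULL) {
  grid <- boundary_occurrence(fits, step, chrom_sizes)
  cons <- call_consensus(grid, chrom_sizes, threshold, merge_dist, min_domain)
  structure(list(grid = grid, boundaries = cons$boundaries,
                 domains = cons$domains, chrom_sizes = chrom_sizes,
                 step = step, threshold = threshold, merge_dist = merge_dist,
                 min_domain = min_domain, cohort = cohort,
                 n_samples = attr(grid, "n_samples")),
            class = "cram_fit")
}

#' @export
print.cram_fit <- function(x, ...) {
  cat("Consensus RAM (cRAM) segmentation",
      if (!is.null(x$cohort)) paste0("[", x$cohort, "]"), "\n")
  cat(sprintf("  %d samples; step %s bp; threshold %.0f%%\n", x$n_samples,
              format(x$step, big.mark = ","), 100 * x$threshold))
  cat(sprintf("  %d consensus boundaries (median %s bp), %d cRAMs (median %s bp)\n",
              nrow(x$boundaries),
              format(stats::median(x$boundaries$end - x$boundaries$start),
                     big.mark = ","),
              nrow(x$domains),
              format(stats::median(x$domains$end - x$domains$start),
                     big.mark = ",")))
  invisible(x)
}

#' @export
summary.cram_fit <- function(object, ...) {
  bs <- object$boundaries$end - object$boundaries$start
  ds <- object$domains$end - object$domains$start
  out <- list(cohort = object$cohort, n_samples = object$n_samples,
              threshold = object$threshold,
              n_boundaries = nrow(object$boundaries),
              n_domains = nrow(object$domains),
              boundary_size = summary(bs), domain_size = summary(ds))
  class(out) <- "summary.cram_fit"
  out
}

#' @export
print.summary.cram_fit <- function(x, ...) {
  cat("cRAM summary", if (!is.null(x$cohort)) paste0("[", x$cohort, "]"), "\n")
  cat(sprintf("  %d samples, threshold %.0f%%\n", x$n_samples,
              100 * x$threshold))
  cat(sprintf("  %d boundaries / %d cRAMs\n", x$n_boundaries, x$n_domains))
  cat("  boundary sizes (bp):\n"); print(x$boundary_size)
  cat("  cRAM sizes (bp):\n"); print(x$domain_size)
  invisible(x)
}

#' Plot cohort boundary occurrence and consensus calls
#'
#' @param x a `cram_fit`.
#' @param chrom chromosome to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cram_fit <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) chrom <- x$grid$chrom[1L]
  g <- x$grid[x$grid$chrom == chrom, , drop = FALSE]
  graphics::plot(g$center / 1e6, g$frac, type = "h", col = "grey40",
                 ylim = c(0, 1), xlab = paste(chrom, "(Mb)"),
                 ylab = "boundary occurrence", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "firebrick")
  b <- x$boundaries[x$boundaries$chrom == chrom, , drop = FALSE]
  if (nrow(b))
    graphics::rect(b$start / 1e6, 0, b$end / 1e6, 1,
                   col = grDevices::adjustcolor("steelblue", 0.25),
                   border = NA)
  invisible(x)
}
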