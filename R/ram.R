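## The per-sample RAM caller: boundary regions at density valleys and the
## module segmentation between them, plus the `ram()` fitting front end.

#' Segment chromosomes into RAMs at density valleys
#'
#' Each valley bin becomes one boundary region `[center - step/2,
#' center + step/2)` clipped to the chromosome; the RAMs (regulation
#' associated modules) are the maximal inter-boundary intervals, including
#' the segments from the chromosome start to the first boundary and from
#' the last boundary to the chromosome end. Boundaries and RAMs tile each
#' chromosome exactly.
#'
#' @param extrema extrema table from [find_extrema()].
#' @param profile the smoothed `density_profile` the extrema came from.
#' @param chrom_sizes named chromosome lengths.
#' @return `list(boundaries, domains)`, both sorted non-overlapping
#'   interval `data.frame`s covering every chromosome of the profile.
#' @export
call_rams <- function(extrema, profile, chrom_sizes) {
  step <- attr(profile, "step")
  bl <- list(); dl <- list()
  for (chr in unique(profile$chrom)) {
    L <- chrom_length(chrom_sizes, chr)
    v <- extrema[extrema$chrom == chr & extrema$type == "valley", , drop = FALSE]
    if (nrow(v)) {
      b <- data.frame(chrom = chr,
                      start = pmax(0, v$center - step / 2),
                      end = pmin(L, v$center + step / 2),
                      stringsAsFactors = FALSE)
      b <- sort_intervals(b)
    } else {
      b <- data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    bl[[chr]] <- b
    dl[[chr]] <- complement_intervals(b, chr, L)
  }
  boundaries <- do.call(rbind, bl)
  domains <- do.call(rbind, dl)
  rownames(boundaries) <- rownames(domains) <- NULL
  attr(boundaries, "step") <- step
  list(boundaries = boundaries, domains = domains)
}

#' Call regulation-associated modules (RAMs) for one sample
#'
#' The full per-sample pipeline: sliding-window peak-density profile
#' ([compute_density()]), tricube local polynomial smoothing
#' ([smooth_profile()]), valley/summit detection ([find_extrema()]) and
#' segmentation into boundary regions and modules ([call_rams()]).
#'
#' @param peaks peak `data.frame` (from [read_peaks()] or
#'   [simulate_peaks()]).
#' @param chrom_sizes named chromosome lengths.
#' @param step grid step in bp; 250 kb is the scale at which modules are
#'   most conserved across samples.
#' @param flank window half-width in bp (default 500 kb).
#' @param span smoothing span; `NULL` for the 2-Mb default
#'   (see [smooth_profile()]).
#' @param prominence minimum valley depth, as a fraction of the
#'   chromosome's median smoothed density, for a valley to be called a
#'   boundary (see [find_extrema()]). The default 0.4 sits between the
#'   depth of true boundary depletions (several-fold density contrast)
#'   and the shallow minima produced by counting noise.
#' @param sample_id optional sample label.
#' @return An object of class `ram_fit` with components `profile`
#'   (density with smoothed values), `extrema`, `boundaries`, `domains`,
#'   `chrom_sizes` and the call parameters. Methods: `print`, `summary`,
#'   `plot`, `fitted` (smoothed density), `residuals` (raw - smoothed).
#' @examples
#' cfg <- sim_config(seed = 7, chrom_sizes = c(chrS = 4e7), n_samples = 1)
#' truth <- simulate_layout(cfg)
#' pk <- simulate_peaks(truth, cfg)[[1]]
#' fit <- ram(pk, cfg$chrom_sizes)
#' fit
#' @export
ram <- function(peaks, chrom_sizes, step = 250000, flank = 500000,
                span = NULL, prominence = 0.4,
                sample_id = attr(peaks, "sample_id")) {
  profile <- compute_density(peaks, chrom_sizes, step, flank)
  profile <- smooth_profile(profile, span)
  extrema <- find_extrema(profile, prominence = prominence)
  seg <- call_rams(extrema, profile, chrom_sizes)
  structure(list(profile = profile, extrema = extrema,
                 boundaries = seg$boundaries, domains = seg$domains,
                 chrom_sizes = chrom_sizes, step = step, flank = flank,
                 span = span, prominence = prominence, sample_id = sample_id,
                 n_peaks = nrow(peaks)),
            class = "ram_fit")
}

#' @export
print.ram_fit <- function(x, ...) {
  cat("RAM segmentation",
      if (!is.null(x$sample_id)) paste0("for sample '", x$sample_id, "'"),
      "\n")
  cat(sprintf("  %d peaks on %d chromosome(s); step %s bp, flank %s bp\n",
              x$n_peaks, length(unique(x$profile$chrom)),
              format(x$step, big.mark = ",", scientific = FALSE),
              format(x$flank, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  %d boundaries, %d modules (median size %s bp)\n",
              nrow(x$boundaries), nrow(x$domains),
              format(stats::median(x$domains$end - x$domains$start),
                     big.mark = ",")))
  invisible(x)
}

#' @export
summary.ram_fit <- function(object, ...) {
  sizes <- object$domains$end - object$domains$start
  per_chrom <- table(object$boundaries$chrom)
  out <- list(sample_id = object$sample_id, step = object$step,
              flank = object$flank, n_peaks = object$n_peaks,
              n_boundaries = nrow(object$boundaries),
              n_domains = nrow(object$domains),
              domain_size = summary(sizes),
              boundaries_per_chrom = per_chrom)
  class(out) <- "summary.ram_fit"
  out
}

#' @export
print.summary.ram_fit <- function(x, ...) {
  cat("RAM segmentation summary\n")
  cat(sprintf("  step %s bp, flank %s bp, %d peaks\n",
              format(x$step, big.mark = ",", scientific = FALSE),
              format(x$flank, big.mark = ",", scientific = FALSE),
              x$n_peaks))
  cat(sprintf("  %d boundaries / %d modules\n", x$n_boundaries, x$n_domains))
  cat("  module sizes (bp):\n")
  print(x$domain_size)
  invisible(x)
}

#' @export
fitted.ram_fit <- function(object, ...) object$profile$smoothed

#' @export
residuals.ram_fit <- function(object, ...)
  object$profile$count - object$profile$smoothed

#' Plot a RAM density profile and its boundaries
#'
#' Raw density (points), smoothed curve (line) and boundary regions
#' (shaded) for one chromosome.
#'
#' @param x a `ram_fit`.
#' @param chrom chromosome to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ram_fit <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) chrom <- x$profile$chrom[1L]
  p <- x$profile[x$profile$chrom == chrom, , drop = FALSE]
  graphics::plot(p$center / 1e6, p$count, pch = 16, cex = 0.4,
                 col = "grey50", xlab = paste(chrom, "(Mb)"),
                 ylab = "peak density", ...)
  graphics::lines(p$center / 1e6, p$smoothed, col = "firebrick", lwd = 2)
  b <- x$boundaries[x$boundaries$chrom == chrom, , drop = FALSE]
  if (nrow(b))
    graphics::rect(b$start / 1e6, graphics::par("usr")[3L], b$end / 1e6,
                   graphics::par("usr")[4L],
                   col = grDevices::adjustcolor("steelblue", 0.25),
                   border = NA)
  invisible(x)
}
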