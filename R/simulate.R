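## Synthetic cohort generator with a known modular ground truth: alternating
## module/boundary layouts, per-sample peak sets, anchor pairs, ecDNA-like
## intervals, point variants and Hi-C contact lists.

#' Simulation configuration
#'
#' Defaults describe a realistic cohort at the method's operating scale:
#' modules with a lognormal length distribution (median 3 Mb, none below
#' 1.5 Mb), peak-poor boundary gaps (median 750 kb), 10 samples sharing
#' 80% of their boundaries, and a 10-fold peak-rate contrast between
#' modules (2 peaks / 100 kb) and boundaries (0.2 peaks / 100 kb).
#'
#' @param seed integer RNG seed; fixed seed gives identical outputs.
#' @param chrom_sizes named chromosome lengths (default three chromosomes
#'   of 100/80/60 Mb, enough for ~50 cohort-shared boundaries).
#' @param n_samples cohort size.
#' @param module_median,module_sdlog,module_min module length distribution
#'   (lognormal, bp; draws below `module_min` are rejected).
#' @param gap_median,gap_sdlog,gap_min boundary gap length distribution.
#' @param shared_boundary_fraction fraction of layout boundaries shared by
#'   the whole cohort; the rest are re-drawn per sample.
#' @param peak_rate_module,peak_rate_boundary Poisson peak-midpoint rates
#'   (peaks per bp) inside modules and boundaries.
#' @param peak_len_meanlog,peak_len_sdlog peak length distribution
#'   (lognormal, bp).
#' @param intra_prob probability that a simulated anchor pair (or ecDNA)
#'   lies inside a single module rather than straddling a boundary.
#' @param ecdna_meanlog,ecdna_sdlog ecDNA length distribution.
#' @param variant_enrichment variant density multiplier inside boundaries
#'   (`e >= 1`; `e = 1` is the uniform null).
#' @param contact_mu,contact_boundary_multiplier flat expected contact
#'   count per record and observed-count inflation at boundary bins.
#' @param step analysis grid step in bp.
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chrS1 = 100e6, chrS2 = 80e6, chrS3 = 60e6),
                       n_samples = 10L,
                       module_median = 3e6, module_sdlog = 0.45,
                       module_min = 1.5e6,
                       gap_median = 750e3, gap_sdlog = 0.35, gap_min = 300e3,
                       shared_boundary_fraction = 0.8,
                       peak_rate_module = 2e-5, peak_rate_boundary = 2e-6,
                       peak_len_meanlog = log(600), peak_len_sdlog = 0.4,
                       intra_prob = 0.9,
                       ecdna_meanlog = log(1e6), ecdna_sdlog = 0.6,
                       variant_enrichment = 2,
                       contact_mu = 10, contact_boundary_multiplier = 3,
                       step = 250000) {
  cfg <- list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
              n_samples = as.integer(n_samples),
              module_median = module_median, module_sdlog = module_sdlog,
              module_min = module_min, gap_median = gap_median,
              gap_sdlog = gap_sdlog, gap_min = gap_min,
              shared_boundary_fraction = shared_boundary_fraction,
              peak_rate_module = peak_rate_module,
              peak_rate_boundary = peak_rate_boundary,
              peak_len_meanlog = peak_len_meanlog,
              peak_len_sdlog = peak_len_sdlog,
              intra_prob = intra_prob,
              ecdna_meanlog = ecdna_meanlog, ecdna_sdlog = ecdna_sdlog,
              variant_enrichment = variant_enrichment,
              contact_mu = contact_mu,
              contact_boundary_multiplier = contact_boundary_multiplier,
              step = step)
  stopifnot(all(chrom_sizes > 0), cfg$n_samples >= 1L,
            module_median < min(chrom_sizes),
            cfg$peak_rate_module >= 0, cfg$peak_rate_boundary >= 0,
            shared_boundary_fraction >= 0, shared_boundary_fraction <= 1,
            variant_enrichment >= 1)
  if (intra_prob < 0 || intra_prob > 1)
    stop("intra_prob must be in [0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

## run expr with a locally seeded RNG, restoring the caller's state
with_sim_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

rlnorm_min <- function(n, median, sdlog, minv) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
    out <- c(out, draw[draw >= minv])
  }
  out[seq_len(n)]
}

#' Simulate the modular ground-truth layout
#'
#' Alternating module/boundary segments are drawn from the configured
#' length distributions until each chromosome is tiled. A fraction
#' `shared_boundary_fraction` of boundaries is marked cohort-shared; for
#' each sample the remaining slots are replaced by private boundaries at
#' random module-interior positions, so every sample's own truth still
#' tiles the chromosome and contains every shared boundary.
#'
#' @param config a [sim_config()].
#' @return `list` of class `sim_truth`: `boundaries` (cohort layout, with
#'   logical `shared` column), `modules`, and `samples` — a list of
#'   per-sample `list(boundaries, modules)`.
#' @export
simulate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    bl <- list()
    for (chr in names(config$chrom_sizes)) {
      L <- config$chrom_sizes[[chr]]
      pos <- 0
      ## leading module so chromosomes start inside a module
      segs_s <- numeric(0); segs_e <- numeric(0)
      repeat {
        pos <- pos + rlnorm_min(1L, config$module_median, config$module_sdlog,
                                config$module_min)
        if (pos >= L) break
        g <- rlnorm_min(1L, config$gap_median, config$gap_sdlog,
                        config$gap_min)
        if (pos + g >= L) break
        segs_s <- c(segs_s, floor(pos)); segs_e <- c(segs_e, floor(pos + g))
        pos <- pos + g
      }
      if (length(segs_s))
        bl[[chr]] <- data.frame(chrom = chr, start = segs_s, end = segs_e,
                                stringsAsFactors = FALSE)
    }
    boundaries <- do.call(rbind, bl)
    rownames(boundaries) <- NULL
    nb <- nrow(boundaries)
    n_shared <- round(config$shared_boundary_fraction * nb)
    shared_idx <- sort(sample.int(nb, n_shared))
    boundaries$shared <- seq_len(nb) %in% shared_idx
    modules <- do.call(rbind, lapply(names(config$chrom_sizes), function(chr)
      complement_intervals(boundaries, chr, config$chrom_sizes[[chr]])))
    rownames(modules) <- NULL
    samples <- lapply(seq_len(config$n_samples), function(s) {
      b <- boundaries[boundaries$shared, c("chrom", "start", "end")]
      n_priv <- nb - n_shared
      if (n_priv > 0L) {
        priv <- list()
        for (k in seq_len(n_priv)) {
          repeat {
            chr <- sample(names(config$chrom_sizes), 1L,
                          prob = config$chrom_sizes / sum(config$chrom_sizes))
            L <- config$chrom_sizes[[chr]]
            w <- rlnorm_min(1L, config$gap_median, config$gap_sdlog,
                            config$gap_min)
            c0 <- stats::runif(1L, w / 2, L - w / 2)
            cand <- data.frame(chrom = chr, start = floor(c0 - w / 2),
                               end = floor(c0 + w / 2),
                               stringsAsFactors = FALSE)
            ## keep private boundaries well clear of existing ones
            near <- rbind(b, do.call(rbind, c(priv, list(cand[0, ]))))
            pad <- data.frame(chrom = near$chrom,
                              start = pmax(0, near$start - 5e5),
                              end = near$end + 5e5)
            if (!any(intervals_overlap_any(cand, pad))) break
          }
          priv[[k]] <- cand
        }
        b <- rbind(b, do.call(rbind, priv))
      }
      b <- sort_intervals(b)
      rownames(b) <- NULL
      mods <- do.call(rbind, lapply(names(config$chrom_sizes), function(chr)
        complement_intervals(b, chr, config$chrom_sizes[[chr]])))
      rownames(mods) <- NULL
      list(boundaries = b, modules = mods)
    })
    names(samples) <- sprintf("sample_%02d", seq_len(config$n_samples))
    structure(list(boundaries = boundaries, modules = modules,
                   samples = samples, config = config),
              class = "sim_truth")
  })
}

## sample point positions from a piecewise-constant rate over segments
sample_segment_points <- function(segments, rate_per_bp) {
  lens <- segments$end - segments$start
  n <- stats::rpois(length(lens), lens * rate_per_bp)
  idx <- rep(seq_along(lens), n)
  if (!length(idx))
    return(data.frame(chrom = character(), pos = numeric()))
  pos <- floor(segments$start[idx] + stats::runif(length(idx)) * lens[idx])
  data.frame(chrom = segments$chrom[idx], pos = pos, stringsAsFactors = FALSE)
}

#' Simulate per-sample peak sets
#'
#' Peak midpoints follow a piecewise-homogeneous Poisson process with rate
#' `peak_rate_module` inside each sample's modules and
#' `peak_rate_boundary` inside its boundaries; peak intervals are centered
#' on the midpoints with lognormal lengths, clipped to the chromosome.
#'
#' @param truth a `sim_truth` from [simulate_layout()].
#' @param config the same [sim_config()].
#' @return Named list of sorted peak `data.frame`s, one per sample.
#' @export
simulate_peaks <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  lapply(stats::setNames(seq_along(truth$samples), names(truth$samples)),
         function(s) {
    with_sim_seed(config$seed + 10000L + s, {
      st <- truth$samples[[s]]
      mids <- rbind(sample_segment_points(st$modules, config$peak_rate_module),
                    sample_segment_points(st$boundaries,
                                          config$peak_rate_boundary))
      if (!nrow(mids)) {
        pk <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
      } else {
        len <- pmax(100, round(stats::rlnorm(nrow(mids),
                                             config$peak_len_meanlog,
                                             config$peak_len_sdlog)))
        half <- floor(len / 2)
        start <- mids$pos - half
        end <- start + len
        Ls <- config$chrom_sizes[mids$chrom]
        start <- pmax(0, start)
        end <- pmin(Ls, end)
        keep <- end > start
        pk <- data.frame(chrom = mids$chrom[keep], start = start[keep],
                         end = end[keep], stringsAsFactors = FALSE)
        pk <- sort_intervals(pk)
      }
      rownames(pk) <- NULL
      attr(pk, "sample_id") <- names(truth$samples)[s]
      pk
    })
  })
}

## pick module rows with probability proportional to length
pick_modules <- function(modules, n) {
  lens <- modules$end - modules$start
  sample.int(nrow(modules), n, replace = TRUE, prob = lens)
}

#' Simulate anchor pairs with known intra-module fraction
#'
#' With probability `intra_prob` both anchors of a pair fall inside one
#' cohort-layout module; otherwise the two anchors are placed in the
#' modules flanking a random boundary (straddling it).
#'
#' @param truth,config see [simulate_peaks()].
#' @param n_pairs number of pairs.
#' @param anchor_width anchor width in bp.
#' @return BEDPE-like `data.frame` with `gene`, `expr_fg`, `expr_bg`
#'   annotation columns and a logical `intra_truth` column.
#' @export
simulate_pairs <- function(truth, config, n_pairs = 500L, anchor_width = 2000L) {
  stopifnot(inherits(truth, "sim_truth"))
  with_sim_seed(config$seed + 20000L, {
    mods <- truth$modules
    bnds <- truth$boundaries
    intra <- stats::runif(n_pairs) < config$intra_prob
    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      if (intra[i] || nrow(bnds) == 0L) {
        m <- mods[pick_modules(mods, 1L), ]
        lo <- m$start; hi <- m$end - anchor_width
        if (hi <= lo) hi <- lo + 1
        a1 <- floor(stats::runif(1L, lo, hi))
        a2 <- floor(stats::runif(1L, lo, hi))
        chr1 <- chr2 <- m$chrom
      } else {
        b <- bnds[sample.int(nrow(bnds), 1L), ]
        left <- mods[mods$chrom == b$chrom & mods$end <= b$start, ]
        right <- mods[mods$chrom == b$chrom & mods$start >= b$end, ]
        if (!nrow(left) || !nrow(right)) { # boundary at a chromosome end
          m <- mods[pick_modules(mods, 1L), ]
          a1 <- floor(stats::runif(1L, m$start, max(m$start + 1, m$end - anchor_width)))
          a2 <- a1
          chr1 <- chr2 <- m$chrom
          intra[i] <- TRUE
        } else {
          ml <- left[nrow(left), ]; mr <- right[1L, ]
          a1 <- floor(stats::runif(1L, ml$start, max(ml$start + 1, ml$end - anchor_width)))
          a2 <- floor(stats::runif(1L, mr$start, max(mr$start + 1, mr$end - anchor_width)))
          chr1 <- ml$chrom; chr2 <- mr$chrom
        }
      }
      rows[[i]] <- data.frame(chrom1 = chr1, start1 = a1,
                              end1 = a1 + anchor_width,
                              chrom2 = chr2, start2 = a2,
                              end2 = a2 + anchor_width,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$gene <- sprintf("gene_%04d", seq_len(n_pairs))
    out$expr_fg <- round(stats::rlnorm(n_pairs, log(50), 1), 2)
    out$expr_bg <- round(stats::rlnorm(n_pairs, log(50), 1), 2)
    out$intra_truth <- intra
    out
  })
}

#' Simulate ecDNA-like intervals
#'
#' With probability `intra_prob` an interval is placed fully inside a
#' module (length capped at the module's size); otherwise it is centered
#' on a random boundary, spanning it.
#'
#' @param truth,config see [simulate_peaks()].
#' @param n number of intervals.
#' @return Interval `data.frame` with logical `intra_truth` column.
#' @export
simulate_ecdnas <- function(truth, config, n = 200L) {
  stopifnot(inherits(truth, "sim_truth"))
  with_sim_seed(config$seed + 30000L, {
    mods <- truth$modules
    bnds <- truth$boundaries
    intra <- stats::runif(n) < config$intra_prob
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- round(stats::rlnorm(1L, config$ecdna_meanlog, config$ecdna_sdlog))
      if (intra[i] || nrow(bnds) == 0L) {
        m <- mods[pick_modules(mods, 1L), ]
        len <- min(len, m$end - m$start - 2)
        s <- floor(stats::runif(1L, m$start, m$end - len))
        rows[[i]] <- data.frame(chrom = m$chrom, start = s, end = s + len,
                                stringsAsFactors = FALSE)
      } else {
        b <- bnds[sample.int(nrow(bnds), 1L), ]
        ctr <- (b$start + b$end) / 2
        len <- max(len, (b$end - b$start) + 2e4) # make sure it spans
        s <- max(0, floor(ctr - len / 2))
        e <- min(config$chrom_sizes[[b$chrom]], s + len)
        rows[[i]] <- data.frame(chrom = b$chrom, start = s, end = e,
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$intra_truth <- intra
    out
  })
}

#' Simulate point variants with boundary enrichment
#'
#' Variant positions follow a piecewise-uniform density: baseline inside
#' modules, `variant_enrichment` times the baseline inside cohort-layout
#' boundaries. With enrichment 1 the variants are uniform over the genome
#' (the null used for type-I calibration).
#'
#' @param truth,config see [simulate_peaks()].
#' @param n number of variants.
#' @param enrichment overrides `config$variant_enrichment` when given.
#' @param seed_offset extra seed offset, for independent replicate cohorts.
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
simulate_variants <- function(truth, config, n = 10000L, enrichment = NULL,
                              seed_offset = 0L) {
  stopifnot(inherits(truth, "sim_truth"))
  e <- if (is.null(enrichment)) config$variant_enrichment else enrichment
  with_sim_seed(config$seed + 40000L + seed_offset, {
    segs <- rbind(cbind(truth$modules[c("chrom", "start", "end")], w = 1),
                  cbind(truth$boundaries[c("chrom", "start", "end")], w = e))
    lens <- (segs$end - segs$start) * segs$w
    idx <- sample.int(nrow(segs), n, replace = TRUE, prob = lens)
    pos <- floor(segs$start[idx] +
                 stats::runif(n) * (segs$end[idx] - segs$start[idx]))
    out <- data.frame(chrom = segs$chrom[idx], pos = pos,
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos), , drop = FALSE]
  })
}

#' Simulate a Hi-C contact list
#'
#' Random intra-chromosomal bin pairs at the analysis resolution with a
#' flat expected count; observed counts are Poisson, inflated by
#' `contact_boundary_multiplier` when either endpoint bin center lies in a
#' cohort-layout boundary (boundary loci are densely contacting).
#'
#' @param truth,config see [simulate_peaks()].
#' @param n_records number of contact records.
#' @param resolution bin size in bp (defaults to `config$step`).
#' @return Contact `data.frame` (`chrom`, `bin_i`, `bin_j`, `observed`,
#'   `expected`).
#' @export
simulate_contacts <- function(truth, config, n_records = 5000L,
                              resolution = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  res <- if (is.null(resolution)) config$step else resolution
  with_sim_seed(config$seed + 50000L, {
    chroms <- names(config$chrom_sizes)
    chr <- sample(chroms, n_records, replace = TRUE,
                  prob = config$chrom_sizes / sum(config$chrom_sizes))
    nbin <- floor(config$chrom_sizes[chr] / res)
    i <- floor(stats::runif(n_records) * nbin) * res
    j <- floor(stats::runif(n_records) * nbin) * res
    bin_i <- pmin(i, j); bin_j <- pmax(i, j)
    inb <- points_in_intervals(chr, bin_i + res / 2, truth$boundaries) |
      points_in_intervals(chr, bin_j + res / 2, truth$boundaries)
    mu <- config$contact_mu *
      ifelse(inb, config$contact_boundary_multiplier, 1)
    data.frame(chrom = chr, bin_i = bin_i, bin_j = bin_j,
               observed = stats::rpois(n_records, mu),
               expected = rep(config$contact_mu, n_records),
               stringsAsFactors = FALSE)
  })
}
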