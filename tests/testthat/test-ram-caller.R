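make_profile <- function(values, step = 250e3, chrom = "chrT") {
  prof <- data.frame(chrom = chrom, bin = seq_along(values),
                     center = (seq_along(values) - 1) * step,
                     count = as.numeric(values))
  attr(prof, "step") <- step
  attr(prof, "flank") <- 500e3
  class(prof) <- c("density_profile", "data.frame")
  prof
}

test_that("density counts peak midpoints in truncated sliding windows", {
  cs <- c(chrT = 2e6)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  d0 <- compute_density(empty, cs, step = 250e3, flank = 500e3)
  expect_equal(nrow(d0), 9L)
  expect_true(all(d0$count == 0))

  one <- genomic_intervals("chrT", 1000, 1200) # midpoint 1100
  d1 <- compute_density(one, cs, step = 250e3, flank = 500e3)
  expect_equal(d1$count, c(1, 1, 1, 0, 0, 0, 0, 0, 0))

  expect_error(compute_density(genomic_intervals("chrX", 0, 10), cs),
               "absent from chrom.sizes")
})

test_that("density matches the brute-force window-membership oracle", {
  cs <- c(chrA = 12e6, chrB = 7e6)
  withr::local_seed(11)
  ## midpoints on a 50-kb lattice plus fully random peaks
  lat <- (0:239) * 50e3 + 25e3
  pk1 <- data.frame(chrom = "chrA", start = lat[1:40] - 100,
                    end = lat[1:40] + 100)
  s <- sort(floor(runif(960, 0, 11.9e6)))
  pk2 <- data.frame(chrom = sample(c("chrA", "chrB"), 960, TRUE),
                    start = s, end = s + sample(100:2000, 960, TRUE))
  peaks <- sort_iv(rbind(pk1, pk2))
  for (st in c(100e3, 250e3)) {
    prof <- compute_density(peaks, cs, step = st, flank = 500e3)
    for (chr in names(cs)) {
      got <- prof$count[prof$chrom == chr]
      exp <- oracle_density(peaks[peaks$chrom == chr, ],
                            prof$center[prof$chrom == chr], 500e3)
      expect_equal(got, exp)
    }
  }
})

test_that("local polynomial smoothing reproduces constants and lines exactly", {
  prof <- make_profile(rep(7, 40))
  sm <- smooth_profile(prof, span = 0.3)
  expect_equal(sm$smoothed, rep(7, 40), tolerance = 1e-10)

  lin <- make_profile(2 + 0.5 * (0:39))
  sm <- smooth_profile(lin, span = 0.25)
  expect_equal(sm$smoothed, lin$count, tolerance = 1e-8)
})

test_that("smoothing matches an independent weighted-least-squares oracle", {
  withr::local_seed(4)
  y <- 10 + 5 * sin((1:60) / 6) + rnorm(60)
  prof <- make_profile(y)
  for (span in c(0.15, 0.3)) {
    sm <- smooth_profile(prof, span = span)
    q <- ceiling(span * 60)
    expect_equal(sm$smoothed, oracle_local_fit(y, q, 2L), tolerance = 1e-6)
  }
})

test_that("smoothing rejects degenerate inputs", {
  expect_error(smooth_profile(make_profile(rep(1, 9))), "< 10")
  expect_error(smooth_profile(make_profile(rep(1, 40)), span = 0), "span")
  expect_error(smooth_profile(make_profile(rep(1, 40)), span = 1.2), "span")
  expect_error(smooth_profile(make_profile(rep(1, 40)), span = 0.01),
               "larger span")
})

test_that("extrema detection follows the strict rise/fall and plateau rules", {
  ## bins are 1-based here; a valley at the k-th bin has center (k-1)*step
  vall <- function(v) {
    prof <- make_profile(seq_along(v))
    prof$smoothed <- v
    ex <- find_extrema(prof)
    ex$bin[ex$type == "valley"]
  }
  expect_length(vall(1:12), 0L)           # monotone
  expect_length(vall(rep(2, 12)), 0L)     # all equal
  expect_equal(vall(c(9:1, 2:9, 9, 9)), 9L)
  expect_equal(vall(c(3, 2, 1, 2, 3, rep(4, 7))), 3L)
  ## plateau valleys collapse to the middle bin, lower index on even length
  expect_equal(vall(c(3, 1, 1, 1, 3, rep(4, 7))), 3L)
  expect_equal(vall(c(3, 1, 1, 3, rep(4, 8))), 2L)
  ## endpoint runs are never extrema
  expect_length(vall(c(1, 2, 3, rep(4, 9))), 0L)
  sm <- c(0, 5, 4, 6, 2, 7, rep(7, 6))
  prof <- make_profile(seq_along(sm)); prof$smoothed <- sm
  ex <- find_extrema(prof)
  expect_false(any(ex$bin %in% c(1L, length(sm))))
  ## valleys and summits strictly alternate
  typ <- ex$type[order(ex$bin)]
  expect_true(all(typ[-1] != typ[-length(typ)]))
})

test_that("extrema agree with pracma::findpeaks on plateau-free profiles", {
  skip_if_not_installed("pracma")
  withr::local_seed(8)
  y <- cumsum(rnorm(80))
  y <- y + seq_along(y) * 1e-6 # break any exact ties
  prof <- make_profile(seq_along(y)); prof$smoothed <- y
  ex <- find_extrema(prof)
  fp <- pracma::findpeaks(-y)
  ref <- sort(fp[, 2])
  ref <- ref[ref > 1 & ref < length(y)]
  expect_equal(sort(ex$bin[ex$type == "valley"]), ref)
})

test_that("prominence filtering drops shallow valleys only", {
  base <- rep(10, 30)
  base[10] <- 9.5   # shallow dip
  base[20] <- 2     # deep boundary-like dip
  prof <- make_profile(seq_along(base)); prof$smoothed <- base
  all_v <- find_extrema(prof)
  expect_setequal(all_v$bin[all_v$type == "valley"], c(10L, 20L))
  filt <- find_extrema(prof, prominence = 0.4)
  expect_equal(filt$bin[filt$type == "valley"], 20L)
})

test_that("RAM segmentation tiles the chromosome around valley boundaries", {
  cs <- c(chrT = 10e6)
  prof <- make_profile(rep(1, 41))
  prof$smoothed <- rep(1, 41)
  ## no valleys: one RAM covering everything
  seg0 <- call_rams(find_extrema(prof), prof, cs)
  expect_equal(nrow(seg0$boundaries), 0L)
  expect_equal(seg0$domains$start, 0)
  expect_equal(seg0$domains$end, 10e6)

  ## valleys at 2.5 Mb and 5.0 Mb (bins 11 and 21 on the 250-kb grid)
  ex <- data.frame(chrom = "chrT", bin = c(11L, 21L),
                   center = c(2.5e6, 5e6), type = "valley")
  seg <- call_rams(ex, prof, cs)
  expect_equal(seg$boundaries$start, c(2.375e6, 4.875e6))
  expect_equal(seg$boundaries$end, c(2.625e6, 5.125e6))
  expect_equal(seg$domains$start, c(0, 2.625e6, 5.125e6))
  expect_equal(seg$domains$end, c(2.375e6, 4.875e6, 10e6))
  expect_tiling(seg$boundaries, seg$domains, "chrT", 10e6)
})

test_that("the fitted ram object is deterministic and tiles every chromosome", {
  cfg <- sim_config(seed = 5, chrom_sizes = c(chrA = 4e7, chrB = 3e7),
                    n_samples = 1)
  truth <- simulate_layout(cfg)
  pk <- simulate_peaks(truth, cfg)[[1]]
  f1 <- ram(pk, cfg$chrom_sizes)
  f2 <- ram(pk, cfg$chrom_sizes)
  expect_identical(f1$boundaries, f2$boundaries)
  for (chr in names(cfg$chrom_sizes))
    expect_tiling(f1$boundaries, f1$domains, chr, cfg$chrom_sizes[[chr]])
  expect_s3_class(f1, "ram_fit")
  expect_equal(fitted(f1) + residuals(f1), f1$profile$count)
  expect_output(print(f1), "RAM segmentation")
  expect_output(print(summary(f1)), "module sizes")
})

test_that("module count does not grow with coarser steps on clean profiles", {
  cfg <- sim_config(seed = 9)
  truth <- simulate_layout(cfg)
  mods <- truth$modules
  pk <- do.call(rbind, lapply(seq_len(nrow(mods)), function(i) {
    m <- mods[i, ]
    mid <- seq(m$start + 25e3, m$end - 25e3, by = 50e3)
    data.frame(chrom = m$chrom, start = mid - 500, end = mid + 500)
  }))
  pk <- sort_iv(pk)
  n_rams <- vapply(c(100e3, 250e3, 500e3), function(st)
    nrow(ram(pk, cfg$chrom_sizes, step = st)$domains), numeric(1))
  expect_true(all(diff(n_rams) <= 0))
})
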