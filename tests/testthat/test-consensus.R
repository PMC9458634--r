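bset <- function(chrom, centers, step = 250e3) {
  b <- data.frame(chrom = chrom, start = centers - step / 2,
                  end = centers + step / 2)
  b$start <- pmax(0, b$start)
  attr(b, "step") <- step
  b
}

test_that("occurrence fractions are exact per-sample counts over the grid", {
  cs <- c(chrT = 5e6)
  sets <- list(bset("chrT", 1e6), bset("chrT", 1e6), bset("chrT", 2e6),
               bset("chrT", 3e6))
  g <- boundary_occurrence(sets, 250e3, cs)
  expect_equal(attr(g, "n_samples"), 4L)
  expect_equal(g$frac[g$center == 1e6], 0.5)
  expect_equal(g$frac[g$center == 2e6], 0.25)
  expect_equal(g$frac[g$center == 4e6], 0)
  expect_true(all(g$frac >= 0 & g$frac <= 1))
})

test_that("occurrence grid matches brute-force per-bin recounting", {
  cs <- c(chrA = 2e7)
  withr::local_seed(21)
  sets <- lapply(1:20, function(i) {
    centers <- sort(sample(seq(0, 2e7, by = 250e3), sample(3:12, 1)))
    bset("chrA", centers)
  })
  g <- boundary_occurrence(sets, 250e3, cs)
  for (b in seq_len(nrow(g))) {
    cc <- g$center[b]
    manual <- sum(vapply(sets, function(s)
      any(cc >= s$start & cc < s$end), logical(1)))
    expect_equal(g$frac[b], manual / 20)
  }
})

test_that("mixed step sizes are rejected", {
  cs <- c(chrT = 5e6)
  s1 <- bset("chrT", 1e6, step = 250e3)
  s2 <- bset("chrT", 1e6, step = 100e3)
  expect_error(boundary_occurrence(list(s1, s2), 250e3, cs), "step")
})

occ_grid <- function(frac, step = 250e3, chrom = "chrT") {
  g <- data.frame(chrom = chrom, bin = seq_along(frac),
                  center = (seq_along(frac) - 1) * step, frac = frac)
  attr(g, "step") <- step
  attr(g, "n_samples") <- 20L
  class(g) <- c("occurrence_grid", "data.frame")
  g
}

test_that("consensus threshold is inclusive and rules merge and absorb", {
  L <- 10e6
  cs <- c(chrT = L)
  ## exactly 25% occurrence is consensus
  f <- rep(0, 41); f[11] <- 0.25
  cons <- call_consensus(occ_grid(f), cs)
  expect_equal(nrow(cons$boundaries), 1L)
  f[11] <- 0.2499
  expect_equal(nrow(call_consensus(occ_grid(f), cs)$boundaries), 0L)

  ## gap of 250 kb between single-bin regions: not merged by distance
  ## (gap not < 250 kb) but absorbed as an island <= 250 kb
  f <- rep(0, 41); f[c(11, 13)] <- 1
  cons <- call_consensus(occ_grid(f), cs)
  expect_equal(nrow(cons$boundaries), 1L)
  expect_equal(cons$boundaries$start, 2.375e6)
  expect_equal(cons$boundaries$end, 3.125e6)

  ## well-separated regions stay apart, islands > 250 kb survive as cRAMs
  f <- rep(0, 41); f[c(11, 16)] <- 1
  cons <- call_consensus(occ_grid(f), cs)
  expect_equal(nrow(cons$boundaries), 2L)
  mid <- cons$domains[cons$domains$start > 0 & cons$domains$end < L, ]
  expect_equal(mid$end - mid$start, 1e6)

  expect_error(call_consensus(occ_grid(f), cs, threshold = 0), "threshold")
  expect_error(call_consensus(occ_grid(f), cs, threshold = 1.5), "threshold")
})

test_that("consensus output matches exhaustive rule enumeration on small grids", {
  withr::local_seed(33)
  step <- 250e3
  for (rep in 1:40) {
    nb <- sample(10:50, 1)
    L <- (nb - 1) * step + sample.int(step, 1)
    f <- sample(c(0, 0.1, 0.2, 0.25, 0.3, 0.6, 1), nb, replace = TRUE,
                prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05))
    cons <- call_consensus(occ_grid(f), c(chrT = L))
    oracle <- oracle_consensus(f, step, L)
    expect_equal(cons$boundaries$start, unname(oracle$boundaries[, "start"]))
    expect_equal(cons$boundaries$end, unname(oracle$boundaries[, "end"]))
    expect_equal(cons$domains$start, unname(oracle$domains[, "start"]))
    expect_equal(cons$domains$end, unname(oracle$domains[, "end"]))
    expect_tiling(cons$boundaries, cons$domains, "chrT", L)
  }
})

test_that("raising the threshold never increases consensus bins", {
  withr::local_seed(5)
  f <- round(runif(60), 2)
  g <- occ_grid(f)
  n_bins <- vapply(c(0.1, 0.25, 0.5, 0.75, 1),
                   function(t) sum(f >= t), numeric(1))
  expect_true(all(diff(n_bins) <= 0))
  n_reg <- vapply(c(0.1, 0.25, 0.5, 0.75),
                  function(t) sum(f >= t), numeric(1))
  expect_true(all(diff(n_reg) <= 0))
})

test_that("consensus is idempotent under re-rasterization", {
  withr::local_seed(13)
  step <- 250e3
  f <- rep(0, 80)
  f[c(10, 11, 25, 40, 41, 42, 70)] <- c(0.3, 0.5, 1, 0.25, 0.25, 0.3, 0.9)
  L <- 79 * step + 1e5
  cs <- c(chrT = L)
  cons1 <- call_consensus(occ_grid(f), cs)
  b <- cons1$boundaries
  attr(b, "step") <- step
  g2 <- boundary_occurrence(list(b), step, cs)
  cons2 <- call_consensus(g2, cs)
  expect_equal(cons2$boundaries$start, cons1$boundaries$start)
  expect_equal(cons2$boundaries$end, cons1$boundaries$end)
})

test_that("the cram_fit front end reports cohort consensus", {
  cfg <- sim_config(seed = 2, chrom_sizes = c(chrA = 5e7), n_samples = 6)
  truth <- simulate_layout(cfg)
  fits <- lapply(simulate_peaks(truth, cfg), ram, chrom_sizes = cfg$chrom_sizes)
  cons <- consensus_ram(fits, cfg$chrom_sizes, cohort = "test")
  expect_s3_class(cons, "cram_fit")
  expect_equal(cons$n_samples, 6L)
  expect_tiling(cons$boundaries, cons$domains, "chrA", 5e7)
  expect_output(print(cons), "cRAM")
  expect_output(print(summary(cons)), "boundary sizes")
  expect_error(consensus_ram(fits, cfg$chrom_sizes, step = 100e3), "step")
})
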