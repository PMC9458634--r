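doms <- function(starts, ends, chrom = "chrT")
  data.frame(chrom = chrom, start = starts, end = ends)

pair <- function(s1, s2, chrom1 = "chrT", chrom2 = chrom1, w = 1000)
  data.frame(chrom1 = chrom1, start1 = s1, end1 = s1 + w,
             chrom2 = chrom2, start2 = s2, end2 = s2 + w)

test_that("pair classification uses midpoints and a single shared domain", {
  d <- doms(c(0, 4e6), c(3e6, 8e6))
  expect_equal(classify_pairs(pair(1e6, 2e6), d)$label, "intra")
  expect_equal(classify_pairs(pair(1e6, 5e6), d)$label, "inter")
  expect_equal(classify_pairs(pair(1e6, 3.5e6), d)$label, "inter") # gap
  expect_equal(classify_pairs(pair(1e6, 1e6, chrom2 = "chrU"), d)$label,
               "inter")
  r <- classify_pairs(pair(1, 2)[0, ], d)
  expect_true(r$empty)
  expect_true(is.na(r$fraction_intra))
})

test_that("pair classification matches the quadratic containment oracle", {
  withr::local_seed(41)
  lat <- seq(0, 45e6, by = 5e6)
  d <- rbind(
    data.frame(chrom = "chrA", start = lat + 5e5,
               end = lat + 5e5 + floor(runif(10, 1e6, 4e6))),
    data.frame(chrom = "chrB", start = lat + 5e5,
               end = lat + 5e5 + floor(runif(10, 1e6, 4e6))))
  p <- data.frame(chrom1 = sample(c("chrA", "chrB"), 200, TRUE),
                  start1 = floor(runif(200, 0, 5e7 - 1e4)))
  p$end1 <- p$start1 + 2000
  p$chrom2 <- ifelse(runif(200) < 0.9, p$chrom1,
                     sample(c("chrA", "chrB"), 200, TRUE))
  p$start2 <- floor(runif(200, 0, 5e7 - 1e4))
  p$end2 <- p$start2 + 2000
  got <- classify_pairs(p, d)
  exp_intra <- oracle_pair_fraction(p, d)
  expect_equal(got$label == "intra", exp_intra)
  expect_equal(got$fraction_intra, mean(exp_intra))
  expect_equal(got$n_intra + got$n_inter, got$n_total)
})

test_that("two-set pair comparison composes two classifications", {
  fg <- doms(0, 8e6)
  bg <- doms(c(0, 4e6), c(3e6, 8e6))
  p <- rbind(pair(1e6, 2e6),   # intra both
             pair(1e6, 5e6),   # intra fg only
             pair(3.2e6, 3.4e6)) # inter both (bg gap)
  cmp <- pair_set_comparison(p, fg, bg)
  expect_equal(cmp$intra_both, 1L)
  expect_equal(cmp$intra_fg_only, 2L)
  expect_equal(cmp$intra_bg_only, 0L)
  expect_equal(cmp$intra_both + cmp$intra_fg_only + cmp$intra_bg_only +
               cmp$inter_both, cmp$n_total)
  same <- pair_set_comparison(p, bg, bg)
  expect_equal(same$intra_fg_only, 0L)
  expect_equal(same$intra_bg_only, 0L)
})

test_that("interval containment applies the median size filter", {
  d <- doms(c(0, 2e6, 5e6, 9e6, 14e6), c(1e6, 4e6, 8e6, 13e6, 19e6))
  ## domain lengths 1,2,3,4,5 Mb -> median cutoff 3 Mb
  iv <- data.frame(chrom = "chrT",
                   start = c(5e6, 9e6, 0),
                   end = c(8.5e6, 11.5e6, 1e6))
  r <- interval_intra_fraction(iv, d, size_filter = "median")
  expect_equal(r$cutoff, 3e6)
  expect_equal(r$n_dropped, 1L)  # the 3.5-Mb interval
  ## 3.5-Mb one dropped; [9,12.5) inside [9,13); [0,1e6) equals a domain
  expect_equal(r$n_intra, 2L)
  expect_equal(r$fraction_intra, 1.0)
  expect_error(interval_intra_fraction(iv, d[0, ]), "empty domain set")
})

test_that("interval containment matches the quadratic oracle", {
  withr::local_seed(52)
  d <- doms(seq(0, 45e6, by = 5e6) + 1e6, seq(0, 45e6, by = 5e6) + 4.5e6)
  iv <- random_intervals(500, "chrT", 48e6, 4e6)
  r <- interval_intra_fraction(iv, d, size_filter = "none")
  expect_equal(r$label == "intra", oracle_interval_intra(iv, d))
})

test_that("boundary/track overlap is reciprocal and 1-bp sensitive", {
  b <- doms(1e6, 2e6)
  tr <- doms(1.9e6, 3e6)
  ov <- boundary_track_overlap(b, tr)
  expect_equal(ov$fraction_boundaries_in_track, 1)
  expect_equal(ov$fraction_track_in_boundaries, 1)
  ## adjacency (zero overlap) does not count
  ov2 <- boundary_track_overlap(b, doms(2e6, 3e6))
  expect_equal(ov2$fraction_boundaries_in_track, 0)
  ## symmetric under swapping with outputs swapped
  withr::local_seed(7)
  x <- random_intervals(50, c("chrA", "chrB"), 3e7)
  y <- random_intervals(80, c("chrA", "chrB"), 3e7)
  oxy <- boundary_track_overlap(x, y)
  oyx <- boundary_track_overlap(y, x)
  expect_equal(oxy$fraction_boundaries_in_track,
               oyx$fraction_track_in_boundaries)
  ## brute-force fraction
  manual <- mean(vapply(seq_len(nrow(x)), function(i)
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i]),
    logical(1)))
  expect_equal(oxy$fraction_boundaries_in_track, manual)
})

test_that("boundary recall counts center matches within tolerance", {
  ref <- doms(c(1e6, 5e6, 9e6), c(1.25e6, 5.25e6, 9.25e6))
  expect_equal(boundary_recall(ref, ref)$recall, 1)
  expect_equal(boundary_recall(ref, ref[0, ])$recall, 0)
  expect_error(boundary_recall(ref[0, ], ref), "empty reference")
  ## jittered query vs brute-force nearest-neighbour check
  withr::local_seed(61)
  jit <- ref
  shift <- sample(c(-3e5, -1e5, 0, 2e5, 4e5), nrow(ref), TRUE)
  jit$start <- jit$start + shift
  jit$end <- jit$end + shift
  rr <- boundary_recall(ref, jit, tolerance = 250e3)
  expect_equal(rr$matched, abs(shift) <= 250e3)
  expect_equal(rr$recall, mean(abs(shift) <= 250e3))
})

test_that("rank-sum density contrast separates depleted boundary bins", {
  prof <- data.frame(chrom = "chrT", bin = 1:40, center = (0:39) * 250e3,
                     count = rep(20, 40))
  attr(prof, "step") <- 250e3
  class(prof) <- c("density_profile", "data.frame")
  prof$count[c(10, 20, 30)] <- c(2, 3, 1)
  b <- doms(c(10, 20, 30) * 250e3 - 375e3, c(10, 20, 30) * 250e3 - 125e3)
  res <- density_contrast(list(s1 = prof), b)
  expect_equal(res$n_boundary, 3L)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$median_boundary, res$median_other)
  expect_error(density_contrast(prof, doms(100e6, 101e6)), "empty")
})

test_that("rank-sum p-values follow exact and approximate conventions", {
  ## exact enumeration for tiny tie-free groups
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  x <- c(5, 6, 7, 8)
  expect_equal(rank_sum_test(x, x + 0.5)$p_value,
               stats::wilcox.test(x, x + 0.5, exact = TRUE)$p.value)
  ## identical groups: p = 1 within tolerance
  expect_gt(rank_sum_test(1:30 + 0.1, 1:30 + 0.1)$p_value, 0.99)
  ## invariance under strictly monotone transforms
  withr::local_seed(3)
  a <- rnorm(25); b <- rnorm(25, 1)
  p1 <- rank_sum_test(a, b)$p_value
  p2 <- rank_sum_test(exp(a), exp(b))$p_value
  expect_equal(p1, p2)
  ## large-sample approximation close to a permutation oracle
  withr::local_seed(9)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  obs <- abs(mean(rank(c(x, y))[1:30]) - 30.5)
  perm <- replicate(2e4, {
    r <- sample(rank(c(x, y)))
    abs(mean(r[1:30]) - 30.5)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_norm <- rank_sum_test(x, y)$p_value
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  expect_lt(abs(p_norm - p_perm), max(2 * se, 0.004))
})

test_that("compartment composition counts labeled bins per domain", {
  d <- doms(c(0, 1e6), c(1e6, 2e6))
  labels <- data.frame(chrom = "chrT", start = seq(0, 1.75e6, by = 250e3),
                       label = c("A", "A", "B", "A", NA, "B", "B", "B"))
  cc <- compartment_composition(d, labels)
  expect_equal(cc$frac_A, c(0.75, 0))
  expect_equal(cc$n_unlabeled, c(0L, 1L))
  expect_equal(cc$frac_A + cc$frac_B, c(1, 1))
  ## all-A labels give fraction 1 everywhere
  labels$label <- "A"
  expect_true(all(compartment_composition(d, labels)$frac_A == 1))
  ## domain with no labeled bins is flagged NA
  d2 <- doms(5e6, 6e6)
  cc2 <- compartment_composition(d2, labels)
  expect_true(is.na(cc2$frac_A))
})
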