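## Independent brute-force oracles used to cross-check the vectorized
## implementations. These deliberately use naive loops and a different code
## path from the package internals.

## O(bins x peaks) midpoint-in-window density count
oracle_density <- function(peaks, centers, flank) {
  mids <- floor((peaks$start + peaks$end) / 2)
  vapply(centers, function(cc)
    sum(mids >= cc - flank & mids < cc + flank), numeric(1))
}

## per-bin tricube weighted least squares via explicit normal equations
oracle_local_fit <- function(y, q, degree = 2L) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(seq_len(n) - i)
    idx <- order(d, seq_len(n))[seq_len(q)]
    dmax <- max(d[idx])
    w <- if (dmax == 0) rep(1, q) else (1 - (d[idx] / dmax)^3)^3
    X <- outer(idx - i, 0:degree, `^`)
    A <- t(X) %*% (w * X)
    b <- t(X) %*% (w * y[idx])
    out[i] <- solve(A, b)[1L]
  }
  out
}

## quadratic all-pairs containment scan for anchor pairs
oracle_pair_fraction <- function(pairs, domains) {
  n <- nrow(pairs)
  intra <- logical(n)
  for (i in seq_len(n)) {
    if (pairs$chrom1[i] != pairs$chrom2[i]) next
    m1 <- floor((pairs$start1[i] + pairs$end1[i]) / 2)
    m2 <- floor((pairs$start2[i] + pairs$end2[i]) / 2)
    for (j in seq_len(nrow(domains))) {
      if (domains$chrom[j] != pairs$chrom1[i]) next
      in1 <- m1 >= domains$start[j] && m1 < domains$end[j]
      in2 <- m2 >= domains$start[j] && m2 < domains$end[j]
      if (in1 && in2) { intra[i] <- TRUE; break }
    }
  }
  intra
}

## quadratic full-containment scan for intervals
oracle_interval_intra <- function(intervals, domains) {
  n <- nrow(intervals)
  intra <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(domains))) {
      if (domains$chrom[j] != intervals$chrom[i]) next
      if (intervals$start[i] >= domains$start[j] &&
          intervals$end[i] <= domains$end[j]) { intra[i] <- TRUE; break }
    }
  }
  intra
}

## exhaustive consensus-rule application on a single-chromosome grid:
## threshold, pairwise fixpoint merging, island absorption
oracle_consensus <- function(frac, step, L, threshold = 0.25,
                             merge_dist = 250e3, min_domain = 250e3) {
  centers <- (seq_along(frac) - 1) * step
  cons <- which(frac >= threshold)
  if (!length(cons))
    return(list(boundaries = cbind(start = numeric(0), end = numeric(0)),
                domains = cbind(start = 0, end = L)))
  regs <- lapply(cons, function(b)
    c(max(0, centers[b] - step / 2), min(L, centers[b] + step / 2)))
  repeat {
    merged <- FALSE
    for (i in seq_along(regs)) {
      for (j in seq_along(regs)) {
        if (i >= j || is.null(regs[[i]]) || is.null(regs[[j]])) next
        gap <- max(regs[[i]][1], regs[[j]][1]) -
          min(regs[[i]][2], regs[[j]][2])
        if (gap < merge_dist) {
          regs[[i]] <- c(min(regs[[i]][1], regs[[j]][1]),
                         max(regs[[i]][2], regs[[j]][2]))
          regs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  m <- do.call(rbind, regs)
  m <- m[order(m[, 1]), , drop = FALSE]
  repeat {
    changed <- FALSE
    if (nrow(m) > 1L) for (i in seq_len(nrow(m) - 1L)) {
      if (m[i + 1L, 1] - m[i, 2] <= min_domain) {
        m[i, 2] <- m[i + 1L, 2]
        m <- m[-(i + 1L), , drop = FALSE]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  if (m[1L, 1] > 0 && m[1L, 1] <= min_domain) m[1L, 1] <- 0
  if (m[nrow(m), 2] < L && L - m[nrow(m), 2] <= min_domain) m[nrow(m), 2] <- L
  gaps_s <- c(0, m[, 2]); gaps_e <- c(m[, 1], L)
  keep <- gaps_e > gaps_s
  list(boundaries = cbind(start = m[, 1], end = m[, 2]),
       domains = cbind(start = gaps_s[keep], end = gaps_e[keep]))
}

## direct Poisson upper-tail series summation
oracle_poisson_tail <- function(observed, expected, terms = 200L) {
  k <- observed:(observed + terms)
  sum(exp(-expected + k * log(expected) - lgamma(k + 1)))
}

## exact hypergeometric upper tail by combinatorial summation
oracle_hyper_tail <- function(N, M, n, m) {
  ks <- m:min(M, n)
  ks <- ks[n - ks <= N - M]
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

## brute-force distinct-partner tally for contact degree
oracle_contact_degree <- function(contacts, cutoff = -10) {
  sig <- contacts[contacts$log10_p <= cutoff, , drop = FALSE]
  env <- new.env()
  for (r in seq_len(nrow(sig))) {
    ka <- paste(sig$chrom[r], sig$bin_i[r])
    kb <- paste(sig$chrom[r], sig$bin_j[r])
    pa <- get0(ka, envir = env, ifnotfound = character())
    assign(ka, union(pa, as.character(sig$bin_j[r])), envir = env)
    pb <- get0(kb, envir = env, ifnotfound = character())
    assign(kb, union(pb, as.character(sig$bin_i[r])), envir = env)
  }
  keys <- ls(env)
  stats::setNames(vapply(keys, function(k) length(get(k, envir = env)),
                         integer(1)), keys)
}

## check that two interval sets partition [0, L) on a chromosome
expect_tiling <- function(boundaries, domains, chrom, L) {
  both <- rbind(boundaries[boundaries$chrom == chrom, c("chrom", "start", "end")],
                domains[domains$chrom == chrom, c("chrom", "start", "end")])
  both <- both[order(both$start), ]
  expect_equal(both$start[1], 0)
  expect_equal(both$end[nrow(both)], L)
  if (nrow(both) > 1L)
    expect_equal(both$start[-1], both$end[-nrow(both)])
}

## small deterministic interval fixture builder
random_intervals <- function(n, chroms, L, max_len = 1e6) {
  s <- floor(runif(n, 0, L - max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + ceiling(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}

sort_iv <- function(df) df[order(df$chrom, df$start, df$end), , drop = FALSE]

## naive point-in-interval membership (loop over intervals)
ramscan_point_in <- function(pos, chrom, intervals) {
  vapply(seq_along(pos), function(i)
    any(intervals$chrom == chrom[i] & pos[i] >= intervals$start &
        pos[i] < intervals$end), logical(1))
}
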