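## Hi-C contact-level computations: vanilla-coverage normalization, Poisson
## contact significance, contact degree and A/B compartment assignment.

#' Vanilla-coverage (VC) normalization of a contact matrix
#'
#' Divides each entry by the product of its row and column coverage (row
#' sums), masks zero-coverage rows/columns to `NA`, then rescales by a
#' single global constant so the grand total over unmasked entries equals
#' that of the input.
#'
#' @param m square symmetric non-negative contact matrix.
#' @return Normalized matrix of the same dimension.
#' @export
vc_normalize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("contact matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("contact matrix must be symmetric", call. = FALSE)
  if (any(m < 0)) stop("negative contact counts", call. = FALSE)
  v <- rowSums(m)
  mask <- v == 0
  out <- m / outer(v, v)
  out[mask, ] <- NA_real_
  out[, mask] <- NA_real_
  ok <- !is.na(out)
  scale <- sum(m[ok]) / sum(out[ok])
  out[ok] <- out[ok] * scale
  out
}

#' Poisson contact significance
#'
#' Upper-tail probability `P(X >= observed)` for `X ~ Poisson(expected)`,
#' returned as `log10(p)`. Computed through the upper regularized gamma
#' function (via [stats::ppois()] in log space), so it is stable far into
#' the tail. Non-integer (normalized) observed counts use
#' `P(X >= ceiling(observed))`.
#'
#' @param observed non-negative observed contact count(s).
#' @param expected positive expected count(s), recycled.
#' @return `log10` p-value(s), `<= 0`; `observed = 0` gives 0 (p = 1).
#' @export
contact_significance <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be > 0", call. = FALSE)
  if (any(observed < 0)) stop("observed must be >= 0", call. = FALSE)
  q <- ceiling(observed) - 1
  stats::ppois(q, expected, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Add significance to a contact list
#'
#' @param contacts contact `data.frame` (see [read_contacts()]).
#' @return The same table with a `log10_p` column.
#' @export
annotate_contacts <- function(contacts) {
  contacts$log10_p <- contact_significance(contacts$observed,
                                           contacts$expected)
  contacts
}

#' Contact degree per bin
#'
#' Number of distinct significant partner bins for each locus. Each
#' significant record contributes to both endpoints; self-contacts
#' (`bin_i == bin_j`) contribute once.
#'
#' @param contacts contact list with `log10_p` computed.
#' @param logp_cutoff significance cutoff on `log10(p)` (default -10, the
#'   threshold used to call a locus a 3D-contact hub).
#' @return `data.frame` with columns `chrom`, `bin`, `degree` (bins with
#'   no significant partner are omitted).
#' @export
contact_degree <- function(contacts, logp_cutoff = -10) {
  if (is.null(contacts$log10_p))
    stop("contacts lack log10_p; run annotate_contacts()", call. = FALSE)
  sig <- contacts[contacts$log10_p <= logp_cutoff, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom = character(), bin = numeric(),
                      degree = integer()))
  fwd <- data.frame(chrom = sig$chrom, bin = sig$bin_i, partner = sig$bin_j,
                    stringsAsFactors = FALSE)
  ns <- sig$bin_i != sig$bin_j
  rev <- data.frame(chrom = sig$chrom[ns], bin = sig$bin_j[ns],
                    partner = sig$bin_i[ns], stringsAsFactors = FALSE)
  edges <- unique(rbind(fwd, rev))
  deg <- stats::aggregate(partner ~ chrom + bin, data = edges, FUN = length)
  names(deg)[names(deg) == "partner"] <- "degree"
  deg[order(deg$chrom, deg$bin), , drop = FALSE]
}

#' Leading eigenvector of a correlation matrix
#'
#' Eigenvector of the largest-magnitude eigenvalue of a symmetric matrix
#' (typically the Pearson correlation matrix of the observed/expected
#' contact matrix at 250 kb), unit-normalized. Rows marked `NA` (masked
#' low-coverage bins) are removed for the decomposition and re-inserted as
#' `NA`. A degenerate leading spectrum (tied top eigenvalues, e.g. the
#' identity) yields an all-`NA` vector with a warning.
#'
#' @param m square symmetric matrix, possibly with `NA`-masked rows.
#' @return Numeric vector of length `nrow(m)`.
#' @export
first_eigenvector <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("matrix must be square", call. = FALSE)
  mask <- apply(m, 1L, function(r) all(is.na(r)))
  mm <- m[!mask, !mask, drop = FALSE]
  if (nrow(mm) < 3L) stop("matrix smaller than 3x3 after masking", call. = FALSE)
  if (any(is.na(mm))) stop("partially-NA rows are not supported", call. = FALSE)
  if (!isTRUE(all.equal(mm, t(mm), tolerance = 1e-8)))
    stop("matrix must be symmetric", call. = FALSE)
  e <- eigen(mm, symmetric = TRUE)
  o <- order(abs(e$values), decreasing = TRUE)
  lam <- e$values[o]
  out <- rep(NA_real_, nrow(m))
  if (abs(lam[1L]) < 1e-12 ||
      (length(lam) > 1L && abs(abs(lam[1L]) - abs(lam[2L])) <= 1e-8 * abs(lam[1L]))) {
    warning("degenerate leading eigenvalues; returning NA track")
    return(out)
  }
  v <- e$vectors[, o[1L]]
  out[!mask] <- v / sqrt(sum(v^2))
  out
}

#' Assign A/B compartments from an eigenvector and an activity track
#'
#' Orients the eigenvector so that it correlates positively with a
#' transcription-activity track (Pol II peak density or TSS density), then
#' labels positive bins A and negative bins B. The result is invariant to
#' the arbitrary global sign of the eigenvector.
#'
#' @param eigenvector per-bin values (may contain `NA` for masked bins).
#' @param activity per-bin activity values, same length; must not be
#'   constant.
#' @return `data.frame` with columns `value` (oriented eigenvector) and
#'   `label` (`"A"`, `"B"` or `NA` for zero or masked bins).
#' @export
assign_compartments <- function(eigenvector, activity) {
  if (length(eigenvector) != length(activity))
    stop("eigenvector and activity must have equal length", call. = FALSE)
  ok <- !is.na(eigenvector) & !is.na(activity)
  if (stats::sd(activity[ok]) == 0)
    stop("constant activity vector: correlation undefined", call. = FALSE)
  r <- stats::cor(eigenvector[ok], activity[ok])
  v <- if (!is.na(r) && r < 0) -eigenvector else eigenvector
  label <- ifelse(is.na(v) | v == 0, NA_character_,
                  ifelse(v > 0, "A", "B"))
  data.frame(value = v, label = label, stringsAsFactors = FALSE)
}
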