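# Within-sample normalization (CPM/TPM/RPKM), between-sample normalization
# (quantile, TMM, UQ, and the counts-adjustment variants CTF/CUF), factor
# centering, and the hyperbolic arcsine transformation.

check_units_counts <- function(x, what) {
  u <- expr_units(x)
  if (!identical(u, "counts")) {
    abort(sprintf(
      "%s requires raw counts, got a matrix with units: %s",
      what, paste(u, collapse = " -> ")
    ))
  }
}

lib_sizes <- function(counts, what) {
  N <- colSums(counts)
  bad <- N <= 0
  if (any(bad)) {
    abort(sprintf(
      "%s: zero library size in sample(s): %s",
      what, paste(colnames(counts)[bad], collapse = ", ")
    ))
  }
  N
}

#' Counts per million
#'
#' Scales each sample to a library size of one million, so each column
#' sums to 1e6.
#'
#' @param counts Raw counts matrix.
#' @return Expression matrix in CPM units.
#' @export
cpm <- function(counts) {
  counts <- as_counts_matrix(counts)
  N <- lib_sizes(counts, "cpm")
  push_unit(sweep(counts, 2, N / 1e6, "/"), "cpm")
}

#' Reads per kilobase per million
#'
#' Corrects each gene count for library size first (per million reads) and
#' then for gene length (per kilobase). Column sums are generally not equal
#' across samples, unlike TPM.
#'
#' @param counts Raw counts matrix.
#' @param lengths Gene lengths in bases: named numeric vector or a
#'   (gene_id, length) data frame covering all genes.
#' @return Expression matrix in RPKM units.
#' @export
rpkm <- function(counts, lengths) {
  counts <- as_counts_matrix(counts)
  N <- lib_sizes(counts, "rpkm")
  len <- resolve_lengths(lengths, rownames(counts))
  out <- sweep(counts, 2, N / 1e6, "/") / (len / 1e3)
  push_unit(out, "rpkm")
}

#' Transcripts per million
#'
#' Divides counts by gene length (in kb) first, then scales each sample so
#' its length-corrected rates sum to one million; every column sums to 1e6.
#'
#' @inheritParams rpkm
#' @return Expression matrix in TPM units.
#' @export
tpm <- function(counts, lengths) {
  counts <- as_counts_matrix(counts)
  len <- resolve_lengths(lengths, rownames(counts))
  rate <- counts / (len / 1e3)
  tot <- colSums(rate)
  if (any(tot <= 0)) {
    abort(sprintf(
      "tpm: all-zero sample(s): %s",
      paste(colnames(counts)[tot <= 0], collapse = ", ")
    ))
  }
  push_unit(sweep(rate, 2, tot / 1e6, "/"), "tpm")
}

#' Quantile normalization
#'
#' Forces every sample to share the same value distribution: each value is
#' replaced by the mean, across samples, of the values at its rank
#' (Bolstad's procedure). Ties receive the mean of the rank-means at the
#' tied positions, via linear interpolation at the average rank.
#'
#' @param mat Expression matrix (counts, CPM, TPM, or RPKM) with >= 2
#'   samples.
#' @return Quantile-normalized expression matrix.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2) {
    abort("quantile normalization needs a matrix with >= 2 samples")
  }
  n <- nrow(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    approx(seq_len(n), ref, xout = rank(x, ties.method = "average"))$y
  })
  dimnames(out) <- dimnames(mat)
  push_unit(set_units(out, expr_units(mat)), "qnt")
}

#' Center scale factors to multiply to one
#'
#' Divides each factor by the geometric mean of all factors.
#'
#' @param raw Named vector of positive scale factors.
#' @return Centered factors whose product is 1.
#' @export
center_factors <- function(raw) {
  if (any(!is.finite(raw)) || any(raw <= 0)) {
    abort("scale factors must be positive and finite")
  }
  raw / exp(mean(log(raw)))
}

# Single-sample TMM factor against a reference column, Robinson-Oshlack
# style: M/A statistics on genes positive in both samples, double trim
# with rank thresholds (ties at the boundary kept), inverse-variance
# precision weights.
tmm_pair_factor <- function(yk, yr, Nk, Nr, logratio_trim, abs_trim, sample_id) {
  pos <- yk > 0 & yr > 0
  if (!any(pos)) {
    warn(sprintf("tmm_factors: no usable genes for sample %s; factor set to 1", sample_id))
    return(1)
  }
  yk <- yk[pos]
  yr <- yr[pos]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warn(sprintf("tmm_factors: no genes survive trimming for sample %s; factor set to 1", sample_id))
    return(1)
  }
  # inverse-variance precision weights: the delta-method variance of M is
  # (N - y) / (N y) summed over the two samples, and each gene is weighted
  # by its reciprocal
  v <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Trimmed mean of M-values scale factors
#'
#' Estimates one positive scale factor per sample from doubly trimmed,
#' precision-weighted log-fold-changes against a reference sample (the
#' sample whose 75th percentile of count/library-size is closest to the
#' mean of that statistic). Only genes with positive counts in both
#' samples enter the estimate. Factors are centered to multiply to one.
#'
#' @param counts Raw counts matrix with >= 2 samples.
#' @param logratio_trim Fraction trimmed from each tail by M, default 0.30.
#' @param abs_trim Fraction trimmed from each tail by A, default 0.05.
#' @return Named vector of centered scale factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as_counts_matrix(counts)
  check_units_counts(counts, "tmm_factors")
  if (ncol(counts) < 2) abort("tmm_factors needs >= 2 samples")
  N <- lib_sizes(counts, "tmm_factors")
  q75 <- vapply(
    seq_len(ncol(counts)),
    function(k) quantile(counts[, k] / N[k], 0.75, names = FALSE),
    numeric(1)
  )
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    tmm_pair_factor(
      counts[, k], counts[, ref], N[k], N[ref],
      logratio_trim, abs_trim, colnames(counts)[k]
    )
  }, numeric(1))
  center_factors(setNames(f, colnames(counts)))
}

#' Upper-quartile scale factors
#'
#' Removes genes with zero counts in every sample, then sets each sample's
#' factor to its 75th percentile of counts divided by its library size
#' (percentiles use linear interpolation between order statistics).
#' Factors are centered to multiply to one.
#'
#' @param counts Raw counts matrix with >= 2 samples.
#' @param prob Quantile used, default 0.75.
#' @return Named vector of centered scale factors.
#' @export
uq_factors <- function(counts, prob = 0.75) {
  counts <- as_counts_matrix(counts)
  check_units_counts(counts, "uq_factors")
  if (ncol(counts) < 2) abort("uq_factors needs >= 2 samples")
  N <- lib_sizes(counts, "uq_factors")
  nonzero <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(nonzero) == 0) abort("uq_factors: no non-zero genes")
  q <- apply(nonzero, 2, quantile, probs = prob, names = FALSE)
  if (any(q <= 0)) {
    abort(sprintf(
      "uq_factors: degenerate library (zero %g-quantile) in sample(s): %s",
      prob, paste(colnames(counts)[q <= 0], collapse = ", ")
    ))
  }
  center_factors(setNames(q / N, colnames(counts)))
}

#' Normalize by effective library size (TMM/UQ workflows)
#'
#' Multiplies each sample's library size by its scale factor and performs
#' a calculation otherwise identical to CPM on the adjusted library size.
#'
#' @param counts Raw counts matrix.
#' @param factors Centered scale factors from [tmm_factors()] or
#'   [uq_factors()], covering all samples.
#' @return Expression matrix normalized by effective library size.
#' @export
apply_effective_library_size <- function(counts, factors) {
  counts <- as_counts_matrix(counts)
  check_units_counts(counts, "apply_effective_library_size")
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing) > 0) {
    abort(sprintf("missing factors for sample(s): %s", paste(missing, collapse = ", ")))
  }
  N <- lib_sizes(counts, "apply_effective_library_size")
  f <- factors[colnames(counts)]
  push_unit(sweep(counts, 2, N * f / 1e6, "/"), "eff_libsize")
}

#' Adjust counts directly by scale factors (CTF/CUF workflows)
#'
#' Divides each gene count by its sample's scale factor, with no
#' library-size correction. With TMM factors this is the CTF method; with
#' upper-quartile factors it is CUF.
#'
#' @inheritParams apply_effective_library_size
#' @return Expression matrix of adjusted counts.
#' @export
apply_count_adjustment <- function(counts, factors) {
  counts <- as_counts_matrix(counts)
  check_units_counts(counts, "apply_count_adjustment")
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing) > 0) {
    abort(sprintf("missing factors for sample(s): %s", paste(missing, collapse = ", ")))
  }
  f <- factors[colnames(counts)]
  if (any(!is.finite(f)) || any(f <= 0)) abort("factors must be positive")
  push_unit(sweep(counts, 2, f, "/"), "count_adjusted")
}

#' Hyperbolic arcsine transformation
#'
#' Elementwise `log(x + sqrt(x^2 + 1))`: a variance-compressing transform
#' defined on all reals that needs no pseudocount. Applied in every
#' workflow, including the plain Counts workflow, before correlation.
#'
#' @param mat Expression matrix (any units).
#' @return Transformed matrix with `"asinh"` appended to its unit chain.
#' @export
asinh_transform <- function(mat) {
  out <- asinh(mat)
  dimnames(out) <- dimnames(mat)
  push_unit(set_units(out, expr_units(mat)), "asinh")
}
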