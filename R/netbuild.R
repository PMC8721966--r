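# Coexpression network construction (pairwise correlation) and the two
# topology-based re-weightings: CLR (z-scores against both endpoint genes'
# edge distributions) and weighted topological overlap.

new_network <- function(weights, kind) {
  structure(
    list(weights = weights, kind = kind, genes = rownames(weights)),
    class = "coexpression_network"
  )
}

#' Construct a coexpression network from a weight matrix
#'
#' Wraps a symmetric gene-by-gene weight matrix (zero diagonal enforced)
#' as a `coexpression_network`, e.g. for externally computed or simulated
#' edge weights.
#'
#' @param weights Symmetric numeric matrix with identical gene rownames
#'   and colnames.
#' @param kind Weight kind tag, one of `"pearson"`, `"spearman"`,
#'   `"clr"`, `"wto"`.
#' @return A `coexpression_network`.
#' @export
coexpression_network <- function(weights,
                                 kind = c("pearson", "spearman", "clr", "wto")) {
  kind <- match.arg(kind)
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights)) {
    abort("`weights` must be a square numeric matrix")
  }
  if (is.null(rownames(weights)) ||
      !identical(rownames(weights), colnames(weights))) {
    abort("`weights` needs identical gene rownames and colnames")
  }
  if (max(abs(weights - t(weights))) > 1e-8) {
    abort("`weights` must be symmetric")
  }
  diag(weights) <- 0
  new_network(weights, kind)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d genes, %s weights\n",
    length(x$genes), x$kind
  ))
  invisible(x)
}

check_network <- function(net, min_genes = 2) {
  if (!inherits(net, "coexpression_network")) {
    abort("expected a coexpression_network")
  }
  if (length(net$genes) < min_genes) {
    abort(sprintf("network needs >= %d genes", min_genes))
  }
  invisible(net)
}

#' Build a correlation coexpression network
#'
#' Computes pairwise Pearson or Spearman correlation between the rows of
#' an expression matrix (genes) across samples. Pairs involving a
#' zero-variance gene receive weight 0 so the network stays total and
#' evaluable. Spearman uses average ranks for ties.
#'
#' @param mat Expression matrix (genes x samples, typically already asinh
#'   transformed) with >= 3 samples and >= 2 genes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `coexpression_network` whose symmetric weight matrix has a
#'   zero diagonal (self-pairs are never scored).
#' @export
correlation_network <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.matrix(mat) || nrow(mat) < 2) abort("need a matrix with >= 2 genes")
  if (ncol(mat) < 3) abort("correlation needs >= 3 samples")
  w <- suppressWarnings(cor(t(mat), method = method))
  if (any(!is.finite(w))) {
    n_const <- sum(apply(mat, 1, function(x) var(x) == 0))
    inform(sprintf(
      "%d zero-variance gene(s); their correlations set to 0", n_const
    ))
    w[!is.finite(w)] <- 0
  }
  diag(w) <- 0
  new_network(w, method)
}

#' Context-likelihood-of-relatedness transformation
#'
#' For each gene i, the weights of its edges to all other genes are
#' summarized by their mean and (population) standard deviation; the edge
#' (i, j) is rescored as `sqrt(z_i(j)^2 + z_j(i)^2)` where each z-score is
#' clipped below at zero. An edge is therefore upweighted only when it is
#' high relative to the edge distributions of both endpoints.
#'
#' @param net A `coexpression_network` with >= 3 genes.
#' @return A `coexpression_network` with non-negative `clr` weights.
#' @export
clr_transform <- function(net) {
  check_network(net, min_genes = 3)
  w <- net$weights
  n <- nrow(w)
  # off-diagonal mean and population sd per gene (diagonal is 0 by
  # construction and excluded from both moments)
  mu <- rowSums(w) / (n - 1)
  s2 <- (rowSums(w^2) - (n - 1) * mu^2) / (n - 1)
  s2[s2 < 0] <- 0 # guard tiny negative round-off
  sigma <- sqrt(s2)
  degenerate <- sigma == 0
  if (any(degenerate)) {
    warn(sprintf(
      "%d gene(s) with constant edge weights; their z-scores set to 0",
      sum(degenerate)
    ))
  }
  z <- (w - mu) / ifelse(degenerate, 1, sigma)
  z[degenerate, ] <- 0
  z[z < 0] <- 0
  diag(z) <- 0
  out <- sqrt(z^2 + t(z)^2)
  dimnames(out) <- dimnames(w)
  new_network(out, "clr")
}

#' Weighted topological overlap transformation
#'
#' Rescores each edge by the weighted neighborhood the two genes share,
#' relative to the smaller of their connectivities:
#' `omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - |a_ij|)`
#' with `k_i = sum_u |a_iu|`. With `variant = "sign"` the raw signed
#' weights are used (output in `[-1, 1]`, possibly negative); with
#' `variant = "abs"` absolute weights are used first.
#'
#' @param net A `coexpression_network` with >= 3 genes and weights in
#'   `[-1, 1]`.
#' @param variant `"sign"` (default) or `"abs"`.
#' @return A `coexpression_network` with `wto` weights.
#' @export
wto_transform <- function(net, variant = c("sign", "abs")) {
  variant <- match.arg(variant)
  check_network(net, min_genes = 3)
  a <- net$weights
  if (any(abs(a) > 1 + 1e-12)) {
    abort("wto_transform requires input weights in [-1, 1]")
  }
  if (variant == "abs") a <- abs(a)
  diag(a) <- 0
  k <- rowSums(abs(a))
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - abs(a)
  if (any(den <= 0)) abort("non-positive wTO denominator; invalid input weights")
  out <- num / den
  diag(out) <- 0
  dimnames(out) <- dimnames(net$weights)
  new_network(out, "wto")
}

#' Extract network edge weights for gene pairs
#'
#' @param net A `coexpression_network`.
#' @param pairs Data frame with `gene_a`, `gene_b` columns.
#' @return Numeric vector of weights (`NA` where a gene is absent).
#' @export
network_weights <- function(net, pairs) {
  check_network(net)
  ia <- match(pairs$gene_a, net$genes)
  ib <- match(pairs$gene_b, net$genes)
  out <- rep(NA_real_, nrow(pairs))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- net$weights[cbind(ia[ok], ib[ok])]
  out
}
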