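# broom-style tidiers for the package's result objects.

#' Tidy a coexpression network into an edge tibble
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return A tibble (`gene_a`, `gene_b`, `weight`) over all unordered
#'   pairs, lexicographically ordered.
#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) {
  pairs <- all_pairs(x$genes)
  pairs$weight <- network_weights(x, pairs)
  pairs
}

#' One-row summary of a coexpression network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return A tibble with gene count, weight kind, and weight range.
#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  tibble(
    n_genes = length(x$genes), kind = x$kind,
    min_weight = min(off), max_weight = max(off)
  )
}

#' Tidy a gold standard into its labeled pair table
#'
#' @param x A `gold_standard`.
#' @param ... Unused.
#' @return The (`gene_a`, `gene_b`, `label`) tibble.
#' @method tidy gold_standard
#' @export
tidy.gold_standard <- function(x, ...) x$pairs

#' One-row summary of a gold standard
#'
#' @param x A `gold_standard`.
#' @param ... Unused.
#' @return A tibble with positive/negative counts and the prior.
#' @method glance gold_standard
#' @export
glance.gold_standard <- function(x, ...) {
  tibble(n_pos = x$n_pos, n_neg = x$n_neg, prior = x$prior)
}

#' Tidy a network evaluation into curve coordinates
#'
#' @param x A `network_evaluation`.
#' @param ... Unused.
#' @return The sweep tibble augmented with `precision`, `recall`, `tpr`,
#'   `fpr`.
#' @method tidy network_evaluation
#' @export
tidy.network_evaluation <- function(x, ...) {
  s <- x$sweep
  tot <- list(P = s$tp[nrow(s)] + s$fn[nrow(s)],
              N = s$fp[nrow(s)] + s$tn[nrow(s)])
  mutate(
    s,
    precision = .data$tp / (.data$tp + .data$fp),
    recall = .data$tp / tot$P,
    tpr = .data$tp / tot$P,
    fpr = .data$fp / tot$N
  )
}

#' One-row summary of a network evaluation
#'
#' @param x A `network_evaluation`.
#' @param ... Unused.
#' @return A tibble with auPRC, prior, log2(auPRC/prior), auROC, the
#'   precision-at-recall values, and the dropped-pair count.
#' @method glance network_evaluation
#' @export
glance.network_evaluation <- function(x, ...) {
  out <- tibble(
    auprc = x$auprc, prior = x$prior,
    log2_auprc_over_prior = x$log2_auprc_over_prior, auroc = x$auroc,
    n_dropped = x$n_dropped
  )
  for (nm in names(x$precision_at_recall)) {
    out[[nm]] <- x$precision_at_recall[[nm]]
  }
  out
}

#' Tidy a workflow comparison into its ordered-pair table
#'
#' @param x A `workflow_comparison`.
#' @param ... Unused.
#' @return The pairs tibble (`workflow_a`, `workflow_b`, `n`, `win_prop`,
#'   `p_value`, `p_adj`, `significant`).
#' @method tidy workflow_comparison
#' @export
tidy.workflow_comparison <- function(x, ...) x$pairs

#' One-row summary of a workflow comparison
#'
#' @param x A `workflow_comparison`.
#' @param ... Unused.
#' @return A tibble with the workflow count, significant-pair count, FDR
#'   threshold, and the top workflow by outperformance count.
#' @method glance workflow_comparison
#' @export
glance.workflow_comparison <- function(x, ...) {
  tibble(
    n_workflows = nrow(x$wins),
    n_pairs = nrow(x$pairs),
    n_significant = sum(x$pairs$significant),
    alpha = x$alpha,
    top_workflow = x$wins$workflow[1],
    top_wins = x$wins$n_outperformed[1]
  )
}
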