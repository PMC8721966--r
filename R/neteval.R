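# Network evaluation against a gold standard: a descending edge-weight
# threshold sweep over the labeled pairs yields confusion counts, from
# which auPRC, auROC, precision at fixed recall, and the comparable
# log2(auPRC/prior) statistic are computed by trapezoidal integration.

#' Confusion-count sweep over edge-weight thresholds
#'
#' Scores only the gold-standard pairs present in the network (pairs with
#' a missing gene are dropped and counted). Pairs are ranked by weight,
#' descending; tied weights enter a single row, so the sweep has one row
#' per distinct weight and ends with every pair predicted positive.
#'
#' @param net A `coexpression_network`.
#' @param std A `gold_standard`.
#' @return A tibble (`threshold`, `tp`, `fp`, `tn`, `fn`) with attribute
#'   `"n_dropped"` (pairs not scoreable in the network).
#' @export
confusion_sweep <- function(net, std) {
  check_network(net)
  stopifnot(inherits(std, "gold_standard"))
  w <- network_weights(net, std$pairs)
  ok <- !is.na(w)
  n_dropped <- sum(!ok)
  if (!any(ok)) abort("no gold-standard pair is scoreable in the network")
  w <- w[ok]
  lab <- std$pairs$label[ok]
  o <- order(w, decreasing = TRUE)
  w <- w[o]
  lab <- lab[o]
  tp_cum <- cumsum(lab == 1L)
  fp_cum <- cumsum(lab == 0L)
  # last index of each run of tied weights
  last <- which(c(w[-1] != w[-length(w)], TRUE))
  P <- sum(lab == 1L)
  N <- sum(lab == 0L)
  out <- tibble(
    threshold = w[last],
    tp = tp_cum[last],
    fp = fp_cum[last],
    tn = N - fp_cum[last],
    fn = P - tp_cum[last]
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

sweep_totals <- function(sweep) {
  list(P = sweep$tp[nrow(sweep)] + sweep$fn[nrow(sweep)],
       N = sweep$fp[nrow(sweep)] + sweep$tn[nrow(sweep)])
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integral of precision over recall across the sweep rows,
#' anchored at recall 0 with the precision of the highest-threshold row.
#'
#' @param sweep A confusion sweep from [confusion_sweep()].
#' @return auPRC in `[0, 1]`.
#' @export
auprc <- function(sweep) {
  stopifnot(nrow(sweep) >= 1)
  tot <- sweep_totals(sweep)
  if (tot$P == 0) abort("auprc undefined with zero positives")
  precision <- sweep$tp / (sweep$tp + sweep$fp)
  recall <- sweep$tp / tot$P
  pracma::trapz(c(0, recall), c(precision[1], precision))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the true-positive rate over the false-positive
#' rate, anchored at (0, 0); the sweep's final row supplies (1, 1).
#'
#' @inheritParams auprc
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(sweep) {
  stopifnot(nrow(sweep) >= 1)
  tot <- sweep_totals(sweep)
  if (tot$P == 0 || tot$N == 0) {
    abort("auroc undefined without both positives and negatives")
  }
  tpr <- sweep$tp / tot$P
  fpr <- sweep$fp / tot$N
  pracma::trapz(c(0, fpr), c(0, tpr))
}

#' Precision at a fixed recall level
#'
#' Step-function convention: the precision of the first sweep row whose
#' recall reaches the level (no interpolation).
#'
#' @inheritParams auprc
#' @param level Recall level in (0, 1], default 0.20.
#' @return Precision at the given recall.
#' @export
precision_at_recall <- function(sweep, level = 0.20) {
  stopifnot(level > 0, level <= 1)
  tot <- sweep_totals(sweep)
  if (tot$P == 0) abort("recall undefined with zero positives")
  recall <- sweep$tp / tot$P
  i <- which(recall >= level)[1]
  sweep$tp[i] / (sweep$tp[i] + sweep$fp[i])
}

#' Prior-normalized log accuracy
#'
#' `log2(auPRC / prior)`: the auPRC of a random ranking equals the prior
#' (the fraction of positives), so this statistic is comparable across
#' gold standards with different priors.
#'
#' @param auprc_value auPRC, > 0.
#' @param prior Fraction of positives among labeled pairs, in (0, 1).
#' @return `log2(auprc_value / prior)`.
#' @export
log2_auprc_over_prior <- function(auprc_value, prior) {
  if (!is.finite(auprc_value) || auprc_value <= 0) {
    abort("auPRC must be positive")
  }
  if (prior <= 0 || prior >= 1) abort("prior must be in (0, 1)")
  log2(auprc_value / prior)
}

#' Evaluate a network against a gold standard
#'
#' Runs the full threshold sweep and returns all evaluation statistics.
#'
#' @param net A `coexpression_network`.
#' @param std A `gold_standard`.
#' @param recall_levels Recall levels for precision-at-recall, default
#'   0.20.
#' @return A `network_evaluation` object: auPRC, prior,
#'   log2(auPRC/prior), auROC, precision at the requested recalls, the
#'   sweep tibble, and the dropped-pair count. Use [glance()] for a
#'   one-row summary and [tidy()] for the PR/ROC coordinates.
#' @export
evaluate_network <- function(net, std, recall_levels = 0.20) {
  sweep <- confusion_sweep(net, std)
  tot <- sweep_totals(sweep)
  prior <- tot$P / (tot$P + tot$N)
  au <- auprc(sweep)
  structure(
    list(
      auprc = au,
      prior = prior,
      log2_auprc_over_prior = log2_auprc_over_prior(au, prior),
      auroc = auroc(sweep),
      precision_at_recall = setNames(
        vapply(recall_levels, function(l) precision_at_recall(sweep, l),
               numeric(1)),
        paste0("p_at_r", recall_levels)
      ),
      sweep = sweep,
      n_dropped = attr(sweep, "n_dropped")
    ),
    class = "network_evaluation"
  )
}

#' @export
print.network_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<network_evaluation>\n",
      "  auPRC %.4g (prior %.4g), log2(auPRC/prior) %.3f\n",
      "  auROC %.4g; %s\n"
    ),
    x$auprc, x$prior, x$log2_auprc_over_prior, x$auroc,
    paste(sprintf("%s = %.4g", names(x$precision_at_recall),
                  x$precision_at_recall), collapse = ", ")
  ))
  invisible(x)
}
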