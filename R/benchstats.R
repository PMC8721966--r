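# Workflow comparison statistics: paired signed-rank tests over dataset
# scores with Benjamini-Hochberg correction, per-method impact summaries
# with the fairness exclusions, experimental-factor covariates, and the
# subsampling design for large source datasets.

# One-sided paired signed-rank p-value for mean(d) > 0. Zero differences
# are dropped (all-zero -> p = 1); exact null for n <= 25 without tied
# magnitudes, normal approximation with continuity correction otherwise.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, alternative = "greater", mu = 0,
                exact = exact, correct = TRUE)$p.value
  )
}

#' Pairwise workflow comparison
#'
#' For every ordered pair of workflows, computes the proportion of shared
#' datasets on which the first scores higher (ties credited 0.5) and a
#' one-sided paired Wilcoxon signed-rank p-value, then applies
#' Benjamini-Hochberg correction across all ordered pairs and flags
#' significance at `alpha`. Each workflow's outperformance count is the
#' number of workflows it significantly beats.
#'
#' @param scores Score tibble with columns `workflow`, `dataset`, and a
#'   score column (default `log2_auprc_over_prior`). Extra columns are
#'   ignored; supply one evaluation setting (one standard kind) at a time.
#' @param alpha FDR threshold, default 0.01.
#' @param score_col Name of the score column.
#' @return A `workflow_comparison` object with elements `pairs` (ordered
#'   pair table) and `wins` (per-workflow significant-win counts). Use
#'   [tidy()] / [glance()] to extract them as tibbles.
#' @export
pairwise_compare <- function(scores, alpha = 0.01,
                             score_col = "log2_auprc_over_prior") {
  stopifnot(all(c("workflow", "dataset", score_col) %in% names(scores)))
  wide <- scores |>
    select("workflow", "dataset", score = dplyr::all_of(score_col)) |>
    tidyr::pivot_wider(names_from = "workflow", values_from = "score")
  wfs <- setdiff(names(wide), "dataset")
  if (length(wfs) < 2) abort("need at least two workflows to compare")
  combos <- expand.grid(workflow_a = wfs, workflow_b = wfs,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$workflow_a != combos$workflow_b, , drop = FALSE]
  res <- purrr::pmap(combos, function(workflow_a, workflow_b) {
    sa <- wide[[workflow_a]]
    sb <- wide[[workflow_b]]
    ok <- !is.na(sa) & !is.na(sb)
    if (sum(ok) < 2) {
      abort(sprintf("fewer than 2 shared datasets for %s vs %s",
                    workflow_a, workflow_b))
    }
    d <- sa[ok] - sb[ok]
    tibble(
      workflow_a = workflow_a, workflow_b = workflow_b, n = sum(ok),
      win_prop = mean((d > 0) + 0.5 * (d == 0)),
      p_value = signed_rank_p(d)
    )
  }) |> bind_rows()
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adj <= alpha
  wins <- res |>
    group_by(workflow = .data$workflow_a) |>
    summarise(n_outperformed = sum(.data$significant), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_outperformed), .data$workflow)
  structure(list(pairs = res, wins = wins, alpha = alpha),
            class = "workflow_comparison")
}

#' @export
print.workflow_comparison <- function(x, ...) {
  cat(sprintf(
    "<workflow_comparison> %d workflows, %d ordered pairs, FDR <= %g\n",
    nrow(x$wins), nrow(x$pairs), x$alpha
  ))
  print(head(x$wins, 10))
  invisible(x)
}

stage_of <- function(stage) {
  switch(stage,
    within = WITHIN_METHODS,
    between = BETWEEN_METHODS,
    transform = TRANSFORM_METHODS
  )
}

#' Per-method impact on workflow performance
#'
#' For each method at each stage (including the "none" choice), the
#' proportion of eligible ordered comparisons (workflow containing the
#' method vs workflow not containing it) that are significant wins.
#' Fairness exclusions: workflows with any within-sample normalization
#' are excluded when assessing between-sample methods, and workflows with
#' TMM/UQ/CTF/CUF are excluded when assessing within-sample methods
#' (including "no within-sample normalization"), since those combinations
#' cannot co-occur.
#'
#' @param comparison A `workflow_comparison` whose workflow names are
#'   parseable (built from [enumerate_workflows()] names).
#' @return A tibble (`stage`, `method`, `n_comparisons`, `n_wins`,
#'   `proportion`); methods with no eligible comparison get `NA`.
#' @export
method_impact <- function(comparison) {
  stopifnot(inherits(comparison, "workflow_comparison"))
  pairs <- comparison$pairs
  wf_names <- unique(c(pairs$workflow_a, pairs$workflow_b))
  spec <- bind_rows(lapply(wf_names, parse_workflow))
  rows <- list()
  for (stage in c("within", "between", "transform")) {
    eligible <- switch(stage,
      within = spec$workflow[!spec$between %in% c("tmm", "uq", "ctf", "cuf")],
      between = spec$workflow[spec$within == "none"],
      transform = spec$workflow
    )
    for (m in stage_of(stage)) {
      with_m <- spec$workflow[spec[[stage]] == m & spec$workflow %in% eligible]
      without_m <- spec$workflow[spec[[stage]] != m & spec$workflow %in% eligible]
      sel <- pairs$workflow_a %in% with_m & pairs$workflow_b %in% without_m
      n_comp <- sum(sel)
      n_wins <- sum(pairs$significant[sel])
      rows[[length(rows) + 1]] <- tibble(
        stage = stage,
        method = if (m == "none") paste0("no_", stage) else m,
        n_comparisons = n_comp,
        n_wins = n_wins,
        proportion = if (n_comp > 0) n_wins / n_comp else NA_real_
      )
    }
  }
  bind_rows(rows)
}

#' Median between-sample similarity
#'
#' Spearman correlation between every pair of samples over the most
#' variable genes (top `variable_fraction` by variance); returns the
#' median over sample pairs.
#'
#' @param counts Counts (or expression) matrix with >= 2 samples.
#' @param variable_fraction Fraction of genes kept, default 0.5.
#' @return Median pairwise Spearman correlation.
#' @export
sample_similarity <- function(counts, variable_fraction = 0.5) {
  if (!is.matrix(counts) || ncol(counts) < 2) abort("need >= 2 samples")
  n_keep <- ceiling(nrow(counts) * variable_fraction)
  if (n_keep < 2) abort("fewer than 2 genes after variance selection")
  v <- apply(counts, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  s <- cor(counts[keep, , drop = FALSE], method = "spearman")
  median(s[upper.tri(s)])
}

#' Read-count diversity of a dataset
#'
#' Sample standard deviation (n - 1 denominator) of the per-sample count
#' sums.
#'
#' @param counts Counts matrix with >= 2 samples.
#' @return Standard deviation of the library sizes.
#' @export
read_count_diversity <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2) abort("need >= 2 samples")
  sd(colSums(counts))
}

#' Bin datasets into equal-size groups by a covariate
#'
#' Sorts datasets by value (ties broken by dataset ID for determinism) and
#' splits them into `n_bins` contiguous groups whose sizes differ by at
#' most one, the remainder going to the lowest bins first.
#'
#' @param values Named numeric vector (names = dataset IDs) or a data
#'   frame (`dataset`, `value`).
#' @param n_bins Number of groups, default 5.
#' @return A tibble (`dataset`, `value`, `bin`).
#' @export
bin_datasets <- function(values, n_bins = 5) {
  if (is.data.frame(values)) {
    df <- tibble(dataset = as.character(values[[1]]),
                 value = as.numeric(values[[2]]))
  } else {
    df <- tibble(dataset = names(values), value = as.numeric(values))
  }
  if (nrow(df) < n_bins) abort("need at least as many datasets as bins")
  df <- arrange(df, .data$value, .data$dataset)
  base <- nrow(df) %/% n_bins
  rem <- nrow(df) %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, rem), rep(0, n_bins - rem))
  df$bin <- rep(seq_len(n_bins), times = sizes)
  df
}

#' Subsampling design for large source datasets
#'
#' From each source dataset with at least `min_source` samples, draws
#' `replicates` subsets without replacement at each target size.
#' Reproducible: each draw uses a sub-seed derived from the base seed and
#' the (source, size, replicate) key, so the design is independent of
#' iteration order.
#'
#' @param corp A `coex_corpus`.
#' @param sizes Target sample sizes, default
#'   `c(5, 6, 7, 9, 11, 13, 16, 25, 40)`.
#' @param replicates Subsets per (source, size), default 10.
#' @param min_source Minimum source sample count for eligibility,
#'   default 70.
#' @param seed Base seed (required).
#' @return A tibble (`source`, `tissue`, `size`, `replicate`,
#'   `sample_ids` list-column).
#' @export
resample_design <- function(corp,
                            sizes = c(5, 6, 7, 9, 11, 13, 16, 25, 40),
                            replicates = 10,
                            min_source = 70,
                            seed) {
  stopifnot(inherits(corp, "coex_corpus"))
  if (missing(seed)) abort("`seed` is required")
  rows <- list()
  for (d in corp$datasets) {
    n <- ncol(d$counts)
    if (n < min_source) next
    ids <- colnames(d$counts)
    for (s in sizes) {
      if (s > n) {
        warn(sprintf("size %d exceeds samples in source %s; skipped", s, d$id))
        next
      }
      for (r in seq_len(replicates)) {
        sub_seed <- derive_seed(seed, paste(d$id, s, r, sep = "|"))
        picked <- with_local_seed(sub_seed, sample(ids, s))
        rows[[length(rows) + 1]] <- tibble(
          source = d$id, tissue = d$tissue, size = s, replicate = r,
          sample_ids = list(picked)
        )
      }
    }
  }
  bind_rows(rows)
}

#' Materialize a resampled corpus from a design
#'
#' @param corp The source `coex_corpus`.
#' @param design Output of [resample_design()] (or a subset of its rows).
#' @return A `coex_corpus` with one dataset per design row, named
#'   `source.sN.rM`.
#' @export
realize_resampled_corpus <- function(corp, design) {
  stopifnot(inherits(corp, "coex_corpus"))
  datasets <- purrr::pmap(design, function(source, tissue, size, replicate,
                                           sample_ids) {
    src <- corp$datasets[[source]]
    corpus_dataset(
      src$counts[, sample_ids, drop = FALSE],
      id = sprintf("%s.s%d.r%d", source, size, replicate),
      tissue = tissue
    )
  })
  corpus(datasets)
}
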