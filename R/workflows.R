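# Workflow enumeration and execution. A workflow is a triple
# (within-sample normalization, between-sample normalization, network
# transformation) obeying the compatibility constraint: TMM/UQ/CTF/CUF
# operate on raw counts, so they cannot follow a within-sample method.

WITHIN_METHODS <- c("none", "cpm", "rpkm", "tpm")
BETWEEN_METHODS <- c("none", "qnt", "tmm", "uq", "ctf", "cuf")
TRANSFORM_METHODS <- c("none", "clr", "wto")

workflow_compatible <- function(within, between) {
  within == "none" | between %in% c("none", "qnt")
}

#' Name a workflow the way the benchmark literature does
#'
#' The all-`none` triple is the `Counts` workflow; otherwise the non-none
#' stages are upper-cased and joined with underscores (e.g. `CTF_CLR`,
#' `TPM_QNT_WTO`).
#'
#' @param within,between,transform Stage method names.
#' @return Character vector of workflow names.
#' @export
workflow_name <- function(within, between, transform) {
  parts <- cbind(within, between, transform)
  apply(parts, 1, function(p) {
    p <- toupper(p[p != "none"])
    if (length(p) == 0) "Counts" else paste(p, collapse = "_")
  })
}

#' Enumerate all valid workflows
#'
#' All (within, between, transform) triples satisfying the compatibility
#' constraint, in a deterministic canonical order; 36 workflows with no
#' exclusions.
#'
#' @param exclude_methods Methods to leave out entirely (any of
#'   `cpm, rpkm, tpm, qnt, tmm, uq, ctf, cuf, clr, wto`, case-insensitive).
#' @return A tibble (`workflow`, `within`, `between`, `transform`).
#' @export
enumerate_workflows <- function(exclude_methods = character()) {
  exclude_methods <- tolower(exclude_methods)
  bad <- setdiff(exclude_methods,
                 c(WITHIN_METHODS, BETWEEN_METHODS, TRANSFORM_METHODS))
  if (length(bad) > 0) {
    abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  }
  grid <- expand.grid(
    transform = TRANSFORM_METHODS,
    between = BETWEEN_METHODS,
    within = WITHIN_METHODS,
    stringsAsFactors = FALSE
  )[, c("within", "between", "transform")]
  grid <- grid[workflow_compatible(grid$within, grid$between), , drop = FALSE]
  grid <- grid[!(grid$within %in% exclude_methods |
                   grid$between %in% exclude_methods |
                   grid$transform %in% exclude_methods), , drop = FALSE]
  tibble(
    workflow = workflow_name(grid$within, grid$between, grid$transform),
    within = grid$within,
    between = grid$between,
    transform = grid$transform
  )
}

#' Parse a workflow name back into its stage triple
#'
#' @param name Workflow name such as `"Counts"`, `"CTF_CLR"`, or
#'   `"TPM_QNT"`.
#' @return A one-row tibble (`workflow`, `within`, `between`, `transform`).
#' @export
parse_workflow <- function(name) {
  all_wf <- enumerate_workflows()
  hit <- all_wf[all_wf$workflow == name, , drop = FALSE]
  if (nrow(hit) != 1) abort(sprintf("unknown workflow name '%s'", name))
  hit
}

#' Run one workflow on a counts dataset
#'
#' Applies, in order: within-sample normalization (if any), between-sample
#' normalization (if any), the hyperbolic arcsine transformation (always),
#' pairwise correlation, and the network transformation (if any).
#'
#' @param counts Raw counts matrix (pre-filtered).
#' @param workflow A workflow name, or a one-row data frame with
#'   `within`, `between`, `transform` columns.
#' @param lengths Gene lengths (required for `tpm`/`rpkm`).
#' @param cor_method Correlation, `"pearson"` (default) or `"spearman"`.
#' @param wto_variant Passed to [wto_transform()], default `"sign"`.
#' @return A `coexpression_network`.
#' @export
run_workflow <- function(counts, workflow, lengths = NULL,
                         cor_method = "pearson", wto_variant = "sign") {
  if (is.character(workflow)) workflow <- parse_workflow(workflow)
  within <- match.arg(workflow$within, WITHIN_METHODS)
  between <- match.arg(workflow$between, BETWEEN_METHODS)
  transform <- match.arg(workflow$transform, TRANSFORM_METHODS)
  if (!workflow_compatible(within, between)) {
    abort(sprintf(
      "incompatible workflow: %s within-sample normalization cannot precede %s",
      within, between
    ))
  }
  counts <- as_counts_matrix(counts)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("workflow stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  mat <- switch(within,
    none = counts,
    cpm = stage("within:cpm", cpm(counts)),
    rpkm = stage("within:rpkm", rpkm(counts, lengths)),
    tpm = stage("within:tpm", tpm(counts, lengths))
  )
  mat <- switch(between,
    none = mat,
    qnt = stage("between:qnt", quantile_normalize(mat)),
    tmm = stage("between:tmm",
                apply_effective_library_size(counts, tmm_factors(counts))),
    uq = stage("between:uq",
               apply_effective_library_size(counts, uq_factors(counts))),
    ctf = stage("between:ctf",
                apply_count_adjustment(counts, tmm_factors(counts))),
    cuf = stage("between:cuf",
                apply_count_adjustment(counts, uq_factors(counts)))
  )
  mat <- stage("asinh", asinh_transform(mat))
  net <- stage("correlation", correlation_network(mat, cor_method))
  switch(transform,
    none = net,
    clr = stage("transform:clr", clr_transform(net)),
    wto = stage("transform:wto", wto_transform(net, wto_variant))
  )
}

#' Score a corpus under a set of workflows
#'
#' Builds one network per (workflow, dataset) and evaluates it against the
#' tissue-naive gold standard and, when tissue gene sets are supplied,
#' against the dataset's tissue-aware standard.
#'
#' @param corp A `coex_corpus`.
#' @param std The tissue-naive `gold_standard`.
#' @param workflows Workflow tibble from [enumerate_workflows()] (default:
#'   all 36).
#' @param lengths Gene lengths for `tpm`/`rpkm` workflows.
#' @param tissue_sets Optional tissue gene sets for tissue-aware scoring
#'   (data frame `tissue`, `gene_id`, or named list).
#' @param min_positives Tissue-standard rejection threshold, default 50.
#' @param cor_method Correlation method.
#' @return A score tibble (`workflow`, `dataset`, `tissue`, `standard`,
#'   `auprc`, `prior`, `log2_auprc_over_prior`, `auroc`), one row per
#'   evaluated network and standard kind.
#' @export
benchmark_corpus <- function(corp, std,
                             workflows = enumerate_workflows(),
                             lengths = NULL,
                             tissue_sets = NULL,
                             min_positives = 50,
                             cor_method = "pearson") {
  stopifnot(inherits(corp, "coex_corpus"))
  tissue_standards <- list()
  if (!is.null(tissue_sets)) {
    tissues <- unique(vapply(corp$datasets, function(d) d$tissue, character(1)))
    for (t in setdiff(tissues, NA_character_)) {
      tissue_standards[[t]] <- build_tissue_standard(
        std, tissue_sets, t, min_positives = min_positives
      )
    }
  }
  rows <- list()
  for (d in corp$datasets) {
    for (i in seq_len(nrow(workflows))) {
      wf <- workflows[i, , drop = FALSE]
      net <- run_workflow(d$counts, wf, lengths = lengths,
                          cor_method = cor_method)
      ev <- evaluate_network(net, std)
      rows[[length(rows) + 1]] <- tibble(
        workflow = wf$workflow, dataset = d$id, tissue = d$tissue,
        standard = "naive", auprc = ev$auprc, prior = ev$prior,
        log2_auprc_over_prior = ev$log2_auprc_over_prior, auroc = ev$auroc
      )
      ts <- tissue_standards[[d$tissue]]
      if (!is.null(ts)) {
        evt <- evaluate_network(net, ts)
        rows[[length(rows) + 1]] <- tibble(
          workflow = wf$workflow, dataset = d$id, tissue = d$tissue,
          standard = "tissue-aware", auprc = evt$auprc, prior = evt$prior,
          log2_auprc_over_prior = evt$log2_auprc_over_prior, auroc = evt$auroc
        )
      }
    }
  }
  bind_rows(rows)
}
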