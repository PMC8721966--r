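# Counts matrices and corpus containers: the universal pipeline inputs.
#
# A counts matrix is a non-negative numeric matrix with genes in rows
# (rownames = gene IDs) and samples in columns (colnames = sample IDs).
# Expression matrices produced by normalization carry a "units" attribute
# recording the full provenance chain (e.g. c("counts", "ctf", "asinh")).

#' Validate a gene-by-sample counts matrix
#'
#' Checks that `x` is a numeric matrix with unique, non-empty gene and
#' sample identifiers and no negative entries, and tags it with `"counts"`
#' units if it has none yet.
#'
#' @param x A numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix (invisibly unchanged apart from the units
#'   attribute).
#' @export
as_counts_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("a counts matrix must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("a counts matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x)) > 0) abort("duplicated gene identifiers")
  if (anyDuplicated(colnames(x)) > 0) abort("duplicated sample identifiers")
  if (any(!is.finite(x))) abort("counts must be finite")
  if (any(x < 0)) abort("counts must be non-negative")
  if (is.null(attr(x, "units"))) attr(x, "units") <- "counts"
  x
}

expr_units <- function(x) attr(x, "units") %||% "counts"

set_units <- function(x, units) {
  attr(x, "units") <- units
  x
}

push_unit <- function(x, unit) set_units(x, c(expr_units(x), unit))

#' Convert base-pair counts to read counts
#'
#' Sequence archives that store per-gene base-pair coverage are converted
#' to (possibly fractional) read counts by dividing each sample's column by
#' its average read length, and additionally by two for paired-end samples
#' so that a fragment sequenced from both ends counts once.
#'
#' @param bp_counts Gene-by-sample matrix of base-pair counts.
#' @param meta Data frame with columns `sample_id`, `avg_read_length`
#'   (bases, > 0) and `paired_end` (logical), one row per sample.
#' @param round_counts If `TRUE`, round the resulting counts half-to-even;
#'   by default fractional counts are kept, since downstream normalizations
#'   are scale-based.
#' @return A counts matrix with the same genes and samples.
#' @export
bp_to_gene_counts <- function(bp_counts, meta, round_counts = FALSE) {
  bp_counts <- as_counts_matrix(bp_counts)
  if (!is.data.frame(meta) ||
      !all(c("sample_id", "avg_read_length", "paired_end") %in% names(meta))) {
    abort("`meta` needs columns sample_id, avg_read_length, paired_end")
  }
  missing <- setdiff(colnames(bp_counts), as.character(meta$sample_id))
  if (length(missing) > 0) {
    abort(sprintf(
      "no sample metadata for: %s", paste(missing, collapse = ", ")
    ))
  }
  idx <- match(colnames(bp_counts), as.character(meta$sample_id))
  rl <- as.numeric(meta$avg_read_length)[idx]
  if (any(!is.finite(rl)) || any(rl <= 0)) {
    abort("avg_read_length must be positive for every sample")
  }
  ends <- ifelse(as.logical(meta$paired_end)[idx], 2, 1)
  out <- sweep(bp_counts, 2, rl * ends, "/")
  if (round_counts) out[] <- round(out)
  as_counts_matrix(set_units(out, "counts"))
}

#' Sum transcript-level counts to gene-level counts
#'
#' @param transcript_counts Transcript-by-sample counts matrix.
#' @param tx2gene Data frame (transcript_id, gene_id) or named character
#'   vector mapping transcript IDs to gene IDs.
#' @return A gene-by-sample counts matrix. Transcripts without a mapping
#'   are dropped with a warning reporting how many.
#' @export
sum_transcripts_to_genes <- function(transcript_counts, tx2gene) {
  transcript_counts <- as_counts_matrix(transcript_counts)
  if (is.data.frame(tx2gene)) {
    map <- setNames(as.character(tx2gene[[2]]), as.character(tx2gene[[1]]))
  } else if (is.character(tx2gene) && !is.null(names(tx2gene))) {
    map <- tx2gene
  } else {
    abort("`tx2gene` must be a two-column data frame or named character vector")
  }
  if (length(map) == 0) abort("empty transcript-to-gene mapping")
  tx <- rownames(transcript_counts)
  mapped <- tx %in% names(map)
  if (!any(mapped)) abort("no transcript in the matrix has a gene mapping")
  if (any(!mapped)) {
    warn(sprintf(
      "%d transcript(s) without a gene mapping dropped", sum(!mapped)
    ))
  }
  kept <- transcript_counts[mapped, , drop = FALSE]
  genes <- map[rownames(kept)]
  out <- rowsum(kept, group = genes, reorder = TRUE)
  as_counts_matrix(set_units(out, "counts"))
}

#' Remove low-coverage samples
#'
#' Drops samples with zero counts in at least `zero_fraction_threshold` of
#' all genes (inclusive bound). Each sample is judged against the full gene
#' set independently, so removal order cannot matter.
#'
#' @param counts Counts matrix.
#' @param zero_fraction_threshold Fraction of zero-count genes at or above
#'   which a sample is removed; in (0, 1], default 0.5.
#' @return The counts matrix with offending samples removed (possibly with
#'   zero columns, in which case a warning is raised).
#' @export
filter_low_coverage_samples <- function(counts, zero_fraction_threshold = 0.5) {
  counts <- as_counts_matrix(counts)
  if (zero_fraction_threshold <= 0 || zero_fraction_threshold > 1) {
    abort("`zero_fraction_threshold` must be in (0, 1]")
  }
  zero_frac <- colMeans(counts == 0)
  keep <- zero_frac < zero_fraction_threshold
  if (!any(keep)) warn("all samples removed by the low-coverage filter")
  counts[, keep, drop = FALSE]
}

#' Keep only long-RNA gene biotypes
#'
#' @param counts Counts matrix.
#' @param types Data frame (gene_id, biotype) or named character vector.
#' @param keep Biotype labels to retain, e.g.
#'   `c("protein_coding", "lncRNA", "antisense")`.
#' @return Counts matrix restricted to genes whose biotype is in `keep`.
#'   Genes missing from the biotype table are dropped with a warning.
#' @export
filter_gene_types <- function(counts,
                              types,
                              keep = c("protein_coding", "lncRNA", "antisense")) {
  counts <- as_counts_matrix(counts)
  if (length(keep) == 0) abort("`keep` must name at least one biotype")
  if (is.data.frame(types)) {
    tv <- setNames(as.character(types[[2]]), as.character(types[[1]]))
  } else if (is.character(types) && !is.null(names(types))) {
    tv <- types
  } else {
    abort("`types` must be a two-column data frame or named character vector")
  }
  genes <- rownames(counts)
  known <- genes %in% names(tv)
  if (any(!known)) {
    warn(sprintf("%d gene(s) missing from the biotype table dropped", sum(!known)))
  }
  retain <- known & tv[genes] %in% keep
  counts[retain, , drop = FALSE]
}

# ---- corpus ---------------------------------------------------------------

#' Bundle datasets into a corpus
#'
#' A corpus is a named collection of datasets, each holding a counts
#' matrix, optional per-sample metadata, and a tissue label. It is the
#' unit over which gene filtering and benchmarking operate.
#'
#' @param datasets A list of datasets created with [corpus_dataset()].
#' @return An object of class `coex_corpus`.
#' @export
corpus <- function(datasets) {
  if (!is.list(datasets)) abort("`datasets` must be a list")
  ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ids) > 0) abort("dataset IDs must be unique")
  names(datasets) <- ids
  structure(list(datasets = datasets), class = "coex_corpus")
}

#' @param counts Counts matrix for one dataset.
#' @param id Unique dataset identifier.
#' @param tissue Tissue label (may be `NA`).
#' @param meta Optional per-sample metadata tibble.
#' @rdname corpus
#' @export
corpus_dataset <- function(counts, id, tissue = NA_character_, meta = NULL) {
  counts <- as_counts_matrix(counts)
  if (ncol(counts) < 1) abort("a dataset needs at least one sample")
  structure(
    list(counts = counts, id = as.character(id),
         tissue = as.character(tissue), meta = meta),
    class = "coex_dataset"
  )
}

#' @export
print.coex_corpus <- function(x, ...) {
  cat(sprintf("<coex_corpus> %d dataset(s)\n", length(x$datasets)))
  for (d in x$datasets) {
    cat(sprintf(
      "  %s [%s]: %d genes x %d samples\n",
      d$id, d$tissue, nrow(d$counts), ncol(d$counts)
    ))
  }
  invisible(x)
}

corpus_ids <- function(corp) names(corp$datasets)

#' Quality-filter a corpus
#'
#' Applies the preprocessing filters in order: low-coverage samples are
#' removed from each dataset, then datasets falling below the minimum
#' sample count are dropped. With `strict_sample_qc = TRUE` a dataset is
#' dropped as soon as any of its samples fails the coverage filter.
#'
#' @param corp A `coex_corpus`.
#' @param zero_fraction_threshold Passed to [filter_low_coverage_samples()].
#' @param min_samples Minimum samples per retained dataset (inclusive).
#' @param strict_sample_qc Drop whole datasets that lost any sample.
#' @return The filtered corpus.
#' @export
filter_corpus_samples <- function(corp,
                                  zero_fraction_threshold = 0.5,
                                  min_samples = 5,
                                  strict_sample_qc = FALSE) {
  stopifnot(inherits(corp, "coex_corpus"))
  kept <- list()
  for (d in corp$datasets) {
    filtered <- filter_low_coverage_samples(d$counts, zero_fraction_threshold)
    if (strict_sample_qc && ncol(filtered) < ncol(d$counts)) next
    if (ncol(filtered) < min_samples) next
    d$counts <- filtered
    if (!is.null(d$meta)) {
      d$meta <- d$meta[d$meta$sample_id %in% colnames(filtered), , drop = FALSE]
    }
    kept[[d$id]] <- d
  }
  corpus(kept)
}

#' Drop datasets with too few samples
#'
#' @param corp A `coex_corpus`.
#' @param min_samples Minimum number of samples (inclusive), default 5.
#' @return The filtered corpus.
#' @export
filter_min_samples <- function(corp, min_samples = 5) {
  stopifnot(inherits(corp, "coex_corpus"), min_samples >= 1)
  kept <- Filter(function(d) ncol(d$counts) >= min_samples, corp$datasets)
  corpus(kept)
}

#' Corpus-wide low-expression gene filter
#'
#' A gene is retained if, in at least one dataset, its CPM is at or above
#' `cpm_threshold` in at least `sample_fraction` of that dataset's samples
#' (both bounds inclusive). All datasets are then subset to the common
#' retained gene set, so the result is invariant to dataset order.
#'
#' @param corp A `coex_corpus` (already sample-filtered).
#' @param cpm_threshold Counts-per-million threshold, default 1.
#' @param sample_fraction Fraction of samples, default 0.2.
#' @return The corpus restricted to the retained genes. The retained gene
#'   IDs are attached as attribute `"retained_genes"`.
#' @export
filter_low_expression_genes <- function(corp,
                                        cpm_threshold = 1,
                                        sample_fraction = 0.2) {
  stopifnot(inherits(corp, "coex_corpus"))
  if (length(corp$datasets) == 0) abort("empty corpus")
  keep_any <- character(0)
  for (d in corp$datasets) {
    cc <- cpm(d$counts)
    frac <- rowMeans(cc >= cpm_threshold)
    keep_any <- union(keep_any, rownames(cc)[frac >= sample_fraction])
  }
  if (length(keep_any) == 0) warn("no gene passed the expression filter")
  keep_any <- sort(keep_any)
  out <- lapply(corp$datasets, function(d) {
    d$counts <- d$counts[intersect(rownames(d$counts), keep_any), , drop = FALSE]
    d
  })
  res <- corpus(out)
  attr(res, "retained_genes") <- keep_any
  res
}
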