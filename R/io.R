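# Plain-text interchange: tab-delimited counts matrices (genes in rows,
# header of sample IDs), two-column lookup tables, gold-standard pair
# tables, edge lists, and a directory-of-datasets corpus layout with a
# YAML manifest. gzip is handled transparently by the readers/writers.

#' Read a gene-by-sample counts matrix from a tab-delimited file
#'
#' First column gene IDs, header row of sample IDs; optionally gzipped.
#' Ensembl-style version suffixes (`.12`) can be stripped from gene IDs.
#'
#' @param path File path.
#' @param strip_versions Strip trailing `.N` version suffixes from gene
#'   IDs (default `TRUE`); the number stripped is reported.
#' @return A counts matrix.
#' @export
read_counts_matrix <- function(path, strip_versions = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(df[[1]])
  if (strip_versions) {
    stripped <- sub("\\.\\d+$", "", genes)
    n_changed <- sum(stripped != genes)
    if (n_changed > 0) {
      inform(sprintf("stripped version suffixes from %d gene ID(s)", n_changed))
    }
    genes <- stripped
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  as_counts_matrix(m)
}

#' Write a counts or expression matrix as tab-delimited text
#'
#' @param mat Matrix with gene rownames and sample colnames.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param id_col Name of the gene-ID column, default `"gene_id"`.
#' @export
write_counts_matrix <- function(mat, path, id_col = "gene_id") {
  df <- as.data.frame(mat)
  df <- cbind(setNames(data.frame(rownames(mat)), id_col), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

read_two_col <- function(path, names, col2 = readr::col_character()) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    X1 = readr::col_character(), X2 = col2
  ), comment = "#", progress = FALSE)
  setNames(df, names)
}

#' Read a gene-length table
#'
#' Two-column tab-delimited file: gene ID, length in bases (no header).
#'
#' @param path File path.
#' @return A tibble (`gene_id`, `length`).
#' @export
read_gene_lengths <- function(path) {
  out <- read_two_col(path, c("gene_id", "length"), readr::col_double())
  if (any(out$length < 1)) abort("gene lengths must be >= 1")
  out
}

#' Read a gene-biotype table
#'
#' Two-column tab-delimited file: gene ID, biotype label (no header).
#'
#' @param path File path.
#' @return A tibble (`gene_id`, `biotype`).
#' @export
read_gene_types <- function(path) {
  read_two_col(path, c("gene_id", "biotype"))
}

#' Read a transcript-to-gene map
#'
#' Two-column tab-delimited file: transcript ID, gene ID (no header).
#'
#' @param path File path.
#' @return A tibble (`transcript_id`, `gene_id`).
#' @export
read_tx2gene <- function(path) {
  read_two_col(path, c("transcript_id", "gene_id"))
}

#' Read per-sample metadata
#'
#' Tab-delimited with a header: `sample_id`, `avg_read_length`,
#' `paired_end` (true/false).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    avg_read_length = readr::col_double(),
    paired_end = readr::col_logical()
  ), progress = FALSE)
}

#' Read a GO term list (one term ID per line)
#'
#' @param path File path.
#' @return Character vector of term IDs.
#' @export
read_term_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read tissue gene sets
#'
#' Two-column tab-delimited file: tissue, gene ID (no header).
#'
#' @param path File path.
#' @return A tibble (`tissue`, `gene_id`).
#' @export
read_tissue_gene_sets <- function(path) {
  read_two_col(path, c("tissue", "gene_id"))
}

#' Write / read a gold standard as a three-column table
#'
#' Tab-delimited `gene_a`, `gene_b`, `label` (1/0) with a header and
#' canonically ordered pairs.
#'
#' @param std A `gold_standard`.
#' @param path File path.
#' @export
write_gold_standard <- function(std, path) {
  stopifnot(inherits(std, "gold_standard"))
  readr::write_tsv(std$pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    label = readr::col_integer()
  ), progress = FALSE)
  gold_standard(df)
}

#' Export a network as an edge list
#'
#' Tab-delimited `gene_a`, `gene_b`, `weight` over all unordered pairs,
#' lexicographically ordered; bit-stable for a fixed input ordering.
#'
#' @param net A `coexpression_network`.
#' @param path Output path; `.gz` triggers gzip.
#' @param digits Significant digits written, default 10.
#' @export
write_edge_list <- function(net, path, digits = 10) {
  check_network(net)
  pairs <- all_pairs(net$genes)
  pairs$weight <- signif(network_weights(net, pairs), digits)
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    weight = readr::col_double()
  ), progress = FALSE)
}

#' Write / read a corpus as a directory of datasets
#'
#' Each dataset's counts go to `<id>.counts.tsv` (and metadata, when
#' present, to `<id>.meta.tsv`); a `manifest.yaml` records dataset IDs,
#' tissues, and file names.
#'
#' @param corp A `coex_corpus`.
#' @param dir Directory (created if needed).
#' @export
write_corpus <- function(corp, dir) {
  stopifnot(inherits(corp, "coex_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(corp$datasets, function(d) {
    counts_file <- paste0(d$id, ".counts.tsv")
    write_counts_matrix(d$counts, file.path(dir, counts_file))
    entry <- list(id = d$id, tissue = d$tissue, counts = counts_file)
    if (!is.null(d$meta)) {
      meta_file <- paste0(d$id, ".meta.tsv")
      readr::write_tsv(d$meta, file.path(dir, meta_file), progress = FALSE)
      entry$meta <- meta_file
    }
    entry
  })
  yaml::write_yaml(unname(manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  datasets <- lapply(manifest, function(entry) {
    corpus_dataset(
      read_counts_matrix(file.path(dir, entry$counts)),
      id = entry$id,
      tissue = entry$tissue %||% NA_character_,
      meta = if (!is.null(entry$meta)) {
        read_sample_meta(file.path(dir, entry$meta))
      }
    )
  })
  corpus(datasets)
}
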