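# Small programmatic fixtures shared across the test files.

# random counts matrix, optionally guaranteed all-positive
random_counts <- function(n_genes, n_samples, max_count = 200, min_count = 0,
                          prefix = "G") {
  m <- matrix(
    sample(min_count:max_count, n_genes * n_samples, replace = TRUE),
    nrow = n_genes,
    dimnames = list(
      sprintf("%s%03d", prefix, seq_len(n_genes)),
      sprintf("S%03d", seq_len(n_samples))
    )
  )
  as_counts_matrix(m * 1.0)
}

# random symmetric correlation-like weight matrix with zero diagonal
random_weight_matrix <- function(n_genes) {
  w <- matrix(runif(n_genes^2, -1, 1), n_genes)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("G%03d", seq_len(n_genes)))
  w
}

as_network <- function(w, kind = "pearson") {
  structure(list(weights = w, kind = kind, genes = rownames(w)),
            class = "coexpression_network")
}

# gold standard over a gene set: first `n_pos` pairs positive
toy_standard <- function(genes, n_pos) {
  cmb <- combn(sort(genes), 2)
  pairs <- tibble::tibble(
    gene_a = cmb[1, ], gene_b = cmb[2, ],
    label = as.integer(seq_len(ncol(cmb)) <= n_pos)
  )
  gold_standard(pairs)
}

# six-gene annotation fixture: two disjoint specific terms of three genes
toy_annotations <- function() {
  tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E", "F"),
    term_id = rep(c("GO:0000001", "GO:0000002"), each = 3),
    evidence = "IDA"
  )
}

# write a small GAF 2.2 file; returns its path
write_toy_gaf <- function(records, path = tempfile(fileext = ".gaf")) {
  gaf_line <- function(gene, term, evidence, qualifier = "involved_in",
                       aspect = "P") {
    paste(
      c("TESTDB", gene, gene, qualifier, term, "PMID:1", evidence, "",
        aspect, "", "", "protein", "taxon:9606", "20260101", "TESTDB",
        "", ""),
      collapse = "\t"
    )
  }
  lines <- c(
    "!gaf-version: 2.2",
    mapply(gaf_line, records$gene, records$term, records$evidence,
           if ("qualifier" %in% names(records)) records$qualifier
           else rep("involved_in", nrow(records)))
  )
  writeLines(lines, path)
  path
}

`%||%` <- rlang::`%||%`

pairs_key <- function(p) paste(p$gene_a, p$gene_b, sep = "|")
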