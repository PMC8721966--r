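# Functional gold standards: positive gene pairs are co-annotations to
# specific GO Biological Process terms under experimental/curated evidence;
# negatives are the screened remainder among genes carrying at least one
# positive edge. Tissue-aware standards subset the naive one by tissue
# expression membership.

#' Default experimental/curated GO evidence codes
#'
#' Experimental (EXP, IDA, IPI, IMP, IGI, TAS) plus curated (IC) evidence.
#' Expression-based IEP annotations are always excluded to avoid
#' circularity with coexpression.
#'
#' @export
experimental_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "TAS", "IC")
}

#' Read GO annotations from a GAF 2.x file
#'
#' Retains Biological Process annotations whose evidence code is in
#' `allowed_evidence`, dropping NOT-qualified records and any evidence in
#' `excluded_evidence` (IEP by default, regardless of the allowed list).
#' Malformed lines (fewer than 15 fields) are skipped with their line
#' numbers logged; more than 10% malformed is an error.
#'
#' @param path Path to a GAF 2.x file (may be gzipped).
#' @param allowed_evidence Evidence codes to keep.
#' @param excluded_evidence Evidence codes to drop unconditionally.
#' @param aspect GO aspect to keep; `"P"` for Biological Process.
#' @param id_column `"db_object_id"` (GAF column 2, default) or
#'   `"db_object_symbol"` (column 3) as the gene identifier.
#' @return A tibble with columns `gene_id`, `term_id`, `evidence`.
#' @export
read_gaf <- function(path,
                     allowed_evidence = experimental_evidence_codes(),
                     excluded_evidence = "IEP",
                     aspect = "P",
                     id_column = c("db_object_id", "db_object_symbol")) {
  id_column <- match.arg(id_column)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  malformed <- nf < 15
  if (any(malformed)) {
    warn(sprintf(
      "skipped %d malformed GAF line(s): %s",
      sum(malformed),
      paste(head(body_idx[malformed], 10), collapse = ", ")
    ))
    if (mean(malformed) > 0.10) {
      abort("more than 10% of GAF lines are malformed")
    }
  }
  fields <- fields[!malformed]
  if (length(fields) == 0) {
    return(tibble(gene_id = character(), term_id = character(),
                  evidence = character()))
  }
  gene_col <- if (id_column == "db_object_id") 2L else 3L
  rec <- tibble(
    gene_id = vapply(fields, `[[`, character(1), gene_col),
    qualifier = vapply(fields, `[[`, character(1), 4L),
    term_id = vapply(fields, `[[`, character(1), 5L),
    evidence = vapply(fields, `[[`, character(1), 7L),
    aspect = vapply(fields, `[[`, character(1), 9L)
  )
  rec |>
    filter(
      .data$aspect == !!aspect,
      !grepl("(^|\\|)NOT($|\\|)", .data$qualifier),
      .data$evidence %in% allowed_evidence,
      !.data$evidence %in% excluded_evidence,
      nzchar(.data$gene_id),
      nzchar(.data$term_id)
    ) |>
    select("gene_id", "term_id", "evidence") |>
    distinct()
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `n_overlap` shared genes between two
#' gene sets of sizes `size_a` and `size_b` drawn from a universe of
#' `universe` genes.
#'
#' @param n_overlap Observed overlap.
#' @param size_a,size_b Set sizes.
#' @param universe Universe size.
#' @return P(X >= n_overlap) for X hypergeometric.
#' @export
hypergeom_overlap_p <- function(n_overlap, size_a, size_b, universe) {
  if (n_overlap < 0 || size_a < 0 || size_b < 0 ||
      n_overlap > min(size_a, size_b) ||
      max(size_a, size_b) > universe) {
    abort("inconsistent hypergeometric counts")
  }
  phyper(n_overlap - 1, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

new_gold_standard <- function(pairs) {
  n_pos <- sum(pairs$label == 1)
  n_neg <- sum(pairs$label == 0)
  structure(
    list(
      pairs = pairs,
      n_pos = n_pos,
      n_neg = n_neg,
      prior = n_pos / (n_pos + n_neg)
    ),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "<gold_standard> %d positives, %d negatives, prior %.4g\n",
    x$n_pos, x$n_neg, x$prior
  ))
  invisible(x)
}

#' Construct a gold standard from labeled pairs
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`, `label`
#'   (1 = positive, 0 = negative); pairs are canonicalized and self-pairs
#'   rejected.
#' @return A `gold_standard` object with its prior.
#' @export
gold_standard <- function(pairs) {
  stopifnot(all(c("gene_a", "gene_b", "label") %in% names(pairs)))
  if (any(pairs$gene_a == pairs$gene_b)) abort("self-pairs are not allowed")
  cp <- canonical_pairs(pairs$gene_a, pairs$gene_b)
  out <- tibble(
    gene_a = cp$gene_a, gene_b = cp$gene_b,
    label = as.integer(pairs$label)
  ) |> distinct()
  key <- pair_key(out$gene_a, out$gene_b)
  if (anyDuplicated(key) > 0) {
    abort("a gene pair appears as both positive and negative")
  }
  if (!all(out$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  new_gold_standard(arrange(out, .data$gene_a, .data$gene_b))
}

#' Build the tissue-naive gold standard from annotations
#'
#' Positive edges are all unordered gene pairs co-annotated to at least
#' one specific term. Candidate negatives are the remaining pairs among
#' genes that carry at least one positive edge; a candidate is left
#' unlabeled (excluded) if (a) its two genes are annotated to two
#' different specific terms whose gene sets overlap significantly
#' (hypergeometric p < `overlap_alpha`, universe = all annotated genes),
#' or (b) the pair is co-annotated to any general term.
#'
#' @param ann Annotation tibble (`gene_id`, `term_id`, ...), already
#'   restricted to the retained evidence codes (see [read_gaf()]).
#' @param specific_terms Character vector of specific term IDs.
#' @param general_terms Character vector of general term IDs (disjoint
#'   from `specific_terms`).
#' @param overlap_alpha Raw p-value threshold for the term-overlap screen,
#'   default 0.05 (no multiple-testing correction).
#' @return A `gold_standard`.
#' @export
build_naive_standard <- function(ann,
                                 specific_terms,
                                 general_terms = character(),
                                 overlap_alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(ann)))
  if (length(intersect(specific_terms, general_terms)) > 0) {
    abort("specific and general term lists must be disjoint")
  }
  ann <- distinct(ann, .data$gene_id, .data$term_id)
  universe <- length(unique(ann$gene_id))
  term_genes <- split(ann$gene_id, ann$term_id)
  spec <- term_genes[intersect(specific_terms, names(term_genes))]

  positives <- bind_rows(lapply(spec, all_pairs)) |> distinct()
  if (nrow(positives) == 0) abort("no positive pairs from the specific terms")
  pos_key <- pair_key(positives$gene_a, positives$gene_b)

  pos_genes <- unique(c(positives$gene_a, positives$gene_b))
  candidates <- all_pairs(pos_genes)
  cand_key <- pair_key(candidates$gene_a, candidates$gene_b)
  candidates <- candidates[!cand_key %in% pos_key, , drop = FALSE]

  # (a) cross-pairs of significantly overlapping specific-term pairs
  excl_key <- character(0)
  terms <- names(spec)
  if (length(terms) >= 2) {
    for (i in seq_len(length(terms) - 1)) {
      for (j in seq(i + 1, length(terms))) {
        gi <- unique(spec[[i]])
        gj <- unique(spec[[j]])
        p <- hypergeom_overlap_p(
          length(intersect(gi, gj)), length(gi), length(gj), universe
        )
        if (p < overlap_alpha) {
          cross <- expand.grid(gene_a = gi, gene_b = gj,
                               stringsAsFactors = FALSE)
          cross <- cross[cross$gene_a != cross$gene_b, , drop = FALSE]
          cp <- canonical_pairs(cross$gene_a, cross$gene_b)
          excl_key <- c(excl_key, pair_key(cp$gene_a, cp$gene_b))
        }
      }
    }
  }
  # (b) pairs co-annotated to any general term
  gen <- term_genes[intersect(general_terms, names(term_genes))]
  for (g in gen) {
    gp <- all_pairs(unique(g))
    if (nrow(gp) > 0) excl_key <- c(excl_key, pair_key(gp$gene_a, gp$gene_b))
  }

  ckey <- pair_key(candidates$gene_a, candidates$gene_b)
  negatives <- candidates[!ckey %in% excl_key, , drop = FALSE]
  if (nrow(negatives) == 0) abort("no negative pairs after screening")

  gold_standard(bind_rows(
    mutate(positives, label = 1L),
    mutate(negatives, label = 0L)
  ))
}

#' Subset a gold standard to a tissue
#'
#' A positive edge is kept when both genes are expressed in the tissue. A
#' negative edge is kept when both genes are expressed in the tissue, or
#' when one gene is expressed in the tissue and the other in at least one
#' of the other considered tissues. Standards with fewer than
#' `min_positives` surviving positives are rejected (returns `NULL` with a
#' message), not an error.
#'
#' @param naive A `gold_standard` (tissue-naive).
#' @param tissue_sets Data frame (`tissue`, `gene_id`) or named list of
#'   gene-ID vectors covering all considered tissues.
#' @param tissue Tissue to subset to (must be in `tissue_sets`).
#' @param min_positives Minimum surviving positive edges, default 50
#'   (inclusive).
#' @return A `gold_standard` with recomputed prior, or `NULL` if rejected.
#' @export
build_tissue_standard <- function(naive, tissue_sets, tissue,
                                  min_positives = 50) {
  stopifnot(inherits(naive, "gold_standard"))
  sets <- if (is.data.frame(tissue_sets)) {
    split(as.character(tissue_sets[[2]]), as.character(tissue_sets[[1]]))
  } else {
    tissue_sets
  }
  if (!tissue %in% names(sets)) {
    abort(sprintf("tissue '%s' not in the tissue gene sets", tissue))
  }
  in_tissue <- unique(sets[[tissue]])
  in_other <- unique(unlist(sets[setdiff(names(sets), tissue)], use.names = FALSE))

  pairs <- naive$pairs
  a_in <- pairs$gene_a %in% in_tissue
  b_in <- pairs$gene_b %in% in_tissue
  both_in <- a_in & b_in
  one_in_other <- (a_in & pairs$gene_b %in% in_other) |
    (b_in & pairs$gene_a %in% in_other)
  keep <- ifelse(pairs$label == 1L, both_in, both_in | one_in_other)
  sub <- pairs[keep, , drop = FALSE]
  n_pos <- sum(sub$label == 1L)
  if (n_pos < min_positives) {
    inform(sprintf(
      "tissue '%s' rejected: %d positive edge(s) < %d required",
      tissue, n_pos, min_positives
    ))
    return(NULL)
  }
  if (sum(sub$label == 0L) == 0) {
    inform(sprintf("tissue '%s' rejected: no negative edges survive", tissue))
    return(NULL)
  }
  new_gold_standard(sub)
}
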