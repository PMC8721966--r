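# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. Keeps generator draws reproducible without
# clobbering the session RNG.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed from a base seed and a character key, so
# that per-dataset / per-replicate draws are independent of iteration order.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(as.character(key))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Resolve a gene-length input (named vector or two-column data frame) to a
# named numeric vector covering `gene_ids`; errors list the missing genes.
resolve_lengths <- function(lengths, gene_ids, arg = "lengths") {
  if (is.data.frame(lengths)) {
    if (ncol(lengths) < 2) {
      abort(sprintf("`%s` data frame needs columns gene_id and length", arg))
    }
    lv <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  } else if (is.numeric(lengths) && !is.null(names(lengths))) {
    lv <- lengths
  } else {
    abort(sprintf("`%s` must be a named numeric vector or a two-column data frame", arg))
  }
  missing <- setdiff(gene_ids, names(lv))
  if (length(missing) > 0) {
    abort(sprintf(
      "missing gene lengths for %d gene(s): %s",
      length(missing), paste(head(missing, 5), collapse = ", ")
    ))
  }
  out <- lv[gene_ids]
  if (any(!is.finite(out)) || any(out < 1)) {
    abort(sprintf("all `%s` must be finite and >= 1", arg))
  }
  out
}

# Canonical unordered gene-pair keys: gene_a < gene_b lexicographically.
canonical_pairs <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  tibble(gene_a = a, gene_b = b)
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

# All unordered pairs from a character vector, canonically ordered.
all_pairs <- function(genes) {
  genes <- sort(unique(genes))
  if (length(genes) < 2) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  idx <- utils::combn(length(genes), 2)
  tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])
}
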