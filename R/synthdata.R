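# Synthetic RNA-seq corpora with planted coexpression modules. Counts are
# negative binomial around gene baselines scaled by a log-normal library
# factor; genes in the same module share a per-sample latent activity, so
# within-module pairs are the planted positives of the matching gold
# standard and cross-module pairs the negatives (background genes stay
# unlabeled).

#' Configuration for the synthetic count generator
#'
#' Defaults describe a high-signal bulk RNA-seq-like dataset: 100 genes of
#' which 5 modules of 10 carry a shared latent activity with effect size
#' `beta = 1.5`, negative-binomial dispersion 0.2 (variance
#' `mu + phi * mu^2`), library-size factors log-normal with sdlog 0.3, and
#' gene baselines log-normal around 50 counts with a wide dynamic range.
#'
#' @param n_genes Total genes.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (scalar or length-`n_modules`);
#'   modules are disjoint and must fit within `n_genes`.
#' @param n_samples Samples per dataset.
#' @param library_sdlog sdlog of the log-normal library-size factor.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression.
#' @param beta Module effect size multiplying the latent activity.
#' @param dispersion Negative-binomial dispersion phi.
#' @param length_range Range (bases) for uniform integer gene lengths.
#' @param avg_read_length Average read length recorded in sample metadata.
#' @param paired_end Paired-end flag recorded in sample metadata.
#' @param seed Seed (required; every draw is reproducible).
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_genes = 100,
                         n_modules = 5,
                         module_size = 10,
                         n_samples = 100,
                         library_sdlog = 0.3,
                         baseline_meanlog = log(50),
                         baseline_sdlog = 1.5,
                         beta = 1.5,
                         dispersion = 0.2,
                         length_range = c(200L, 10000L),
                         avg_read_length = 100,
                         paired_end = FALSE,
                         seed) {
  if (missing(seed)) abort("`seed` is required")
  module_size <- rep_len(module_size, n_modules)
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), n_samples = as.integer(n_samples),
    library_sdlog = library_sdlog, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, beta = beta, dispersion = dispersion,
    length_range = as.integer(length_range),
    avg_read_length = avg_read_length, paired_end = isTRUE(paired_end),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 2 || cfg$n_samples < 1) abort("invalid dimensions")
  if (sum(cfg$module_size) > cfg$n_genes) {
    abort("modules do not fit in the gene universe")
  }
  if (any(cfg$module_size < 2)) abort("module_size must be >= 2")
  if (cfg$dispersion <= 0 || cfg$library_sdlog < 0 || cfg$baseline_sdlog < 0) {
    abort("dispersion must be > 0 and sdlog parameters >= 0")
  }
  if (cfg$length_range[1] < 1 || cfg$length_range[2] < cfg$length_range[1]) {
    abort("invalid length_range")
  }
  structure(cfg, class = "synth_config")
}

# Gene-level quantities shared across datasets of a corpus: identities,
# module assignment, baselines, lengths.
synth_genes <- function(cfg) {
  with_local_seed(derive_seed(cfg$seed, "genes"), {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    module <- rep(NA_integer_, cfg$n_genes)
    pos <- 1L
    for (m in seq_len(cfg$n_modules)) {
      module[pos:(pos + cfg$module_size[m] - 1L)] <- m
      pos <- pos + cfg$module_size[m]
    }
    list(
      gene_ids = gene_ids,
      module = module,
      baseline = rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog),
      length = sample(seq(cfg$length_range[1], cfg$length_range[2]),
                      cfg$n_genes, replace = TRUE)
    )
  })
}

synth_standard <- function(gene_ids, module) {
  in_mod <- !is.na(module)
  ids <- gene_ids[in_mod]
  mods <- module[in_mod]
  pairs <- all_pairs(ids)
  ma <- mods[match(pairs$gene_a, ids)]
  mb <- mods[match(pairs$gene_b, ids)]
  gold_standard(mutate(pairs, label = as.integer(ma == mb)))
}

synth_samples <- function(cfg, genes, seed_key, sample_prefix) {
  with_local_seed(derive_seed(cfg$seed, seed_key), {
    sample_ids <- sprintf("%s_S%03d", sample_prefix, seq_len(cfg$n_samples))
    s <- rlnorm(cfg$n_samples, 0, cfg$library_sdlog)
    act <- matrix(rnorm(cfg$n_modules * cfg$n_samples),
                  nrow = cfg$n_modules)
    effect <- matrix(1, nrow = cfg$n_genes, ncol = cfg$n_samples)
    in_mod <- !is.na(genes$module)
    effect[in_mod, ] <- exp(cfg$beta * act[genes$module[in_mod], , drop = FALSE])
    mu <- sweep(genes$baseline * effect, 2, s, "*")
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$dispersion),
      nrow = cfg$n_genes,
      dimnames = list(genes$gene_ids, sample_ids)
    )
    list(counts = as_counts_matrix(counts * 1.0),
         meta = tibble(
           sample_id = sample_ids,
           avg_read_length = cfg$avg_read_length,
           paired_end = cfg$paired_end
         ))
  })
}

#' Generate one synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @return A list with `counts` (matrix), `meta` (sample metadata tibble),
#'   `lengths` (tibble `gene_id`, `length`), `truth` (list: `modules`
#'   tibble and the planted `standard`), and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synth_genes(cfg)
  smp <- synth_samples(cfg, genes, "samples", "D1")
  list(
    counts = smp$counts,
    meta = smp$meta,
    lengths = tibble(gene_id = genes$gene_ids, length = genes$length),
    truth = list(
      modules = tibble(gene_id = genes$gene_ids, module = genes$module),
      standard = synth_standard(genes$gene_ids, genes$module)
    ),
    config = cfg
  )
}

#' Generate a synthetic corpus with a shared gold standard
#'
#' All datasets share the gene universe, module truth, baselines and
#' lengths; each dataset draws its own samples. Tissue labels are assigned
#' round-robin and, emulating tissue-restricted expression knowledge, each
#' tissue's expressed gene set is the union of the modules assigned to it
#' (round-robin over modules).
#'
#' @param cfg A [synth_config()]; its seed governs the whole corpus.
#' @param n_datasets Number of datasets.
#' @param n_tissues Number of tissue labels, default 3.
#' @return A list with `corpus` (a `coex_corpus`), `standard` (the shared
#'   planted `gold_standard`), `truth` (modules tibble), `lengths`, and
#'   `tissue_sets` (tibble `tissue`, `gene_id`).
#' @export
generate_corpus <- function(cfg, n_datasets, n_tissues = 3) {
  stopifnot(inherits(cfg, "synth_config"), n_datasets >= 1)
  genes <- synth_genes(cfg)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  datasets <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    id <- sprintf("DS%03d", i)
    smp <- synth_samples(cfg, genes, paste0("dataset|", id), id)
    datasets[[i]] <- corpus_dataset(
      smp$counts, id = id,
      tissue = tissues[((i - 1) %% n_tissues) + 1],
      meta = smp$meta
    )
  }
  mod_tissue <- tissues[((seq_len(cfg$n_modules) - 1) %% n_tissues) + 1]
  tissue_sets <- tibble(
    tissue = mod_tissue[genes$module[!is.na(genes$module)]],
    gene_id = genes$gene_ids[!is.na(genes$module)]
  )
  list(
    corpus = corpus(datasets),
    standard = synth_standard(genes$gene_ids, genes$module),
    truth = tibble(gene_id = genes$gene_ids, module = genes$module),
    lengths = tibble(gene_id = genes$gene_ids, length = genes$length),
    tissue_sets = tissue_sets
  )
}
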