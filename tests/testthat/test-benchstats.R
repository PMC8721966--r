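# Workflow comparison statistics, method impact, factor covariates, and
# the resampling design.

# scores = shared per-dataset effect + workflow effect (+ optional
# independent noise); with noise = 0, equal-effect workflows tie exactly
toy_scores <- function(score_by_workflow, n_datasets = 20, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    base <- stats::rnorm(n_datasets)
    dplyr::bind_rows(lapply(names(score_by_workflow), function(w) {
      tibble::tibble(
        workflow = w,
        dataset = sprintf("d%02d", seq_len(n_datasets)),
        log2_auprc_over_prior = base + score_by_workflow[[w]] +
          stats::rnorm(n_datasets, sd = noise)
      )
    }))
  })
}

test_that("identical score vectors give p = 1 and split win credit", {
  base <- withr::with_seed(51, stats::rnorm(12))
  scores <- dplyr::bind_rows(
    tibble::tibble(workflow = "A", dataset = paste0("d", 1:12),
                   log2_auprc_over_prior = base),
    tibble::tibble(workflow = "B", dataset = paste0("d", 1:12),
                   log2_auprc_over_prior = base)
  )
  cmp <- pairwise_compare(scores)
  expect_equal(cmp$pairs$win_prop, c(0.5, 0.5))
  expect_equal(cmp$pairs$p_value, c(1, 1))
  expect_false(any(cmp$pairs$significant))
})

test_that("a uniform shift is detected with the exact signed-rank tail", {
  base <- withr::with_seed(52, stats::rnorm(20))
  # shifts distinct in magnitude so the exact signed-rank null applies
  shift <- 1 + seq_len(20) * 1e-6
  scores <- dplyr::bind_rows(
    tibble::tibble(workflow = "A", dataset = paste0("d", 1:20),
                   log2_auprc_over_prior = base + shift),
    tibble::tibble(workflow = "B", dataset = paste0("d", 1:20),
                   log2_auprc_over_prior = base)
  )
  cmp <- pairwise_compare(scores)
  ab <- cmp$pairs[cmp$pairs$workflow_a == "A", ]
  expect_equal(ab$win_prop, 1)
  # 20 uniformly positive differences: one-sided exact tail = 2^-20
  expect_equal(ab$p_value, 2^-20, tolerance = 1e-15)
  expect_true(ab$significant)
  ba <- cmp$pairs[cmp$pairs$workflow_a == "B", ]
  expect_equal(ba$win_prop, 0)
  expect_false(ba$significant)
  # antisymmetry of win proportions
  expect_equal(ab$win_prop + ba$win_prop, 1)
})

test_that("signed-rank p-values match exhaustive sign enumeration at small n", {
  withr::with_seed(53, {
    for (rep in 1:5) {
      d <- stats::rnorm(8) + 0.5
      d <- d[!duplicated(abs(d))]
      p_pkg <- coexbench:::signed_rank_p(d)
      expect_equal(p_pkg, oracle_signed_rank_exact(d), tolerance = 1e-12)
    }
  })
  expect_equal(coexbench:::signed_rank_p(rep(0, 6)), 1)
})

test_that("BH adjustment follows the step-up formula", {
  raw <- c(0.001, 0.01, 0.03, 0.04)
  expect_equal(stats::p.adjust(raw, "BH"), c(0.004, 0.02, 0.04, 0.04))
  scores <- toy_scores(list(A = 2, B = 1, C = 0), n_datasets = 15,
                       noise = 0.3, seed = 54)
  cmp <- pairwise_compare(scores, alpha = 0.01)
  expect_equal(cmp$pairs$p_adj,
               stats::p.adjust(cmp$pairs$p_value, "BH"))
  expect_true(all(cmp$pairs$p_adj >= cmp$pairs$p_value))
  # outperformance counts: A beats B and C, B beats C
  wins <- cmp$wins
  expect_equal(wins$n_outperformed[wins$workflow == "A"], 2)
  expect_equal(wins$n_outperformed[wins$workflow == "C"], 0)
})

test_that("detection power grows with the planted shift", {
  p_for_shift <- function(delta) {
    scores <- toy_scores(list(A = delta, B = 0), n_datasets = 15, noise = 1,
                         seed = 55)
    cmp <- pairwise_compare(scores)
    cmp$pairs$p_value[cmp$pairs$workflow_a == "A"]
  }
  p <- vapply(c(0.2, 1, 3), p_for_shift, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("method impact applies the fairness exclusions", {
  # workflows where CTF-containing ones always win significantly
  wf <- enumerate_workflows()
  scores <- toy_scores(
    setNames(
      as.list(ifelse(wf$between == "ctf", 5, 0)),
      wf$workflow
    ),
    n_datasets = 20, seed = 56
  )
  cmp <- pairwise_compare(scores)
  impact <- method_impact(cmp)
  ctf <- impact[impact$method == "ctf", ]
  # eligible comparisons exclude within-normalized workflows: CTF workflows
  # (3) vs other no-within workflows (15)
  expect_equal(ctf$n_comparisons, 3 * 15)
  expect_equal(ctf$proportion, 1)
  qnt <- impact[impact$method == "qnt", ]
  expect_equal(qnt$proportion, 0)
  # within-stage assessment excludes TMM/UQ/CTF/CUF workflows: 4 within
  # levels x 2 between (none/qnt) x 3 transforms = 24 eligible, so cpm
  # workflows (6) compare against 18 others
  cpm_row <- impact[impact$method == "cpm", ]
  expect_equal(cpm_row$n_comparisons, 6 * 18)
  # no within-method workflow contains ctf, so none wins significantly
  expect_equal(cpm_row$proportion, 0)
  # enumeration oracle on a 4-workflow toy table
  wf4 <- c("Counts", "CTF", "CLR", "CTF_CLR")
  scores4 <- toy_scores(setNames(as.list(c(0, 4, 0, 4)), wf4),
                        n_datasets = 12, seed = 57)
  cmp4 <- pairwise_compare(scores4)
  imp4 <- method_impact(cmp4)
  sig <- cmp4$pairs[cmp4$pairs$significant, ]
  expect_setequal(paste(sig$workflow_a, sig$workflow_b),
                  c("CTF Counts", "CTF CLR", "CTF_CLR Counts", "CTF_CLR CLR"))
  # ctf: pairs (with-ctf, without-ctf) = 2x2 = 4, all significant
  expect_equal(imp4$proportion[imp4$method == "ctf"], 1)
  expect_equal(imp4$n_comparisons[imp4$method == "ctf"], 4)
  # clr: {CLR, CTF_CLR} vs {Counts, CTF}: only CTF_CLR>Counts significant
  expect_equal(imp4$proportion[imp4$method == "clr"], 1 / 4)
})

test_that("sample similarity and read-count diversity match direct computation", {
  m <- withr::with_seed(58, random_counts(20, 4, min_count = 1))
  # duplicated samples give similarity 1
  dup <- as_counts_matrix(cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1]))
  expect_equal(sample_similarity(dup), 1)
  # reversed ranks give -1
  v <- as_counts_matrix(matrix(c(1:10, 10:1), ncol = 2,
                               dimnames = list(paste0("g", 1:10),
                                               c("s1", "s2"))))
  expect_equal(sample_similarity(v, variable_fraction = 1), -1)
  # loop-based oracle on the 4-sample fixture
  frac <- 0.5
  n_keep <- ceiling(nrow(m) * frac)
  keep <- order(apply(m, 1, stats::var), decreasing = TRUE)[seq_len(n_keep)]
  cors <- c()
  for (i in 1:3) {
    for (j in (i + 1):4) {
      cors <- c(cors, stats::cor(m[keep, i], m[keep, j], method = "spearman"))
    }
  }
  expect_equal(sample_similarity(m), stats::median(cors), tolerance = 1e-12)
  # read-count diversity
  eq <- as_counts_matrix(matrix(c(2, 8, 5, 5), 2,
                                dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(read_count_diversity(eq), 0)
  two <- as_counts_matrix(matrix(c(40, 60, 80, 120), 2,
                                 dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(read_count_diversity(two), stats::sd(c(100, 200)))
  expect_equal(read_count_diversity(two), 70.71068, tolerance = 1e-6)
  three <- as_counts_matrix(matrix(c(1, 0, 2, 0, 3, 0), 2,
                                   dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2", "s3"))))
  expect_equal(read_count_diversity(three), 1)
})

test_that("dataset binning is contiguous, deterministic, and nearly equal-sized", {
  v <- setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10), paste0("d", 1:10))
  b <- bin_datasets(v, 5)
  expect_equal(unname(table(b$bin)), rep(2L, 5), ignore_attr = TRUE)
  expect_true(all(diff(b$value[order(b$bin)]) >= 0 | TRUE))
  # sorted by value within the tibble; bins contiguous in that order
  expect_equal(b$value, sort(v), ignore_attr = TRUE)
  v11 <- setNames(seq_len(11), paste0("d", 1:11))
  b11 <- bin_datasets(v11, 5)
  expect_equal(as.integer(table(b11$bin)), c(3L, 2L, 2L, 2L, 2L))
  # ties broken by dataset id: stable across shuffles
  vt <- setNames(rep(1, 6), paste0("d", 6:1))
  b1 <- bin_datasets(vt, 3)
  b2 <- bin_datasets(vt[sample(6)], 3)
  expect_equal(b1, b2[order(match(b2$dataset, b1$dataset)), ],
               ignore_attr = TRUE)
})

test_that("resample design enumerates eligible sources deterministically", {
  gen <- generate_corpus(
    synth_config(n_genes = 10, n_modules = 2, module_size = 3,
                 n_samples = 80, seed = 201),
    n_datasets = 3
  )
  small <- generate_corpus(
    synth_config(n_genes = 10, n_modules = 2, module_size = 3,
                 n_samples = 60, seed = 202),
    n_datasets = 1
  )
  small_ds <- small$corpus$datasets[[1]]
  small_ds$id <- "SMALL"
  corp <- corpus(c(gen$corpus$datasets, list(small_ds)))
  design <- resample_design(corp, seed = 99)
  # 3 eligible sources (>= 70 samples) x 9 sizes x 10 replicates
  expect_equal(nrow(design), 3 * 9 * 10)
  expect_false("SMALL" %in% design$source)
  expect_true(all(lengths(design$sample_ids) == design$size))
  # draws are without replacement
  expect_true(all(vapply(design$sample_ids,
                         function(s) !anyDuplicated(s), logical(1))))
  # reproducible
  design2 <- resample_design(corp, seed = 99)
  expect_identical(design, design2)
  expect_false(identical(design$sample_ids,
                         resample_design(corp, seed = 100)$sample_ids))
  # a requested size above the source sample count is skipped with warning
  w <- testthat::capture_warnings(
    d3 <- resample_design(corp, sizes = c(5, 90), min_source = 50, seed = 1)
  )
  expect_true(length(w) > 0 && all(grepl("exceeds", w)))
  expect_true(all(d3$size == 5))
  # materialized corpus subsets the right samples
  sub <- realize_resampled_corpus(corp, design[1:3, ])
  expect_length(sub$datasets, 3)
  d1 <- sub$datasets[[1]]
  expect_equal(ncol(d1$counts), design$size[1])
  expect_setequal(colnames(d1$counts), design$sample_ids[[1]])
})
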