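# Within- and between-sample normalization, factor centering, asinh.

test_that("cpm scales columns to one million", {
  m <- as_counts_matrix(matrix(c(1, 1, 2), 3,
                               dimnames = list(paste0("g", 1:3), "s1")))
  expect_equal(unname(cpm(m)[, 1]), c(250000, 250000, 500000))
  single <- as_counts_matrix(matrix(7, 1, dimnames = list("g1", "s1")))
  expect_equal(unname(cpm(single)[, 1]), 1e6)
  rnd <- withr::with_seed(11, random_counts(30, 6, min_count = 1))
  expect_equal(unname(colSums(cpm(rnd))), rep(1e6, 6))
  zero <- as_counts_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(cpm(zero), "s1")
})

test_that("rpkm corrects library size then length; tpm corrects length first", {
  m <- as_counts_matrix(matrix(c(10, 20), 2,
                               dimnames = list(c("g1", "g2"), "s1")))
  len <- c(g1 = 1000, g2 = 2000)
  r <- rpkm(m, len)
  expect_equal(unname(r[, 1]), c(10 / (30 / 1e6) / 1, 20 / (30 / 1e6) / 2))
  expect_equal(r["g1", 1], r["g2", 1]) # both 333333.33
  t <- tpm(m, len)
  expect_equal(unname(t[, 1]), c(5e5, 5e5)) # equal rates after length division
  # equal lengths: tpm proportional to cpm
  rnd <- withr::with_seed(12, random_counts(20, 4, min_count = 1))
  eq_len <- setNames(rep(500, 20), rownames(rnd))
  expect_equal(unname(tpm(rnd, eq_len)), unname(cpm(rnd)),
               ignore_attr = TRUE)
  # tpm columns always sum to 1e6; rpkm columns generally do not
  lens <- setNames(sample(200:5000, 20), rownames(rnd))
  expect_equal(unname(colSums(tpm(rnd, lens))), rep(1e6, 4))
  demo <- as_counts_matrix(matrix(c(10, 10), 2,
                                  dimnames = list(c("g1", "g2"), "s1")))
  expect_false(isTRUE(all.equal(sum(rpkm(demo, len)[, 1]), 1e6)))
  expect_error(rpkm(m, c(g1 = 1000)), "g2")
})

test_that("quantile normalization matches hand computation and the rank-mean oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  same <- cbind(s1 = c(4, 1, 9), s2 = c(4, 1, 9))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(quantile_normalize(same)), unname(same),
               ignore_attr = TRUE)
  # ties: average of the tied positions' rank-means (4x3 oracle case)
  tied <- matrix(c(5, 5, 2, 8,
                   1, 3, 3, 7,
                   4, 4, 4, 9), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(quantile_normalize(tied)), unname(oracle_quantile_normalize(tied)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sorted columns identical; value multisets equal across columns
  rnd <- withr::with_seed(13, matrix(rnorm(40), 10, 4))
  dimnames(rnd) <- list(paste0("g", 1:10), paste0("s", 1:4))
  qn <- quantile_normalize(rnd)
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]), ignore_attr = TRUE)
  # idempotent in the tie-free case
  expect_equal(unname(quantile_normalize(qn)), unname(qn), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("factor centering divides by the geometric mean", {
  expect_equal(center_factors(c(a = 2, b = 0.5)), c(a = 2, b = 0.5))
  expect_equal(center_factors(c(a = 2, b = 2)), c(a = 1, b = 1))
  expect_equal(center_factors(c(a = 1, b = 4)), c(a = 0.5, b = 2))
  f <- withr::with_seed(5, runif(7, 0.2, 3))
  names(f) <- paste0("s", 1:7)
  cf <- center_factors(f)
  expect_equal(prod(cf), 1, tolerance = 1e-12)
  expect_equal(center_factors(cf), cf, tolerance = 1e-12)
  expect_error(center_factors(c(1, -1)), "positive")
})

test_that("tmm factors are 1 for identical or purely depth-scaled columns", {
  m <- withr::with_seed(21, random_counts(50, 3, min_count = 1))
  dup <- m[, c(1, 1, 1, 1)]
  colnames(dup) <- paste0("s", 1:4)
  f <- tmm_factors(as_counts_matrix(dup))
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)
  scaled <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  expect_equal(unname(tmm_factors(as_counts_matrix(scaled))), c(1, 1),
               tolerance = 1e-12)
})

test_that("tmm factors match the straight-line oracle, including asymmetric fixtures", {
  withr::with_seed(22, {
    for (rep in 1:20) {
      m <- random_counts(sample(8:12, 1), sample(3:6, 1),
                         min_count = 1, max_count = 500)
      expect_equal(tmm_factors(m), oracle_tmm_factors(m), tolerance = 1e-10)
    }
    # 10% of genes inflated 8-fold in one sample
    m <- random_counts(50, 3, min_count = 5, max_count = 300)
    m[1:5, 2] <- m[1:5, 2] * 8
    m <- as_counts_matrix(m)
    expect_equal(tmm_factors(m), oracle_tmm_factors(m), tolerance = 1e-10)
  })
})

test_that("uq factors match the percentile oracle and depth-scaling gives 1", {
  m <- withr::with_seed(23, random_counts(40, 4, min_count = 0, max_count = 400))
  m[1:6, ] <- 0 # all-zero genes must be removed before the percentile
  m <- as_counts_matrix(m)
  expect_equal(uq_factors(m), oracle_uq_factors(m), tolerance = 1e-10)
  dup <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = 3 * m[, 1])
  expect_equal(unname(uq_factors(as_counts_matrix(dup))), rep(1, 3),
               tolerance = 1e-12)
  # heavy high-count tail fixture
  skewed <- withr::with_seed(24, {
    s <- random_counts(60, 3, min_count = 1, max_count = 50)
    s[1:10, 3] <- s[1:10, 3] + 5000
    as_counts_matrix(s)
  })
  expect_equal(uq_factors(skewed), oracle_uq_factors(skewed), tolerance = 1e-10)
  # sample with >75% zero counts but a positive library size
  degen <- as_counts_matrix(matrix(c(rep(0, 7), 1, 2:9), ncol = 2,
                                   dimnames = list(paste0("g", 1:8),
                                                   c("bad", "ok"))))
  expect_error(uq_factors(degen), "degenerate")
})

test_that("tmm and uq factors agree with edgeR on positive-count fixtures", {
  skip_if_not_installed("edgeR")
  withr::with_seed(25, {
    for (rep in 1:5) {
      m <- random_counts(80, 5, min_count = 1, max_count = 1000)
      ef <- edgeR::calcNormFactors(m, method = "TMM")
      expect_equal(unname(tmm_factors(m)), unname(ef), tolerance = 1e-10)
      eu <- edgeR::calcNormFactors(m, method = "upperquartile", p = 0.75)
      expect_equal(unname(uq_factors(m)), unname(eu), tolerance = 1e-10)
    }
  })
})

test_that("factor estimates are invariant under global count rescaling", {
  m <- withr::with_seed(26, random_counts(30, 4, min_count = 1))
  expect_equal(tmm_factors(as_counts_matrix(m * 3)), tmm_factors(m),
               tolerance = 1e-10)
  expect_equal(uq_factors(as_counts_matrix(m * 3)), uq_factors(m),
               tolerance = 1e-10)
})

test_that("effective-library-size and direct count adjustment apply factors correctly", {
  m <- withr::with_seed(27, random_counts(20, 3, min_count = 1))
  ones <- setNames(rep(1, 3), colnames(m))
  expect_equal(unname(apply_effective_library_size(m, ones)), unname(cpm(m)),
               ignore_attr = TRUE)
  one <- as_counts_matrix(matrix(c(10, 90), 2,
                                 dimnames = list(c("g1", "g2"), "s1")))
  f <- c(s1 = 2)
  expect_equal(apply_effective_library_size(one, f)["g1", 1], 10 / 200 * 1e6)
  expect_equal(apply_count_adjustment(one, f)["g1", 1], 5)
  expect_equal(unname(apply_count_adjustment(m, ones)), unname(m),
               ignore_attr = TRUE)
  # CTF and TMM outputs differ exactly by the per-sample factor 1e6 / N_k
  tf <- tmm_factors(m)
  ctf <- apply_count_adjustment(m, tf)
  tmm <- apply_effective_library_size(m, tf)
  N <- colSums(m)
  expect_equal(unname(tmm), unname(sweep(ctf, 2, 1e6 / N, "*")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_count_adjustment(m, tf[-1]), "missing factors")
  # unit-tag guard: CTF/TMM refuse already-normalized input
  expect_error(apply_count_adjustment(cpm(m), tf), "raw counts")
  expect_error(tmm_factors(cpm(m)), "raw counts")
})

test_that("count adjustment of depth-scaled replicates leaves constant gene ratios", {
  base <- withr::with_seed(28, random_counts(40, 1, min_count = 10)[, 1])
  m <- as_counts_matrix(cbind(s1 = base, s2 = 4 * base))
  adj <- apply_count_adjustment(m, tmm_factors(m))
  ratios <- adj[, 2] / adj[, 1]
  expect_equal(unname(ratios), rep(ratios[[1]], length(ratios)),
               tolerance = 1e-10)
})

test_that("asinh transform matches its closed form and round-trips", {
  m <- matrix(c(0, 1, 1e6), 3, dimnames = list(paste0("g", 1:3), "s1"))
  out <- asinh_transform(m)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], log(1 + sqrt(2)))
  expect_equal(out[3, 1], log(2 * 1e6), tolerance = 1e-9)
  x <- withr::with_seed(29, matrix(rnorm(50, sd = 10), 10, 5))
  dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:5))
  y <- asinh_transform(x)
  expect_true(all(diff(asinh(sort(x))) > 0)) # monotone
  expect_equal(unname(sinh(y)), unname(x), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(tail(attr(y, "units"), 1), "asinh")
})
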