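# Independent brute-force oracles, written as plain scalar loops straight
# from the method definitions. They deliberately share no code with the
# package internals so that agreement is evidence, not tautology.

oracle_quantile_normalize <- function(mat) {
  n <- nrow(mat)
  sorted <- sapply(seq_len(ncol(mat)), function(j) sort(mat[, j]))
  ref <- numeric(n)
  for (i in seq_len(n)) ref[i] <- mean(sorted[i, ])
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    for (i in seq_len(n)) {
      lo <- floor(r[i])
      hi <- ceiling(r[i])
      out[i, j] <- (ref[lo] + ref[hi]) / 2
    }
  }
  out
}

# linear-interpolation percentile between order statistics (type 7)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  n_samp <- ncol(counts)
  N <- numeric(n_samp)
  for (k in seq_len(n_samp)) N[k] <- sum(counts[, k])
  q <- numeric(n_samp)
  for (k in seq_len(n_samp)) q[k] <- oracle_percentile(counts[, k] / N[k], 0.75)
  ref <- which.min(abs(q - mean(q)))
  raw <- numeric(n_samp)
  for (k in seq_len(n_samp)) {
    if (k == ref) {
      raw[k] <- 1
      next
    }
    M <- c()
    A <- c()
    w <- c()
    for (g in seq_len(nrow(counts))) {
      yk <- counts[g, k]
      yr <- counts[g, ref]
      if (yk > 0 && yr > 0) {
        M <- c(M, log2((yk / N[k]) / (yr / N[ref])))
        A <- c(A, 0.5 * log2((yk / N[k]) * (yr / N[ref])))
        # precision weight = 1 / delta-method variance of M
        w <- c(w, 1 / ((N[k] - yk) / (N[k] * yk) +
                         (N[ref] - yr) / (N[ref] * yr)))
      }
    }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    num <- 0
    den <- 0
    for (g in seq_len(n)) {
      if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
        num <- num + w[g] * M[g]
        den <- den + w[g]
      }
    }
    raw[k] <- 2^(num / den)
  }
  centered <- raw / prod(raw)^(1 / n_samp)
  names(centered) <- colnames(counts)
  centered
}

oracle_uq_factors <- function(counts, p = 0.75) {
  keep <- rep(FALSE, nrow(counts))
  for (g in seq_len(nrow(counts))) keep[g] <- any(counts[g, ] > 0)
  raw <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    raw[k] <- oracle_percentile(counts[keep, k], p) / sum(counts[, k])
  }
  centered <- raw / prod(raw)^(1 / length(raw))
  names(centered) <- colnames(counts)
  centered
}

oracle_clr <- function(W) {
  n <- nrow(W)
  out <- matrix(0, n, n, dimnames = dimnames(W))
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    vals <- W[i, others]
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2))
    for (j in others) {
      z[i, j] <- if (sigma == 0) 0 else max(0, (W[i, j] - mu) / sigma)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
    }
  }
  out
}

oracle_wto <- function(W, variant = "sign") {
  a <- if (variant == "abs") abs(W) else W
  diag(a) <- 0
  n <- nrow(a)
  out <- matrix(0, n, n, dimnames = dimnames(W))
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(abs(a[i, ]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - abs(a[i, j]))
    }
  }
  out
}

# brute force over every distinct threshold, predicting positive at
# weight >= threshold
oracle_sweep <- function(weights, labels) {
  thr <- sort(unique(weights), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    pred <- weights >= t
    data.frame(
      threshold = t,
      tp = sum(pred & labels == 1),
      fp = sum(pred & labels == 0),
      tn = sum(!pred & labels == 0),
      fn = sum(!pred & labels == 1)
    )
  })
  do.call(rbind, rows)
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

oracle_auprc <- function(weights, labels) {
  sw <- oracle_sweep(weights, labels)
  P <- sum(labels == 1)
  prec <- sw$tp / (sw$tp + sw$fp)
  rec <- sw$tp / P
  oracle_trapz(c(0, rec), c(prec[1], prec))
}

oracle_auroc <- function(weights, labels) {
  sw <- oracle_sweep(weights, labels)
  oracle_trapz(c(0, sw$fp / sum(labels == 0)), c(0, sw$tp / sum(labels == 1)))
}

# exact one-sided signed-rank p-value by enumerating all sign vectors
oracle_signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 0L
  geq <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    w <- sum(r[signs])
    total <- total + 1L
    if (w >= w_obs) geq <- geq + 1L
  }
  geq / total
}

# exhaustive pair-labeling oracle for the naive gold standard on small
# annotation fixtures
oracle_naive_standard <- function(ann, specific_terms, general_terms = character(),
                                  alpha = 0.05) {
  ann <- unique(ann[, c("gene_id", "term_id")])
  universe <- length(unique(ann$gene_id))
  genes_of <- function(t) unique(ann$gene_id[ann$term_id == t])
  spec <- intersect(specific_terms, unique(ann$term_id))
  pos <- list()
  for (t in spec) {
    g <- sort(genes_of(t))
    if (length(g) >= 2) {
      cmb <- combn(g, 2)
      for (c_i in seq_len(ncol(cmb))) {
        pos[[paste(cmb[, c_i], collapse = "|")]] <- TRUE
      }
    }
  }
  pos_genes <- sort(unique(unlist(strsplit(names(pos), "|", fixed = TRUE))))
  labels <- list()
  for (i in seq_along(pos_genes)) {
    for (j in seq_along(pos_genes)) {
      if (i >= j) next
      g1 <- pos_genes[i]
      g2 <- pos_genes[j]
      key <- paste(sort(c(g1, g2)), collapse = "|")
      if (!is.null(pos[[key]])) {
        labels[[key]] <- 1L
        next
      }
      excluded <- FALSE
      for (t1 in spec) {
        for (t2 in spec) {
          if (t1 == t2) next
          s1 <- genes_of(t1)
          s2 <- genes_of(t2)
          if (g1 %in% s1 && g2 %in% s2) {
            ov <- length(intersect(s1, s2))
            p <- phyper(ov - 1, length(s1), universe - length(s1),
                        length(s2), lower.tail = FALSE)
            if (p < alpha) excluded <- TRUE
          }
        }
      }
      for (t in intersect(general_terms, unique(ann$term_id))) {
        g <- genes_of(t)
        if (g1 %in% g && g2 %in% g) excluded <- TRUE
      }
      if (!excluded) labels[[key]] <- 0L
    }
  }
  n_pos <- sum(unlist(labels) == 1L)
  n_neg <- sum(unlist(labels) == 0L)
  list(n_pos = n_pos, n_neg = n_neg, prior = n_pos / (n_pos + n_neg),
       labels = labels)
}
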