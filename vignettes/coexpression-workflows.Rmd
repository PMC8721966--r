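---
title: "Methods: benchmarking coexpression-network workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking coexpression-network workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexbench)
```

# The pipeline

`coexbench` builds one coexpression network per dataset by composing, in
this fixed order:

1. **within-sample normalization** — none, CPM, TPM, or RPKM;
2. **between-sample normalization** — none, quantile (QNT), TMM, upper
   quartile (UQ), or the counts-adjustment variants CTF/CUF;
3. **hyperbolic arcsine transformation** (always applied);
4. **pairwise correlation** across samples (Pearson by default,
   Spearman optionally);
5. **network transformation** — none, CLR, or weighted topological
   overlap (WTO).

TMM, UQ, CTF, and CUF estimate their scale factors from *raw counts*, so
they cannot follow a within-sample method; the package enforces this
through a units tag carried on every expression matrix, and workflow
enumeration respects it: 36 valid triples in total
(1 within-none × 6 between + 3 within × 2 between, × 3 transforms).

## Between-sample scale factors

The TMM factor for a sample is estimated against a reference sample (the
one whose 75th percentile of count/library-size is closest to the mean of
that statistic across samples). For genes with positive counts in both
samples, M (log2 fold change of library-size-normalized counts) and A
(mean log2 abundance) statistics are formed; genes are doubly trimmed —
the top and bottom 30% by M and 5% by A are removed, using rank
thresholds `floor(n · trim) + 1 … n + 1 − (floor(n · trim) + 1)` with
average ranks, so ties at the boundary are kept — and the factor is
`2^(Σ M/v / Σ 1/v)` where `v = (N_k − y_k)/(N_k y_k) + (N_r − y_r)/(N_r y_r)`
is the delta-method variance of M (each gene is weighted by its
*precision*, the reciprocal of its variance). Factors are then centered
to multiply to one by dividing by their geometric mean. The test suite
verifies this implementation to 1e-10 both against a straight-line
scalar-loop oracle and against `edgeR::calcNormFactors`.

UQ factors are the 75th percentile of each sample's counts (after
removing genes that are zero in *every* sample) divided by its library
size, then centered. Percentiles use linear interpolation between order
statistics (R's default type-7 definition); this choice is documented
because percentile dialects change UQ factors, and it is guarded by the
oracle tests.

TMM/UQ workflows multiply each library size by its factor and perform a
CPM-like division by this *effective library size*. CTF/CUF divide each
raw count by the factor directly, with no library-size division — the
two differ exactly by a per-sample multiplier `1e6 / N_k`, which matters
because the subsequent asinh transform is non-linear, so the resulting
correlations differ.

## Quantile normalization

QNT follows the sorted-column-means procedure: each value is replaced by
the mean across samples of the values at its rank. Ties receive the mean
of the rank-means at the tied positions (implemented by linear
interpolation at the average rank). QNT composes with counts, CPM, TPM,
or RPKM input; it is the only between-sample method that may follow a
within-sample method.

## The asinh transform

`asinh(x) = ln(x + √(x² + 1))` behaves like `log(2x)` for large x but
passes through zero smoothly, so no pseudocount is needed and small
counts are compressed less than a shifted log would. It is applied in
*every* workflow, including the plain Counts workflow, immediately
before correlation.

## Network transformations

**CLR** summarizes each gene's edge-weight distribution by its mean and
standard deviation, z-scores each edge against both endpoint
distributions with negative z-scores clipped to zero, and combines them
as `√(z_i(j)² + z_j(i)²)`. Conventions that had to be fixed: the moments
are taken over the `n − 1` off-diagonal weights of the gene, with the
*population* (divide-by-n) standard deviation; a gene with constant edge
weights (σ = 0) contributes z ≡ 0 with a warning. Both choices are
guarded by loop-based oracle tests.

**WTO** (sign variant) rescores each edge by the weighted neighborhood
the two genes share:
`ω_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − |a_ij|)` with
`k_i = Σ_u |a_iu|`. With signed correlations as input, ω can be
negative; we keep the signed output in `[−1, 1]` rather than clamping to
`[0, 1]`, since clamping would discard the sign information that the
signed variant exists to preserve. An `abs` variant is also provided.

Genes with zero variance across samples would make the correlation
undefined; they receive correlation 0 (with a message) so the network
stays total and every gold-standard pair remains evaluable.

# Evaluation

Only gold-standard pairs are scored; unlabeled network edges are
ignored, and standard pairs whose genes are absent from the network are
dropped and counted. Pairs are ranked by weight descending; tied weights
enter a single confusion row, which makes the sweep deterministic and
independent of input order. auPRC and auROC are trapezoidal integrals
over the sweep; the PR curve is anchored at recall 0 with the precision
of the highest-threshold row, and the ROC curve at (0, 0).
Precision-at-recall uses the first row whose recall reaches the level
(a step function, no interpolation).

`log2(auPRC/prior)` is the headline score: the auPRC of a random ranking
equals the prior in expectation, so the statistic is comparable across
gold standards with different positive fractions — a perfect ranking
scores `−log2(prior)`. One numerical caveat, visible in the calibration
test: with a *finite* standard the mean auPRC of random rankings sits
very slightly above the prior (the trapezoidal curve is computed from
small-count precisions at low recall). The calibration check therefore
uses a standard of a few thousand pairs, where this finite-sample offset
is well inside the 3-standard-error band of 200 replicates.

## Gold standards

Positives are all unordered pairs of genes co-annotated to at least one
"specific" GO Biological Process term, using experimental evidence codes
(EXP, IDA, IPI, IMP, IGI, TAS) plus curated IC; IEP (inferred from
expression) is always excluded to avoid circularity with coexpression,
and NOT-qualified records are dropped. Candidate negatives are the
remaining pairs among genes carrying at least one positive edge; a
candidate is left unlabeled when its genes are annotated to two
*different* specific terms whose gene sets overlap significantly
(hypergeometric upper tail, raw p < 0.05 — no multiple-testing
correction, mirroring a screening rather than inferential use), or when
the pair is co-annotated to a "general" term. Two conventions were open
and are fixed here: the hypergeometric universe is the number of
distinct genes with at least one retained BP annotation, and the overlap
screen considers *all* pairs of specific terms. Annotations are used as
given — no propagation up the GO graph is performed; the specific/general
term lists are user-supplied curation inputs.

A tissue-aware standard keeps positives only when both genes are in the
tissue's expressed gene set, and negatives when both are in-tissue or
one is in-tissue and the other is expressed in some other considered
tissue (the asymmetric rule keeps cross-tissue non-interactions
informative). Standards with fewer than 50 surviving positives are
rejected — signaled with a `NULL` return, not an error, so corpus-level
code can skip them.

# Workflow comparison

Per ordered workflow pair, scores are compared across shared datasets:
the win proportion (ties credited 0.5) and a one-sided paired Wilcoxon
signed-rank p-value. The "paired Wilcoxon" is implemented as the
signed-rank test: exact null when n ≤ 25 with no zero or tied-magnitude
differences, normal approximation with continuity correction otherwise;
zero differences are dropped and an all-zero difference vector yields
p = 1. Benjamini–Hochberg correction is applied across all ordered pairs
within one evaluation setting (one corpus × standard kind), and
significance is declared at FDR ≤ 0.01.

Method impact aggregates these comparisons per method: the proportion of
(workflow-with-method, workflow-without-method) ordered comparisons that
are significant wins. Two fairness exclusions keep the comparisons
balanced: workflows containing a within-sample method are excluded when
assessing between-sample methods, and workflows containing
TMM/UQ/CTF/CUF are excluded when assessing within-sample methods
(including the "none" level), because those combinations cannot
co-occur.

The experimental-factor covariates are: sample similarity (median
Spearman correlation over all sample pairs using the top 50% of genes by
variance — `ceiling(n/2)` genes, variance ties broken by order), read
count diversity (sample standard deviation, n − 1 denominator, of
per-sample count sums), and dataset binning into five contiguous
equal-size groups (remainder to the lowest bins, ties broken by dataset
ID for determinism).

The subsampling design draws, from every source dataset with at least 70
samples, ten random subsets at each of nine sizes
(5, 6, 7, 9, 11, 13, 16, 25, 40) without replacement. Each draw derives
its own sub-seed from the base seed and the (source, size, replicate)
key, so the design is reproducible and independent of iteration order.

# The synthetic corpus generator

The generator emulates the statistical structure the benchmark assumes:
overdispersed counts, heterogeneous sequencing depth, and functionally
coherent gene modules.

* Counts are negative binomial with variance `μ + φ μ²`; the dispersion
  default is φ = 0.2, a typical bulk RNA-seq scale.
* Per-gene baselines are log-normal (`meanlog = log 50`, `sdlog = 1.5`),
  giving the wide dynamic range of expression levels real data shows.
* Per-sample library factors are log-normal with `sdlog = 0.3` by
  default (moderate depth variation; raise it to stress between-sample
  normalization, as the README example does).
* Each of the default 5 modules of 10 genes shares a standard-normal
  latent activity per sample; a module gene's mean is multiplied by
  `exp(β · activity)` with β = 1.5 by default — the high-signal
  condition under which every workflow separates the planted modules,
  used by the acceptance checks. Background genes have β = 0.
* Gene lengths are uniform integers in 200–10,000 bp; sample metadata
  records an average read length (100 bp) and paired-end flag for the
  base-pair-count conversion path.

Modules are disjoint and their activities independent, so the implied
gold standard is unambiguous: within-module pairs are positives,
cross-module pairs negatives, background genes unlabeled, and the prior
is exactly `Σ C(m_i, 2) / C(Σ m_i, 2)` over module sizes — checked
exactly in the tests. Corpora share gene-level quantities (assignment,
baselines, lengths) across datasets while drawing samples independently;
tissues are assigned round-robin and each tissue's "expressed" gene set
is the union of its modules, which exercises the tissue-aware
subsetting rules.

What the generator does *not* emulate: batch effects and other
structured technical covariance, GC/length bias in counting,
isoform-level effects, correlated or overlapping modules, and asymmetric
global expression shifts. Passing tests on synthetic corpora therefore
demonstrate that the machinery is correct and the statistics calibrated,
not that any particular workflow ranking carries over to real tissue
compendia, where those factors drive much of the difficulty.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is stable: oracle
equivalence on ~100 random fixtures of ≤ 12 genes × ≤ 6 samples;
calibration with 200 random networks over a 3,160-pair standard; the
full 36-workflow benchmark on corpora of 60 genes × 100 samples; and the
subsampling design instantiated from 27 eligible synthetic sources
(27 × 9 × 10 = 2,430 subset specifications). Every stochastic step is
seeded; dataset- and draw-level sub-seeds are derived by hashing the
base seed with a stable key, and repeated runs produce byte-identical
edge lists and evaluation summaries.

# Known limitations

* VST/rlog count transformations and mutual-information CLR are out of
  scope; CLR here operates on correlation networks.
* The comparison statistics assume one score per (workflow, dataset);
  partially overlapping dataset sets are handled pairwise, which can
  make win proportions and p-values rest on different dataset subsets
  for different pairs.
* The WTO sign variant's negative outputs mean its weights are not
  directly interpretable as overlap fractions; rank-based evaluation is
  unaffected.
* `benchmark_corpus` recomputes scale factors per workflow rather than
  caching them; at desk scale this is negligible, for very large
  corpora a caching layer would help.
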