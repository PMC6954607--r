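---
title: "Selecting and evaluating RNA-seq reference genes with refpick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and evaluating RNA-seq reference genes with refpick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refpick)
```

## The problem

Count-based differential-expression tools estimate per-sample scaling
factors under the assumption that most genes do not change. When a
treatment perturbs a substantial share of the transcriptome — transgenic
effector lines, strong stress, tumours — that assumption fails, and
normalizing against genes *known to be stable in this very experiment*
becomes attractive. Pre-compiled housekeeping lists do not guarantee
stability in new conditions; `refpick` instead derives reference genes
from the data itself and provides independent stability diagnostics to
audit the choice.

## The selection model

Let `c_gj` be the read count of gene `g` in sample `j` and `L_g` the
gene's exonic length in base pairs.

**TPM.** `TPM_gj = 10^6 · (c_gj/L_g) / Σ_i (c_ij/L_i)`. Each sample column
sums to exactly $10^6$, removing library-size and length effects within a
sample. The default uses the plain annotated length; an optional effective
length `max(L_g − μ_frag + 1, 1)` is available through the `frag_len`
argument of `counts_to_tpm()` for libraries where the mean fragment length
is known and comparable to gene lengths. CV statistics are computed on
linear TPM, not log TPM, because the selection criterion targets relative
dispersion of the abundance estimate itself.

**Expression cutoff.** Weakly expressed genes carry mostly shot noise and
must not enter the CV ranking. The cutoff is found per sample, with no
tuning, from the shape of the log2 TPM distribution of detected genes
(zeros removed):

1. Sweep lower-quantile truncations `q = q0, q0 + 0.005, …, 0.50`, where
   `q0` is the fraction of values tied at the minimum rounded to two
   decimals. Quantiles use the linear-interpolation ("type 7") convention.
2. At each truncation cut `c_q`, refit the retained tail with a normal by
   maximum likelihood (sample mean/SD) and record the Kolmogorov–Smirnov
   statistic `D_q` between the tail's empirical CDF and the fit. While the
   weak mode is still included the tail is far from normal and `D_q` is
   large; `D_q` collapses once the cut passes the inter-mode valley.
   `D_q` is used as a raw distance, never as a test — the normal's
   parameters come from the same data, so its null distribution would be
   invalid anyway.
3. Fit `D_q` against `c_q` with a forward-stepwise piecewise-linear model:
   a base of intercept plus linear trend, then hinge pairs
   `(max(c − t, 0), max(t − c, 0))` with candidate knots `t` at the
   observed cuts, each step adding the pair that most reduces the residual
   sum of squares. Stepping stops when the relative RSS reduction falls
   below 0.005 or the design reaches 21 columns. The linear base term
   matters: it guarantees that an exactly linear trace retains no knots,
   so a featureless trace cannot produce a spurious cutoff.
4. The cutoff `κ_j` is the smallest knot above 0 (log2 TPM = 0, i.e. TPM
   = 1 — a natural floor, since on the TPM scale a large share of
   detected-but-negligible genes sits below 1). If no knot qualifies the
   sample falls back open (`κ_j = min(c_q)`, flag raised): silently
   discarding genes is worse than not filtering. A `min-interior`
   alternative rule is available for data whose expressed mode sits
   unusually low.

A gene is **active** when all its TPM values are positive and its mean
log2 TPM reaches the mean cutoff `κ̄` (boundary inclusive). The mean-vs-
mean aggregation is the least stringent defensible rule; the stricter
"above the sample's own cutoff in every sample" variant is exposed as
`rule = "per-sample"` and recorded in the output provenance, because the
aggregation choice is genuinely open and downstream users should see
which was used.

**Selection.** The `max(min_genes, round(f · n_active))` active genes with
the smallest CV (round half-up, CV ties broken by gene ID) form the
reference set. The default `f = 0.005` keeps the set small enough to be
credibly stable yet large enough (tens of genes on a typical
transcriptome) to anchor normalization across the expression range; the
`min_genes = 1` floor protects small active sets from rounding to zero.

## Stability diagnostics

**geNorm.** `V_ik` is the SD over samples (n−1 denominator) of
`log2 TPM_i − log2 TPM_k`; `M_i = mean_{k≠i} V_ik`. The stepwise ranking
repeatedly removes the gene with the largest `M` (ties: the
lexicographically first ID is removed, for determinism) until two genes —
inseparable by construction — remain. The pairwise-variation series
`V_{n,n+1}` is the SD of `log2(NF_n/NF_{n+1})` with `NF_n` the per-sample
geometric mean of the `n` best genes' linear TPM.

**NormFinder-style index.** Within each group the log2 expression is
decomposed as gene effect + sample effect + residual; the raw residual
variance `v_ig` (n_g − 1 denominator) is shrunk by the group's across-gene
mean, `σ̂²_ig = max(0, v_ig − mean_{i'}(v_{i'g})/(I−1))`. The inter-group
difference `d_ig = (x̄_i·g − x̄_i··) − (x̄_··g − x̄_···)` is shrunk with an
empirical-Bayes factor `γ_i = τ²/(τ² + mean_g(σ̂²_ig/n_g))`,
`τ² = max(0, var_g(d_ig) − mean_g(σ̂²_ig/n_g))`. Stability is
`ρ_i = mean_g(|γ_i d_ig| + √(σ̂²_ig/n_g))`; with one group,
`ρ_i = √σ̂²_i1`. This is a fixed, testable reconstruction of the
variance-decomposition-with-shrinkage family of stability indices; exact
numerical identity with any particular legacy implementation is not
claimed — the test suite pins the decomposition against an explicit-loop
ANOVA oracle, and the index is used for ordering and against the
conventional 0.5 suitability threshold. At least three candidate genes are
required (the shrinkage is undefined below that), and every group needs at
least two samples.

Both metrics run on log2 of linear TPM with **no pseudocount**: genes with
a zero in any sample are excluded from the log-based metrics (and reported
in the CV block only). A pseudocount would silently compress ratios for
exactly the low-expression genes whose stability is most overstated by it
— and a gene with dropouts cannot serve as a reference regardless.

**Control-gene size factors.** Median-of-ratios restricted to the
reference set: per usable reference (all counts positive) the
pseudo-reference is its geometric mean across samples; a sample's raw
factor is the median of its ratios; factors are rescaled to unit geometric
mean so factor sets from different reference choices are directly
comparable. References containing zeros are dropped and counted in the
output. The linear-scale median is used (for an odd number of usable
references it coincides with the log-scale median convention).

## The simulator

`simulate_counts()` emulates the structure of a two-genotype plant RNA-seq
comparison with four replicates per genotype:

* lengths log-uniform on [200, 10000] bp;
* a bimodal log2 base expression: a weakly-expressed mode N(−2, 1) holding
  30% of genes and an expressed mode N(5, 2);
* 100 planted stable genes drawn from the upper half of the expressed
  mode with dispersion $10^{-4}$ and zero fold change;
* 10% DE genes with |log2 FC| uniform on [0.5, 3], random sign — large
  enough to create the compositional shift that motivates control-gene
  normalization, without implying a wholesale transcriptome rewiring;
* background/noise dispersions uniform on [0.02, 0.3], i.e. biological
  CVs of roughly 14–55%, the range typical of replicated plant genotype
  experiments — a markedly cleaner background would let sampling noise
  alone mimic stability;
* sample size factors log-uniform on [0.5, 2] and negative-binomial counts
  (variance `μ + αμ²`) at an expected depth of 20 million fragments per
  sample.

What the simulator does *not* model: GC and positional bias, transcript-
level structure and isoform switching, correlated gene modules, batch
effects, and count over-dispersion heterogeneity along the mean. Passing
the planted-truth tests therefore shows the pipeline's internal logic is
sound under a faithful null model of its assumptions — not that selected
genes on real data are biologically validated references; the stability
diagnostics exist precisely to audit them there.

## Numerical choices and degenerate inputs

* The KS sweep requires ≥ 200 positive values per sample; traces need
  ≥ 10 points for the knot fit. Zero-variance truncation tails are
  skipped with a warning.
* Heavy truncation of even a perfectly unimodal normal drifts from its
  refitted normal (the KS distance approaches ~0.09 near the 50% cut), so
  the sweep's signal is the *interior peak-then-collapse* shape, not the
  absolute distance level; the knot fit responds to exactly that shape.
* When the weak mode holds close to half the genes the inter-mode valley
  collides with the q = 0.5 sweep cap and the sample falls back open
  rather than guessing a cutoff.
* Selection tie-breaks (equal CV) and geNorm removal ties are resolved by
  gene ID, making every output order-deterministic and row-permutation
  invariant.
* All pipeline stages are deterministic; only `simulate_counts()` consumes
  a seed.

## Problem sizes and validation

The test suite validates each stage against independent oracles: exact
rational arithmetic for TPM, two-pass mean/SD for CV, `ks.test` for the
sweep statistic, a double-loop pairwise oracle for geNorm, an explicit-loop
ANOVA oracle for the NormFinder-style decomposition, and the classic
all-gene median-of-ratios estimator for size factors. End-to-end checks run
the full pipeline on simulated datasets of 12,000 genes × 8 samples (the
study-design default) and recover ≥ 80% planted stable genes among the
selections, with every selected gene below the 0.5 stability threshold;
smaller simulations (50–4,000 genes) exercise I/O, invariants and
properties.
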