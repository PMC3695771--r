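---
title: "Semi-parallel association scans: models, approximations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parallel association scans: models, approximations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semigwas)
```

## The problem

A GWAS fits the same tiny regression model once per SNP — typically
10⁵–10⁷ times — and keeps only the SNP coefficient, its standard error and
the p-value. Calling a general-purpose model fitter in that loop spends
almost all of its time on per-call overhead and on re-factorizing a
covariate matrix that never changes. `semigwas` removes the loop: the
covariate structure is factorized once, and every per-SNP quantity for a
block of SNPs is produced by a handful of dense matrix products. The second
bottleneck, reading arbitrary SNP blocks from files that store one record
per individual, is removed by converting the data once into a SNP-major
container.

## Exact linear scans by residualization

With phenotype `y`, covariates `X` (n × (k+1), intercept included) and one
SNP dose vector `s`, the scan model is `y = βs + Xγ + ε`. By the
Frisch–Waugh–Lovell theorem the multiple-regression β equals the
simple-regression slope of the residualized variables

y\* = y − X(XᵀX)⁻¹Xᵀy,  s\* = s − X(XᵀX)⁻¹Xᵀs,

so for a block `S` of b SNP columns:

- β̂ = (S\*ᵀy\*) / colSums(S\*²) — one matrix–vector product,
- RSS = Σy\*² − β̂²·colSums(S\*²), σ̂² = RSS/(n−k−2),
- var(β̂) = σ̂² / colSums(S\*²).

The degrees of freedom n−k−2 count the intercept, the k covariates and the
SNP, even though the covariates were removed by projection.

Two numerical choices matter. First, the projection is computed through the
QR factorization of `X` (the residual is formed as `S − Q(QᵀS)` with the
economy Q), never via an explicit inverse of `XᵀX`: this is the standard
conditioning-safe route, and the right-to-left evaluation order guarantees
the largest intermediate is (k+1) × b — an n × n projection matrix is never
formed, which is what makes large n feasible. Second, RSS is obtained by
the cancellation-prone identity above; values in `[−10⁻⁸·Σy*², 0)` are
clamped to zero as roundoff, while larger negative values flag the SNP as
`failed` rather than silently producing a NaN.

Per-SNP covariate coefficients γ are a deliberate non-output: they are not
recoverable from the residualized scheme, and a scan does not report them.

### Degenerate inputs

- A SNP whose residualized column has `colSums(S*²) ≤ 10⁻¹²·n`
  (monomorphic, or collinear with the covariates) is flagged
  `monomorphic`; its estimates are withheld and the rest of the block is
  unaffected. No minor-allele-frequency filter is applied — flagging
  replaces filtering.
- An exact fit (RSS = 0) reports the exact slope with `se = 0` and
  `log10_p = −Inf` under status `ok`; this arises only in contrived data
  but wiping the estimate would hide a correct answer.
- A rank-deficient covariate matrix aborts the scan naming the offending
  columns; covariates are shared by all SNPs, so this is a data error, not
  a per-SNP condition.

## One-step logistic scans

Logistic regression has no closed form; maximum likelihood iterates
weighted least squares (IRLS) with weights `w = p(1−p)` that depend on the
coefficients. Since the weights would differ per SNP, exact
semi-parallelization is impossible. The package instead fits the
covariate-only null model once (hand-rolled IRLS; tolerance 10⁻⁸ on the
largest coefficient change, at most 25 iterations, zero start — ordinary
GLM practice) and takes, for every SNP, a single Fisher-scoring step from
`(γ̃, 0)` using the null weights w̃:

β̂₁ = Σ w̃ z\* s\* / Σ w̃ s\*²,  var(β̂₁) = 1 / Σ w̃ s\*²,

where `z* `and `s*` are the working response and SNP residualized against
`X` in the w̃ metric. `z*` does not depend on the SNP and is cached in the
null context. The weight "matrix" is held as a vector and only ever used as
an elementwise scale — materializing diag(w) would reintroduce the n × n
memory trap the projection order avoids. The one-step estimate is *exactly*
the SNP coordinate of one full-model Fisher-scoring update (the weighted
Frisch–Waugh–Lovell identity); the test suite verifies this to 10⁻¹⁰
against an independent implementation of the full update.

As an estimator of the fully iterated ML solution it is approximate, and
the approximation degrades with effect size. The package's bias study
quantifies this: 1000 simulated models, n = 2000, dose ~ Uniform(0, 2),
true OR ~ Uniform(1, 5) on the OR scale, intercept 0 (a balanced-prevalence
default, exposed as a parameter), `y ~ Bernoulli(expit(log(OR)·dose))`.
Each replicate is fitted by full ML and by the one-step estimator; the
relative difference of odds ratios is smoothed against the ML estimate with
a loess curve (span 0.5, a conventional default for reading a trend off a
scatter of this density). The smoothed underestimation is ≈0.1% at
OR = 1.33, ≈6% at OR = 3 and ≈17% at OR = 5, is ≈0 at OR = 1, nonnegative,
monotone increasing, and insensitive to the per-replicate sample size —
all reproduced by `scripts/acceptance.R` and the test suite at run time.
Since reported GWAS effects have a median OR near 1.33 and rarely exceed 3,
the one-step estimate is adequate for ranking and discovery; for the
handful of top hits, `refit_top_log10p` re-fits the full ML model, which is
cheap because it applies to few SNPs.

One-step Wald p-values use the normal reference with no df correction (the
large-sample convention); in the far tail they are slightly
anti-conservative relative to ML, visibly so only beyond −log₁₀p ≈ 25 —
far past genome-wide significance, where a hit is a hit either way.

## Storage

The container is a directory with a flat binary file of one unsigned byte
per (SNP, individual) cell in SNP-major order plus a JSON metadata sidecar
(dimensions, IDs, chunk shape, encoding). A dose d ∈ [0, 2] is stored as
round(100·d), so the round-trip error is at most 0.005 — far below the
noise of genotype imputation; 255 is the missing sentinel (doses only reach
200). Reading SNPs [a, b) for all n individuals is a single seek plus one
contiguous read of (b−a)·n bytes, so block access cost is independent of
where the block sits. Conversion from row-per-person text streams the input
in blocks of individuals (`chunk_individuals` rows at a time) and patches
the corresponding byte ranges of each SNP record, so the full matrix is
never in memory. This plain layout was chosen over an array-container
dependency: it needs nothing beyond base R connections, is byte-stable
across platforms, and the seek arithmetic *is* the chunking.

PLINK BED input decodes the 2-bit pairs least-significant-pair-first with
00→2, 10→1, 11→0 and 01→missing (in-memory code 3, the conventional raw
missing marker; sentinel 255 on disk). The published pair table fixes the
bit layout but which allele a file's A1 is remains a data-coding question,
so orientation is a flag (`allele_count = "a1"` default, `"a2"` flips) and
not an assumption.

## Missing data and QC

Individuals with missing phenotype or covariates are dropped from the whole
analysis (`complete_cases`). Missing genotypes cannot be handled by 0/1
weights without breaking the shared projection, so SNPs with call rate
below 0.95 are removed (the boundary is kept: a call rate of exactly 95%
passes) and the remainder are mean-imputed with the per-SNP observed mean
of the analyzed sample — computed after the complete-case subset so the
mean matches the individuals actually analyzed. Imputation never alters
observed entries. On a polygenic simulation (n = 2000, m = 500, per-SNP
effects N(0, 0.15²)) at 95% call rate, imputed-data estimates correlate
with complete-data estimates above 0.99 with no sign flips among
|t| > 4 SNPs. Under a pure null that correlation is mathematically capped
near √0.95 ≈ 0.975 (the estimates are then noise sharing 95% of their
terms), so the effect-spread design is the meaningful form of the check.

## What the simulator does and does not emulate

Genotypes are independent Uniform(0, 2) doses (maximal-entropy imputed
dosages) or Binomial(2, maf) hard calls; phenotypes and covariates are
independent standard normals; missingness is entry-wise independent. This
matches the cost structure and the error model the engines care about, and
it makes every test self-contained and exactly reproducible from a master
seed (per-replicate substreams are drawn from it). It does **not** emulate
linkage disequilibrium, allele-frequency spectra, population
stratification, relatedness, or informative missingness — so passing tests
demonstrate numerical correctness and calibration of the engines, not
robustness to confounding in real cohorts. Kinship/mixed-model correction
is explicitly out of scope.

## Problem sizes and performance

The test suite exercises the exactness claims at n = 500–2000 and
m = 200–2000 with k up to 30, and the bias study at its full 1000 × 2000
design — sizes at which the brute-force reference fitters remain usable as
oracles; the engines themselves scale linearly in n·m and are routinely
used far beyond that. Throughput is logged in Msips (millions of
SNP–individual pairs per second) as information only; it is
hardware-dependent and never asserted.

One honest caveat: historical comparisons of this algorithm family against
looping `lm()`/`glm()` report 60–300× speedups, but most of that gap is the
fitters' per-call interface overhead. Against an optimized closed-form
per-SNP solver (this package's own oracle) on a modern BLAS, the measured
advantage of the semi-parallel path at n = 2000, m = 2000, k = 10 is
roughly an order of magnitude — still decisive over a genome, but the
hundreds-fold figures should be read as comparisons against unoptimized
loops.

## Known limitations

- The logistic engine is a one-step approximation; for |log OR| large it
  biases toward zero (quantified above). Use `refit_top_log10p` for final
  effect sizes of top hits.
- Per-SNP weights (genotype uncertainty, case-control sampling weights) are
  incompatible with the shared projection and unsupported.
- Interaction terms, multi-SNP models, score/likelihood-ratio tests, Firth
  correction and genomic control are out of scope.
- The linear-scale `p` column underflows to 0 around |stat| ≳ 38;
  `log10_p` is the authoritative output.
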