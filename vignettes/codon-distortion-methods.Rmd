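---
title: "Methods: codon-usage-weighted distortion and phylogenetic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage-weighted distortion and phylogenetic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonDistortion)
```

# The distortion model

`codonDistortion` measures how badly a random point mutation is expected to
distort the physicochemical message of a proteome, given how the organism
actually uses codons. For a codon usage distribution $P(c_i)$ over the 61
sense codons, a mutation kernel $P(Y = c_j \mid X = c_i)$ and an amino-acid
cost matrix $d$, the expected distortion is

$$D = \sum_{i,j} P(c_i)\, P(Y = c_j \mid X = c_i)\, d(aa_i, aa_j),$$

with $d(aa_i, aa_j) = 0$ whenever $c_i$ and $c_j$ encode the same amino
acid. $D$ is a per-symbol expected cost: linear in both the usage
distribution and the mutation probability, so it composes predictably
(a mixture of usage profiles mixes the $D$ values, and halving $\mu$
exactly halves $D$).

## Cost matrices

$d(aa_i, aa_j) = (v_i - v_j)^2$, the squared difference of a property
scale, with an absolute-difference variant available via the `form`
argument. The squared form is the default because it is the convention of
the error-minimization literature this measure descends from. Four scales
ship with the package as plain TSV fixtures under `inst/extdata/`
(user-replaceable via `readPropertyScale()`):

| scale | source | units |
|---|---|---|
| `hydropathy` | Kyte & Doolittle (1982) | index, −4.5…4.5 |
| `polar_requirement` | Woese et al. (1966) | chromatographic index |
| `molecular_volume` | Grantham (1974) | Å³ |
| `isoelectric_point` | CRC Handbook pI values | pH units |

This quartet follows Haig & Hurst's (1991) genetic-code analysis. Their
exact numeric tables are not printed in most derived work, so the fixtures
are transcribed from the primary scale sources cited above; the resulting
$D$ values can only be validated against those sources and against the
package's independent brute-force oracle, not against any published
per-taxon table.

## The mutation kernel

The background mutation model is a minimal two-parameter (Kimura-style)
kernel over codons. Per replication event a codon stays intact with
probability $1-\mu$; with probability $\mu$ it suffers **exactly one**
single-nucleotide substitution. Conditional on a substitution, the event is
a transition with probability $\kappa/(1+\kappa)$ — spread uniformly over
the 3 transition neighbors — and a transversion with probability
$1/(1+\kappa)$, uniform over the 6 transversion neighbors. Codon pairs
differing at two or three positions get probability zero.

Choices worth making explicit:

* **Single-site events.** The model conditions on one substitution
  occurring; multi-hit events are second-order in $\mu$ and excluded by
  design, mirroring the two-parameter substitution model it invokes.
* **Uniform neighbor distributions.** No positional or context bias is
  assumed; uniformity is the minimal assumption consistent with defining
  $\kappa$ as a rate ratio, and it makes the off-diagonal transition share
  exactly $\kappa/(1+\kappa)$ — about 71% at the default $\kappa = 2.5$,
  the value typical of genome-wide/intronic ti/tv estimates that
  approximate mutation prior to selection.
* **$\mu = 1$ by default.** $D$ is linear in $\mu$, so between-taxon
  comparisons are unaffected by its value; $\mu = 1$ reports cost per
  mutation. $\mu$ stays configurable for anyone wanting cost per
  replication.
* **Mutations into stop codons** have no defined property cost. The
  default policy excludes them from the sum (they contribute 0), the
  common convention; `stopPolicy = "max_penalty"` instead charges the
  largest cost in the matrix as a nonsense penalty. The policy is recorded
  in every output table.

## Codon usage extraction

Usage is counted from CDS FASTA taking frame as given (position 1; no ORF
detection). Records whose length is not a multiple of 3 are skipped whole
and logged; in-frame triplets containing ambiguity codes are skipped
individually. U is mapped to T on read. Frequencies are defined over the
61 sense codons with stops excluded and renormalized — $d$ is an
amino-acid matrix, so stop codons cannot carry usage mass; their counts
are kept for diagnostics. GC-content is the G+C fraction of the retained
coding-region bases (ambiguity codes excluded from numerator and
denominator), and enters the regressions as a fraction (0–1), matching the
0.5 baseline convention used throughout.

# Phylogenetic generalized least squares

Each distortion measure is regressed on GC, temperature (°C), NaCl (w/V%)
and pH in a separate model. Residual covariance is Brownian:
$V_{ij}$ equals the branch length shared by the root-to-tip paths of tips
$i$ and $j$ (computed from the tree with `ape`). Estimation is exact GLS
by Cholesky whitening:

$$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y, \qquad
\hat\sigma^2 = \frac{e^\top V^{-1} e}{n - k}.$$

Conventions, chosen where the literature is not unanimous:

* **R².** The generalized $R^2$ against the GLS intercept-only null:
  $R^2 = 1 - (e^\top V^{-1} e) / ((y-\hat\mu_0\mathbf 1)^\top V^{-1}
  (y-\hat\mu_0\mathbf 1))$ with $\hat\mu_0$ the GLS mean. The model F is
  $(R^2/\mathrm{df_1})/((1-R^2)/\mathrm{df_2})$ with $\mathrm{df_1}$ the
  predictor count and $\mathrm{df_2} = n - k$. This is the caper-style
  convention.
* **Inference.** $\hat\sigma^2$ uses the $n-k$ (REML-flavoured) divisor;
  p-values are two-sided Student-t with $n-k$ df; the four models are
  reported without multiple-testing correction, as four separate a priori
  analyses.
* **Standardized coefficients** Z-transform response and predictors with
  the plain (unweighted) mean and standard deviation before refitting, so
  they absorb any affine rescaling of a predictor's units.
* **Degenerate trees.** If $V$ is numerically singular (duplicate tips,
  zero branch lengths), the diagonal gets a single jitter of
  $10^{-10}\,\mathrm{tr}(V)/n$; if that does not cure it the fit fails —
  degenerate trees are treated as data errors, not fitting problems.
  Polytomies are accepted as-is.
* **Branch-length transforms.** Only the plain Brownian correlation is
  implemented; Pagel-λ and similar transforms are a deliberate extension
  point, not a feature, since the plain Brownian model is the reference
  analysis here.

The implementation is validated three ways in the test suite: exact
agreement with OLS on star phylogenies (where $V \propto I$), exact
agreement with direct-matrix-inversion GLS on random 64-tip trees, and
agreement with `nlme::gls` under `ape::corBrownian`.

# The synthetic-data generator

No external data ship with the package; a fully seeded generator produces
study-shaped inputs instead. One master seed expands into fixed per-stage
substreams (tree, traits, usage, FASTA), so each stage is independently
reproducible.

1. **Tree.** A pure-birth (Yule) tree, rescaled to unit height so trait
   rates read directly as variance accrued from root to tip. Default 64
   tips — a realistic prokaryote panel size.
2. **Traits.** Each predictor evolves by Brownian motion from the
   mesophilic baseline (GC = 0.5, T = 30 °C, NaCl = 2.5 w/V%, pH = 7).
   Default root-to-tip standard deviations: 0.1 (GC fraction), 20 °C,
   3 w/V%, 1 pH unit — spreads that span mesophiles to moderate
   extremophiles without making extremes the norm. After simulation,
   traits are clamped to physical ranges (T ∈ [0, 110] °C, NaCl ∈ [0, 30],
   pH ∈ [4, 10], GC ∈ [0.05, 0.95]) and clamp events are counted; at the
   default rates clamping is rare.
3. **Codon usage.** The base sense-codon distribution is the product of
   per-position nucleotide probabilities with $P(G)=P(C)=\mathrm{gc}/2$,
   so GC is a genuine causal driver of composition. Each predictor then
   applies a log-linear tilt along *distortion axes*: the per-codon
   expected mutation cost under one scale at the reference kernel
   ($\kappa = 2.5$), residualized against the codon's G+C count (so
   environmental tilts cannot leak into realized GC) and standardized.
   Planted default effects: temperature tilts the hydropathy, volume and
   isoelectric axes (+0.04 per axis-SD per 10 °C), NaCl the polar and
   isoelectric axes (+0.08 per w/V%), pH the polar axis (+0.06 per unit),
   and GC the hydropathy axis (+0.04 per 0.1 GC) on top of its direct
   compositional effect. These sizes were fixed once, at
   generator-design time, to produce moderate, unmistakably directional
   effects — large enough to dominate sampling noise at the default codon
   sample, small enough that tilted distributions stay close to the base
   composition. Counts are drawn Dirichlet-multinomial (concentration
   5000) with 100 genes × 200 codons = 20 000 codons per taxon, emulating
   gene-to-gene and sampling heterogeneity.
4. **Files.** `writeScenario()` emits Newick, per-taxon CDS FASTA (genes
   sampled codon-by-codon from the tip profile, one stop appended each)
   and trait/manifest TSVs that the file pipeline consumes unchanged.

**What the generator does and does not emulate.** It produces phylogenetic
signal in predictors, GC-driven composition, environment-linked distortion
and realistic sampling noise. It does **not** emulate amino-acid-level
selection, expression-weighted codon usage, horizontal gene transfer,
sequence evolution along the tree, or the correlation structure of real
proteomes. Passing tests therefore demonstrate that the pipeline recovers
effects of the planted kind and calibrates correctly under its own
assumptions — not that any particular biological claim holds in real data.

# Numerical choices and test scale

* All distortion quantities are exact rational kernel weights times scale
  values, so the vectorized engine is required to match a naive
  triple-loop oracle to 1e−12 absolute (50 random profiles × 4 scales ×
  3 κ values in the suite).
* Kernel row-stochasticity and the transition share κ/(1+κ) are checked to
  1e−12 on a κ × μ grid; off-diagonal mass is summed directly rather than
  via 1 − diagonal, which would cancel catastrophically at small μ.
* GLS agreement with its oracles is required to 1e−10.
* Statistical properties use fixed-seed replicate batteries sized for
  stable verdicts at reasonable cost: type-I calibration with 200
  null replicates on 64-tip trees (each coefficient's rejection rate must
  sit inside the central 99.5% binomial band around 5%), sign recovery
  with 100 replicates of the default 64-taxon scenario (≥ 90% correct
  signs per planted effect), and κ-sweep stability on 3 scenarios across
  κ ∈ {2.5, 5, 7.5, 10} (no significant coefficient may flip sign).
* Ultrametric simulated trees make $V$ well-conditioned; the jitter path
  is exercised only by deliberately degenerate fixtures.

# Known limitations

* Only the standard genetic code is analyzed end-to-end; the code table is
  pluggable but alternative-code scoring (and the codon-usage feedback it
  would require) is out of scope.
* Usage is unweighted by expression; every CDS counts equally.
* The PGLS stage assumes the tree is known without error and branch
  lengths are meaningful; tree inference is upstream of this package.
* pH effects in the generator are weak by design, reflecting how narrow
  realistic pH optima ranges are; tests assert nothing about pH sign
  recovery.
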