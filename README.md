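# codonDistortion

Mutational robustness of the standard genetic code, weighted by the codon
usage of real (or simulated) organisms.

Classic error-minimization studies score the genetic code assuming codons
occur uniformly. Organisms do not use codons uniformly: GC-content and
adaptation to extreme environments (high temperature, high salinity,
unusual pH) reshape codon usage, and with it the *expected* severity of a
random point mutation. `codonDistortion` quantifies this with the
information-theoretic distortion

```
D = Σ_{i,j} P(c_i) · P(Y = c_j | X = c_i) · d(aa_i, aa_j)
```

where `P(c_i)` is the taxon's usage of sense codon `c_i`,
`P(Y = c_j | X = c_i)` a two-parameter background mutation kernel (a codon
mutates with probability μ, by a single-nucleotide change that is a
transition with probability κ/(1+κ)), and `d(aa_i, aa_j)` the squared
difference of an amino-acid property (zero for synonymous changes). Four
property scales — Kyte–Doolittle hydropathy, Woese polar requirement,
Grantham molecular volume, and isoelectric point — give four measures
`D_hyd`, `D_pol`, `D_vol`, `D_pI` per taxon. These are regressed on
GC-content and environmental optima (temperature, NaCl, pH) by phylogenetic
generalized least squares (PGLS) under a Brownian-motion covariance, so
that shared ancestry does not masquerade as an environmental effect.

The package is aimed at molecular evolution researchers studying
genetic-code optimality and codon usage: it provides the distortion engine,
the mutation kernel, codon-usage extraction from CDS FASTA, the PGLS stage,
and a fully seeded synthetic-data generator (Yule tree, Brownian traits,
codon usage with planted environmental effects) for validating the whole
pipeline without any external data.

## Worked example

Build the kernel at the main-analysis ti/tv ratio κ = 2.5, simulate a
64-taxon synthetic study, and fit the four PGLS models:

```r
library(codonDistortion)

kern <- buildMutationKernel(kappa = 2.5, mu = 1)
kern
#> MutationKernel: 64 x 64, kappa = 2.5, mu = 1 (transition share 0.7143)

sim  <- simulateScenario(syntheticScenario(nTips = 64, seed = 1))
ds   <- assembleComparativeData(sim, kappa = 2.5)
head(datasetTraits(ds), 3)
#>   taxon_id D_hyd D_pol D_vol  D_pI     gc temperature  nacl    ph
#> 1       t1 7.428 3.489  1985 3.879 0.5829      24.825 1.965 5.588
#> 2       t2 7.097 4.557  1880 4.426 0.5644       1.756 3.921 7.757
#> 3       t3 7.487 3.090  1953 3.305 0.6348      26.118 0.000 6.877

fits <- runFullAnalysis(ds)
fits$D_hyd
#> PGLS fit of D_hyd (n = 64)
#>   R2 = 0.753, F(4,59) = 44.858, p = 2.97e-17
#>          term    beta       se       t         p beta_std
#> 1 (Intercept) 4.63746 0.427776 10.8408 1.145e-15       NA
#> 2          gc 3.36988 0.490352  6.8724 4.447e-09  0.41860
#> 3 temperature 0.02585 0.002809  9.2029 5.253e-13  0.88446
#> 4        nacl 0.09245 0.015667  5.9012 1.886e-07  0.42825
#> 5          ph 0.01046 0.039610  0.2642 7.926e-01  0.02032
```

Reading the output: each row is one predictor of hydropathic distortion.
The positive, significant `temperature` and `gc` coefficients say that in
this simulated study hotter optima and GC-richer coding regions both come
with codon usages whose random mutations distort hydropathy more — exactly
the effects the generator planted; `ph` carries no planted hydropathy
effect and is correctly non-significant. `beta_std` are standardized
partial coefficients (all variables Z-transformed), comparable across
predictors. With 64 taxa every model reports the `F(4, 59)` shape: 4
predictors, 64 − 5 denominator degrees of freedom.

The same analysis runs file-to-file on FASTA + Newick + TSV inputs via
`pipelineSimulate()`, `pipelineDistortion()`, `pipelinePgls()` and
`pipelineSweep()` (or the `inst/scripts/codon_distortion.R` front end with
subcommands `simulate`, `distortion`, `pgls`, `sweep`).

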