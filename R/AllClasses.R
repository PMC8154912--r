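#' @import methods
#' @importFrom stats pf pt rgamma rmultinom rnorm sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

setOldClass("phylo")

#' PropertyScale: an amino-acid physicochemical property scale
#'
#' Maps each of the 20 canonical amino acids (1-letter IUPAC code) to a real
#' number in the scale's native units, e.g. Kyte-Doolittle hydropathy or
#' Woese polar requirement.
#'
#' @slot name scale identifier, e.g. \code{"hydropathy"}.
#' @slot values named numeric vector over the 20 canonical amino acids.
#' @exportClass PropertyScale
setClass("PropertyScale",
  representation(name = "character", values = "numeric"))

setValidity("PropertyScale", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  aa <- names(object@values)
  missing_aa <- setdiff(AMINO_ACIDS, aa)
  if (length(missing_aa))
    msg <- c(msg, paste0("scale misses amino acids: ",
                         paste(missing_aa, collapse = ", ")))
  extra <- setdiff(aa, AMINO_ACIDS)
  if (length(extra))
    msg <- c(msg, paste0("unknown amino acids: ", paste(extra, collapse = ", ")))
  if (anyNA(object@values))
    msg <- c(msg, "scale contains missing values")
  if (length(msg)) msg else TRUE
})

#' DistortionMatrix: pairwise amino-acid substitution costs
#'
#' Symmetric non-negative cost matrix d(aa_i, aa_j) derived from one
#' property scale; zero on the diagonal so that synonymous codon changes
#' cost nothing.
#'
#' @slot d 20 x 20 named numeric matrix of costs.
#' @slot scaleName name of the property scale the costs derive from.
#' @slot form \code{"squared"} or \code{"absolute"} difference of scale values.
#' @exportClass DistortionMatrix
setClass("DistortionMatrix",
  representation(d = "matrix", scaleName = "character", form = "character"))

setValidity("DistortionMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (!is.numeric(d) || nrow(d) != ncol(d))
    msg <- c(msg, "d must be a square numeric matrix")
  if (!identical(rownames(d), colnames(d)))
    msg <- c(msg, "row and column names must agree")
  if (any(d < 0)) msg <- c(msg, "costs must be non-negative")
  if (any(abs(diag(d)) > 0)) msg <- c(msg, "diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-12) msg <- c(msg, "d must be symmetric")
  if (!object@form %in% c("squared", "absolute"))
    msg <- c(msg, "form must be 'squared' or 'absolute'")
  if (length(msg)) msg else TRUE
})

#' MutationKernel: codon-level background mutation model
#'
#' A 64 x 64 row-stochastic matrix of conditional probabilities
#' P(Y = c_j | X = c_i) under a two-parameter mutation model: a codon either
#' stays intact (probability 1 - mu) or suffers exactly one single-nucleotide
#' substitution, which is a transition with probability kappa/(1+kappa) and a
#' transversion otherwise.
#'
#' @slot prob 64 x 64 numeric matrix with codon dimnames.
#' @slot kappa transition/transversion rate ratio (> 0).
#' @slot mu per-codon mutation probability in (0, 1].
#' @exportClass MutationKernel
setClass("MutationKernel",
  representation(prob = "matrix", kappa = "numeric", mu = "numeric"))

setValidity("MutationKernel", function(object) {
  msg <- character()
  q <- object@prob
  if (!all(dim(q) == c(64L, 64L)))
    msg <- c(msg, "kernel must be 64 x 64")
  if (!identical(rownames(q), CODONS) || !identical(colnames(q), CODONS))
    msg <- c(msg, "dimnames must be the 64 codons in lexicographic order")
  if (any(q < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (max(abs(rowSums(q) - 1)) > 1e-12)
    msg <- c(msg, "rows must sum to 1")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be positive")
  if (object@mu <= 0 || object@mu > 1) msg <- c(msg, "mu must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CodonUsageProfile: per-taxon codon usage and GC-content
#'
#' Holds raw in-frame codon counts over all 64 codons, the codon usage
#' distribution P(c_i) over the 61 sense codons (stop codons excluded and
#' the rest renormalized), the GC fraction of the coding region, and a
#' record of how many sequences contributed.
#'
#' @slot taxonId taxon identifier.
#' @slot counts named numeric vector of counts over all 64 codons.
#' @slot freq named numeric vector of frequencies over the 61 sense codons.
#' @slot gc GC fraction in [0, 1].
#' @slot nUsed number of sequences that contributed codons.
#' @slot nSkipped number of sequences skipped (length not a multiple of 3).
#' @exportClass CodonUsageProfile
setClass("CodonUsageProfile",
  representation(taxonId = "character", counts = "numeric", freq = "numeric",
                 gc = "numeric", nUsed = "integer", nSkipped = "integer"))

setValidity("CodonUsageProfile", function(object) {
  msg <- character()
  if (!identical(names(object@counts), CODONS))
    msg <- c(msg, "counts must cover the 64 codons in lexicographic order")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@freq) != 61L)
    msg <- c(msg, "freq must cover the 61 sense codons")
  if (any(object@freq < 0)) msg <- c(msg, "frequencies must be non-negative")
  if (abs(sum(object@freq) - 1) > 1e-12)
    msg <- c(msg, "frequencies must sum to 1")
  if (object@gc < 0 || object@gc > 1) msg <- c(msg, "gc must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ComparativeDataset: phylogeny plus tip traits for PGLS
#'
#' Couples a rooted tree with per-tip records of the four distortion
#' responses and the four predictors (GC fraction, optimal growth
#' temperature in degrees C, optimal NaCl concentration in w/V%, optimal pH).
#' Tip labels and trait taxon ids must be in bijection.
#'
#' @slot tree an \code{ape::phylo} rooted tree with branch lengths.
#' @slot traits data.frame with column \code{taxon_id} plus numeric trait
#'   columns; rows are matched to tips by \code{taxon_id}.
#' @exportClass ComparativeDataset
setClass("ComparativeDataset",
  representation(tree = "phylo", traits = "data.frame"))

setValidity("ComparativeDataset", function(object) {
  msg <- character()
  tr <- object@tree
  if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    msg <- c(msg, "tree must have non-negative branch lengths")
  if (!"taxon_id" %in% names(object@traits))
    msg <- c(msg, "traits must have a taxon_id column")
  else {
    ids <- object@traits$taxon_id
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate taxon_id in traits")
    if (!setequal(ids, tr$tip.label))
      msg <- c(msg, "tip labels and trait taxon_ids must be in bijection")
  }
  if (length(msg)) msg else TRUE
})

#' PGLSResult: one fitted phylogenetic regression
#'
#' @slot response name of the response variable.
#' @slot coefficients data.frame with columns term, beta, se, t, p, beta_std.
#' @slot r2 generalized R-squared against the GLS intercept-only null.
#' @slot fstat model F statistic.
#' @slot df1,df2 numerator / denominator degrees of freedom.
#' @slot pModel model p-value from the F distribution.
#' @slot sigma2 GLS residual variance estimate.
#' @slot n number of tips used.
#' @exportClass PGLSResult
setClass("PGLSResult",
  representation(response = "character", coefficients = "data.frame",
                 r2 = "numeric", fstat = "numeric", df1 = "integer",
                 df2 = "integer", pModel = "numeric", sigma2 = "numeric",
                 n = "integer"))

#' SyntheticScenario: parameters of the synthetic-data generator
#'
#' Describes a complete synthetic study: a Yule tree, Brownian-evolving
#' environmental traits around a mesophilic baseline
#' (GC = 0.5, T = 30 degrees C, NaCl = 2.5 w/V%, pH = 7), and per-taxon codon
#' usage whose composition responds to GC and to planted environmental
#' effects.
#'
#' @slot nTips number of tips (>= 4).
#' @slot seed integer seed; expanded into per-stage substreams.
#' @slot birthRate Yule speciation rate.
#' @slot traitBaseline named numeric: gc, temperature, nacl, ph.
#' @slot traitRates named numeric Brownian variances accrued over the
#'   unit-height tree, same names as \code{traitBaseline}.
#' @slot effectSizes named list: for each environmental predictor, a named
#'   numeric vector of log-linear tilt coefficients on the distortion axes
#'   (\code{hyd}, \code{pol}, \code{vol}, \code{pI}).
#' @slot noiseConcentration Dirichlet-multinomial concentration of the codon
#'   usage sampling noise.
#' @slot genesPerTaxon,geneLengthCodons size of the emitted CDS set.
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(nTips = "integer", seed = "integer", birthRate = "numeric",
                 traitBaseline = "numeric", traitRates = "numeric",
                 effectSizes = "list", noiseConcentration = "numeric",
                 genesPerTaxon = "integer", geneLengthCodons = "integer"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@nTips < 4L) msg <- c(msg, "nTips must be >= 4")
  if (object@birthRate <= 0) msg <- c(msg, "birthRate must be positive")
  need <- c("gc", "temperature", "nacl", "ph")
  if (!all(need %in% names(object@traitBaseline)))
    msg <- c(msg, "traitBaseline must name gc, temperature, nacl, ph")
  if (!all(need %in% names(object@traitRates)))
    msg <- c(msg, "traitRates must name gc, temperature, nacl, ph")
  if (any(object@traitRates < 0)) msg <- c(msg, "trait rates must be >= 0")
  if (object@noiseConcentration <= 0)
    msg <- c(msg, "noiseConcentration must be positive")
  if (object@geneLengthCodons < 2L)
    msg <- c(msg, "geneLengthCodons must be >= 2")
  if (object@genesPerTaxon < 1L) msg <- c(msg, "genesPerTaxon must be >= 1")
  if (length(msg)) msg else TRUE
})
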