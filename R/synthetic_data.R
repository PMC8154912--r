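# Synthetic study generator: Yule tree, Brownian environmental traits around
# a mesophilic baseline, and codon usage whose composition responds to
# GC-content and to planted environmental effects.
#
# The generator exists to exercise the pipeline end to end: GC drives the
# per-position nucleotide composition of codons, and each environmental
# predictor applies a log-linear tilt along a "distortion axis" - the
# standardized per-codon mutational vulnerability under one property scale -
# so that planted effects propagate to the distortion measures with
# controllable sign and size.

# deterministic substream seeds (< 2^31) so stages are independently
# reproducible from one scenario seed
.substreamSeed <- function(seed, stage, index = 0L) {
  stage_code <- c(tree = 1L, traits = 2L, usage = 3L, fasta = 4L)[[stage]]
  as.integer((as.numeric(seed) * 48271 + stage_code * 7919 + index * 104729)
             %% 2147483629)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param nTips number of tips, >= 4.
#' @param birthRate speciation rate of the Yule process.
#' @param seed integer seed; the same seed gives an identical tree.
#' @param unitHeight if TRUE (default) branch lengths are rescaled so the
#'   tree height is 1, making trait rates read as variance accrued from root
#'   to tip.
#' @return a rooted \code{ape::phylo} with \code{nTips} labeled tips and
#'   positive branch lengths.
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1L, unitHeight = TRUE) {
  if (!is.numeric(nTips) || nTips < 4L) stop("nTips must be >= 4")
  if (birthRate <= 0) stop("birthRate must be positive")
  set.seed(.substreamSeed(seed, "tree"))
  tree <- ape::rphylo(as.integer(nTips), birth = birthRate, death = 0)
  if (unitHeight) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  tree
}

#' Simulate Brownian environmental traits on a tree
#'
#' Each trait evolves by Brownian motion from its baseline: tip values are
#' multivariate normal with mean the baseline and covariance rate * V, where
#' V is the shared-path (Brownian) matrix of the tree. After simulation,
#' traits are clamped to their physical ranges (temperature to [0, 110]
#' degrees C, NaCl to [0, 30] w/V%, pH to [4, 10], GC to [0.05, 0.95]) and
#' the number of clamped values is recorded in the \code{"nClamped"}
#' attribute.
#'
#' @param tree a rooted \code{ape::phylo} with branch lengths.
#' @param baseline named numeric of trait baselines; default the mesophilic
#'   reference point GC = 0.5, T = 30 degrees C, NaCl = 2.5 w/V%, pH = 7.
#' @param rates named numeric Brownian variances per unit branch length,
#'   same names as \code{baseline}.
#' @param seed integer seed.
#' @return data.frame with \code{taxon_id} plus one column per trait, rows
#'   ordered as \code{tree$tip.label}; attribute \code{nClamped}.
#' @export
simulateTraits <- function(tree,
                           baseline = c(gc = 0.5, temperature = 30,
                                        nacl = 2.5, ph = 7),
                           rates = c(gc = 0.01, temperature = 400,
                                     nacl = 9, ph = 1),
                           seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!all(names(baseline) %in% names(rates)))
    stop("rates must be named like baseline")
  if (any(rates < 0)) stop("negative trait rates are invalid")
  V <- ape::vcv.phylo(tree)
  n <- nrow(V)
  set.seed(.substreamSeed(seed, "traits"))
  out <- data.frame(taxon_id = tree$tip.label, stringsAsFactors = FALSE)
  n_clamped <- 0L
  bounds <- list(temperature = c(0, 110), nacl = c(0, 30), ph = c(4, 10),
                 gc = c(0.05, 0.95))
  for (tr in names(baseline)) {
    rate <- rates[[tr]]
    x <- if (rate == 0) rep(baseline[[tr]], n) else {
      R <- chol(rate * V + diag(1e-12 * rate * mean(diag(V)), n))
      baseline[[tr]] + as.vector(crossprod(R, rnorm(n)))
    }
    if (tr %in% names(bounds)) {
      b <- bounds[[tr]]
      clamped <- x < b[1] | x > b[2]
      n_clamped <- n_clamped + sum(clamped)
      x <- pmin(pmax(x, b[1]), b[2])
    }
    out[[tr]] <- x
  }
  attr(out, "nClamped") <- n_clamped
  out
}

#' Distortion axes: standardized per-codon mutational vulnerability
#'
#' For each property scale, the vulnerability of sense codon i is its
#' expected cost under one round of mutation, sum_j q(i, j) d(aa_i, aa_j)
#' at the reference kernel. Axes are residualized against the codon's G+C
#' count (so tilting along an axis does not move realized GC) and
#' standardized to mean 0, sd 1 across the 61 sense codons.
#'
#' @param kappa reference ti/tv ratio of the vulnerability kernel.
#' @param scales named list of [PropertyScale-class]; default built-ins.
#' @param code genetic code.
#' @return 61 x n_scales matrix, rows named by sense codon, columns
#'   \code{hyd}, \code{pol}, \code{vol}, \code{pI}.
#' @export
distortionAxes <- function(kappa = 2.5, scales = builtinScales(),
                           code = standardGeneticCode()) {
  sense <- senseCodons(code)
  kern <- buildMutationKernel(kappa, mu = 1)
  q <- kernelProb(kern)[sense, , drop = FALSE]
  gc_count <- vapply(strsplit(sense, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  axes <- vapply(scales, function(sc) {
    dm <- buildDistortionMatrix(sc, code)
    w <- rowSums(q * .codonCostMatrix(dm, code, "exclude"))
    r <- stats::residuals(stats::lm(w ~ gc_count))
    as.vector(scale(r))
  }, numeric(length(sense)))
  rownames(axes) <- sense
  colnames(axes) <- .scaleAbbrev(names(scales))
  axes
}

#' Default planted effect sizes
#'
#' Log-linear tilt coefficients per distortion axis and per unit of scaled
#' predictor deviation (GC in units of 0.1 from 0.5, temperature in units of
#' 10 degrees C from 30, NaCl in w/V% from 2.5, pH in units from 7):
#' positive temperature effects on the hydropathy, volume and isoelectric
#' axes, positive NaCl effects on the polar and isoelectric axes, a weaker
#' positive pH effect on the polar axis, and a positive GC effect on the
#' hydropathy axis (on top of GC's direct compositional effect on the base
#' codon distribution).
#'
#' @return named list of named numeric vectors.
#' @export
defaultEffectSizes <- function() {
  list(gc = c(hyd = 0.04),
       temperature = c(hyd = 0.04, vol = 0.04, pI = 0.04),
       nacl = c(pol = 0.08, pI = 0.08),
       ph = c(pol = 0.06))
}

# scaled deviation of each predictor from the baseline
.predictorDeviation <- function(gc, temperature, nacl, ph) {
  c(gc = (gc - 0.5) / 0.1,
    temperature = (temperature - 30) / 10,
    nacl = nacl - 2.5,
    ph = ph - 7)
}

#' Synthesize a codon usage profile from GC and environment
#'
#' The base sense-codon distribution is the product of per-position
#' nucleotide probabilities with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2, renormalized over sense codons. Each
#' environmental predictor then applies a log-linear tilt along its
#' distortion axes, scaled by its deviation from the mesophilic baseline and
#' the planted effect size. Counts are drawn from a Dirichlet-multinomial
#' with the given concentration.
#'
#' @param gc GC fraction in (0, 1).
#' @param temperature,nacl,ph environmental optima.
#' @param effectSizes named list as in [defaultEffectSizes()].
#' @param noiseConcentration Dirichlet concentration of sampling noise;
#'   \code{Inf} gives exact multinomial sampling of the tilted distribution.
#' @param nCodons number of codons drawn.
#' @param seed integer seed.
#' @param taxonId identifier stored in the profile.
#' @param axes distortion axes from [distortionAxes()]; precompute when
#'   generating many taxa.
#' @return a [CodonUsageProfile-class] (GC slot is the realized GC of the
#'   sampled codons).
#' @export
synthesizeUsage <- function(gc, temperature = 30, nacl = 2.5, ph = 7,
                            effectSizes = defaultEffectSizes(),
                            noiseConcentration = 5000, nCodons = 20000L,
                            seed = 1L, taxonId = "taxon",
                            axes = distortionAxes()) {
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("gc must be strictly inside (0, 1)")
  pi0 <- .baseSenseDistribution(gc)
  tilt <- numeric(length(pi0))
  dev <- .predictorDeviation(gc, temperature, nacl, ph)
  for (pred in names(effectSizes)) {
    eff <- effectSizes[[pred]]
    for (ax in names(eff))
      tilt <- tilt + eff[[ax]] * dev[[pred]] * axes[, ax]
  }
  pi_tilted <- pi0 * exp(tilt)
  pi_tilted <- pi_tilted / sum(pi_tilted)
  set.seed(.substreamSeed(seed, "usage"))
  p <- if (is.finite(noiseConcentration)) {
    g <- rgamma(length(pi_tilted), shape = noiseConcentration * pi_tilted)
    if (sum(g) == 0) pi_tilted else g / sum(g)
  } else pi_tilted
  counts <- as.vector(rmultinom(1, size = nCodons, prob = p))
  names(counts) <- names(pi_tilted)
  usageFromCounts(counts, taxonId = taxonId)
}

# base distribution over the 61 sense codons from independent per-position
# nucleotide probabilities driven by GC
.baseSenseDistribution <- function(gc, code = standardGeneticCode()) {
  p_nt <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sense <- senseCodons(code)
  p <- vapply(strsplit(sense, ""), function(b) prod(p_nt[b]), numeric(1))
  setNames(p / sum(p), sense)
}

#' Construct a synthetic scenario
#'
#' @param nTips number of taxa; default 64, a realistic prokaryote panel.
#' @param seed master seed expanded into per-stage substreams.
#' @param birthRate Yule speciation rate.
#' @param traitBaseline,traitRates see [simulateTraits()].
#' @param effectSizes see [defaultEffectSizes()].
#' @param noiseConcentration Dirichlet-multinomial concentration.
#' @param genesPerTaxon,geneLengthCodons size of the emitted CDS set; the
#'   product (default 100 x 200 = 20000 codons) sets the codon sample size
#'   per taxon.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nTips = 64L, seed = 1L, birthRate = 1,
                              traitBaseline = c(gc = 0.5, temperature = 30,
                                                nacl = 2.5, ph = 7),
                              traitRates = c(gc = 0.01, temperature = 400,
                                             nacl = 9, ph = 1),
                              effectSizes = defaultEffectSizes(),
                              noiseConcentration = 5000,
                              genesPerTaxon = 100L,
                              geneLengthCodons = 200L) {
  new("SyntheticScenario", nTips = as.integer(nTips), seed = as.integer(seed),
      birthRate = birthRate, traitBaseline = traitBaseline,
      traitRates = traitRates, effectSizes = effectSizes,
      noiseConcentration = noiseConcentration,
      genesPerTaxon = as.integer(genesPerTaxon),
      geneLengthCodons = as.integer(geneLengthCodons))
}

#' Simulate a scenario in memory
#'
#' Runs the three generator stages: Yule tree, Brownian traits, and one
#' codon usage profile per tip (sample size genesPerTaxon x
#' geneLengthCodons codons).
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with \code{tree}, \code{traits} (simulated environmental
#'   values) and \code{profiles} (list of [CodonUsageProfile-class] keyed by
#'   taxon).
#' @export
simulateScenario <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  tree <- simulateTree(scenario@nTips, scenario@birthRate, scenario@seed)
  traits <- simulateTraits(tree, scenario@traitBaseline, scenario@traitRates,
                           scenario@seed)
  axes <- distortionAxes()
  n_codons <- scenario@genesPerTaxon * scenario@geneLengthCodons
  profiles <- lapply(seq_len(nrow(traits)), function(i) {
    synthesizeUsage(gc = traits$gc[i], temperature = traits$temperature[i],
                    nacl = traits$nacl[i], ph = traits$ph[i],
                    effectSizes = scenario@effectSizes,
                    noiseConcentration = scenario@noiseConcentration,
                    nCodons = n_codons,
                    seed = .substreamSeed(scenario@seed, "usage", i),
                    taxonId = traits$taxon_id[i], axes = axes)
  })
  names(profiles) <- traits$taxon_id
  list(tree = tree, traits = traits, profiles = profiles)
}

#' Assemble the comparative dataset of a simulated scenario
#'
#' Computes the four-scale distortion panel for every tip profile at the
#' given kernel and joins it with the environmental traits. The GC predictor
#' is the realized GC of each profile (what the sequence pipeline would
#' measure), not the latent simulated value.
#'
#' @param sim result of [simulateScenario()].
#' @param kappa,mu kernel parameters.
#' @param scales,stopPolicy passed to [distortionPanel()].
#' @return a [ComparativeDataset-class] ready for [runFullAnalysis()].
#' @export
assembleComparativeData <- function(sim, kappa = 2.5, mu = 1,
                                    scales = builtinScales(),
                                    stopPolicy = "exclude") {
  kern <- buildMutationKernel(kappa, mu)
  panels <- do.call(rbind, lapply(sim$profiles, distortionPanel,
                                  kernel = kern, scales = scales,
                                  stopPolicy = stopPolicy))
  traits <- sim$traits
  traits$gc <- vapply(sim$profiles[traits$taxon_id], profileGc, numeric(1))
  merged <- merge(panels[, c("taxon_id", "D_hyd", "D_pol", "D_vol", "D_pI")],
                  traits, by = "taxon_id")
  comparativeDataset(sim$tree, merged)
}

#' Write a scenario to disk
#'
#' Emits a complete input set consumed unchanged by the file pipeline: a
#' Newick tree, one CDS FASTA per taxon (genes sampled codon-by-codon from
#' the tip's usage profile, one stop codon appended per gene), a trait TSV
#' and a FASTA manifest TSV.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory; created if missing.
#' @return invisibly, list of written paths (\code{tree}, \code{traits},
#'   \code{manifest}, \code{fasta}).
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  sim <- simulateScenario(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(sim$tree, file = tree_path)
  traits_path <- file.path(dir, "traits.tsv")
  .writeTsvAtomic(sim$traits, traits_path)
  fasta_dir <- file.path(dir, "cds")
  dir.create(fasta_dir, showWarnings = FALSE)
  stops <- names(standardGeneticCode())[standardGeneticCode() == STOP]
  fasta_paths <- character(0)
  for (i in seq_along(sim$profiles)) {
    prof <- sim$profiles[[i]]
    id <- taxonId(prof)
    set.seed(.substreamSeed(scenario@seed, "fasta", i))
    p <- codonFreq(prof)
    genes <- vapply(seq_len(scenario@genesPerTaxon), function(g) {
      body <- sample(names(p), scenario@geneLengthCodons - 1L,
                     replace = TRUE, prob = p)
      paste0(paste(body, collapse = ""), sample(stops, 1L))
    }, character(1))
    fa <- Biostrings::DNAStringSet(setNames(genes,
      paste0(id, "_gene", seq_along(genes))))
    path <- file.path(fasta_dir, paste0(id, ".fasta"))
    Biostrings::writeXStringSet(fa, path)
    fasta_paths <- c(fasta_paths, path)
  }
  manifest <- data.frame(taxon_id = names(sim$profiles),
                         fasta = fasta_paths, stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  .writeTsvAtomic(manifest, manifest_path)
  invisible(list(tree = tree_path, traits = traits_path,
                 manifest = manifest_path, fasta = fasta_paths))
}
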