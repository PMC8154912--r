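test_that("Yule trees have the requested tips and are seed-deterministic", {
  tr <- simulateTree(8, 1.0, seed = 7)
  expect_identical(ape::Ntip(tr), 8L)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  tr2 <- simulateTree(8, 1.0, seed = 7)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_false(identical(ape::write.tree(simulateTree(8, 1.0, seed = 8)),
                         ape::write.tree(tr)))
  tr64 <- simulateTree(64, 1.0, seed = 1)
  expect_identical(ape::Ntip(tr64), 64L)
  expect_equal(max(ape::node.depth.edgelength(tr64)), 1)  # unit height
  expect_error(simulateTree(3), ">= 4")
  expect_error(simulateTree(8, birthRate = 0), "positive")
})

test_that("zero-rate traits sit exactly at the baseline", {
  tr <- simulateTree(8, seed = 2)
  tt <- simulateTraits(tr, rates = c(gc = 0, temperature = 0, nacl = 0,
                                     ph = 0), seed = 2)
  expect_true(all(tt$gc == 0.5))
  expect_true(all(tt$temperature == 30))
  expect_true(all(tt$nacl == 2.5))
  expect_true(all(tt$ph == 7))
  expect_identical(tt$taxon_id, tr$tip.label)
})

test_that("Brownian trait variance and cherry covariance match the tree", {
  # fixed 2-tip cherry of depth 1 with shared depth 0.6
  tr <- ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1);")
  rate <- 9
  vals <- vapply(1:500, function(r) {
    tt <- simulateTraits(tr, baseline = c(temperature = 30),
                         rates = c(temperature = rate), seed = 5000 + r)
    tt$temperature[match(c("A", "B"), tt$taxon_id)]
  }, numeric(2))
  v_emp <- apply(vals, 1, var)
  expect_lt(abs(v_emp[1] - rate) / rate, 0.15)
  cov_emp <- cov(vals[1, ], vals[2, ])
  V <- brownianCovariance(tr)
  expect_lt(abs(cov_emp - rate * V["A", "B"]) / (rate * V["A", "B"]), 0.25)
})

test_that("trait clamping respects the physical ranges", {
  tr <- simulateTree(32, seed = 5)
  tt <- simulateTraits(tr, rates = c(gc = 0.5, temperature = 1e4,
                                     nacl = 500, ph = 50), seed = 5)
  expect_true(all(tt$ph >= 4 & tt$ph <= 10))
  expect_true(all(tt$nacl >= 0 & tt$nacl <= 30))
  expect_true(all(tt$temperature >= 0 & tt$temperature <= 110))
  expect_true(all(tt$gc >= 0.05 & tt$gc <= 0.95))
  expect_gt(attr(tt, "nClamped"), 0)
  expect_error(simulateTraits(tr, rates = c(gc = -1, temperature = 0,
                                            nacl = 0, ph = 0)), "negative")
})

test_that("neutral parameters reproduce the GC-driven base distribution", {
  # no effects, no noise: expected usage is the renormalized product
  # distribution with all nucleotides at 1/4
  prof <- synthesizeUsage(gc = 0.5, effectSizes = list(),
                          noiseConcentration = Inf, nCodons = 2e6L, seed = 3)
  p <- codonFreq(prof)
  expect_true(all(abs(p - 1 / 61) < 4 * sqrt((1 / 61) / 2e6)))
  expect_error(synthesizeUsage(gc = 0), "gc")
  expect_error(synthesizeUsage(gc = 1), "gc")
})

test_that("realized GC of sampled codons tracks the input GC", {
  for (g in c(0.35, 0.5, 0.65)) {
    prof <- synthesizeUsage(gc = g, effectSizes = list(),
                            noiseConcentration = Inf, nCodons = 1e5L,
                            seed = 11)
    # sense-codon renormalization biases realized GC slightly; allow 0.02
    expect_lt(abs(profileGc(prof) - g), 0.02)
  }
})

test_that("planted temperature effects raise hydropathic distortion", {
  axes <- distortionAxes()
  k <- buildMutationKernel(2.5, 1)
  D_at <- function(temp, r)
    distortionPanel(synthesizeUsage(0.5, temperature = temp,
                                    noiseConcentration = 5000,
                                    nCodons = 20000L, seed = 1000 + r,
                                    axes = axes),
                    k)$D_hyd
  hot <- vapply(1:30, function(r) D_at(80, r), numeric(1))
  cold <- vapply(1:30, function(r) D_at(30, r), numeric(1))
  expect_gt(mean(hot), mean(cold))
})

test_that("scenario simulation is fully seed-deterministic", {
  s1 <- simulateScenario(syntheticScenario(nTips = 8, seed = 42))
  s2 <- simulateScenario(syntheticScenario(nTips = 8, seed = 42))
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_equal(s1$traits, s2$traits)
  expect_equal(codonCounts(s1$profiles[[3]]), codonCounts(s2$profiles[[3]]))
  s3 <- simulateScenario(syntheticScenario(nTips = 8, seed = 43))
  expect_false(identical(codonCounts(s1$profiles[[1]]),
                         codonCounts(s3$profiles[[1]])))
})

test_that("written scenarios are complete and round-trip through the readers", {
  dir <- withr::local_tempdir()
  scen <- syntheticScenario(nTips = 8, seed = 9, genesPerTaxon = 50L,
                            geneLengthCodons = 50L)
  paths <- writeScenario(scen, dir)
  expect_true(file.exists(paths$tree))
  expect_true(file.exists(paths$traits))
  expect_length(paths$fasta, 8L)
  tr <- ape::read.tree(paths$tree)
  expect_identical(ape::Ntip(tr), 8L)
  traits <- readTraitTable(paths$traits)
  expect_identical(nrow(traits), 8L)
  expect_setequal(traits$taxon_id, tr$tip.label)
  # every gene is a codon multiple ending in a stop
  fa <- readCdsFasta(paths$fasta[1])
  expect_true(all(Biostrings::width(fa) %% 3 == 0))
  stops <- c("TAA", "TAG", "TGA")
  last <- substring(as.character(fa), Biostrings::width(fa) - 2,
                    Biostrings::width(fa))
  expect_true(all(last %in% stops))
  # same seed gives byte-identical files
  dir2 <- withr::local_tempdir()
  writeScenario(scen, dir2)
  expect_identical(readLines(file.path(dir2, "tree.nwk")),
                   readLines(paths$tree))
  expect_identical(readLines(file.path(dir2, "cds", basename(paths$fasta[1]))),
                   readLines(paths$fasta[1]))
})

test_that("emitted FASTA recovers the generating profile", {
  dir <- withr::local_tempdir()
  # 600 genes x 170 codons > 1e5 codons: sampling error should be tiny
  scen <- syntheticScenario(nTips = 4, seed = 77, genesPerTaxon = 600L,
                            geneLengthCodons = 170L)
  paths <- writeScenario(scen, dir)
  sim <- simulateScenario(scen)
  man <- read.delim(paths$manifest, stringsAsFactors = FALSE)
  prof_back <- codonUsageFromFasta(man$fasta[1], taxonId = man$taxon_id[1])
  p_gen <- codonFreq(sim$profiles[[man$taxon_id[1]]])
  expect_gt(cor(codonFreq(prof_back), p_gen), 0.99)
})
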