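# Compact show() methods for the S4 containers.

setMethod("show", "PropertyScale", function(object) {
  v <- object@values
  cat("PropertyScale '", object@name, "': 20 amino acids, range [",
      format(min(v)), ", ", format(max(v)), "]\n", sep = "")
})

setMethod("show", "DistortionMatrix", function(object) {
  cat("DistortionMatrix (", object@form, " difference) from scale '",
      object@scaleName, "'\n  max cost ", format(max(object@d)), "\n",
      sep = "")
})

setMethod("show", "MutationKernel", function(object) {
  cat("MutationKernel: 64 x 64, kappa = ", format(object@kappa),
      ", mu = ", format(object@mu),
      " (transition share ", format(round(object@kappa / (1 + object@kappa), 4)),
      ")\n", sep = "")
})

setMethod("show", "CodonUsageProfile", function(object) {
  cat("CodonUsageProfile '", object@taxonId, "': ",
      format(sum(object@counts)), " codons, GC = ",
      format(round(object@gc, 4)), ", sequences used/skipped = ",
      object@nUsed, "/", object@nSkipped, "\n", sep = "")
})

setMethod("show", "ComparativeDataset", function(object) {
  cat("ComparativeDataset: ", ape::Ntip(object@tree), " tips, traits: ",
      paste(setdiff(names(object@traits), "taxon_id"), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "PGLSResult", function(object) {
  cat("PGLS fit of ", object@response, " (n = ", object@n, ")\n",
      "  R2 = ", format(round(object@r2, 3)),
      ", F(", object@df1, ",", object@df2, ") = ",
      format(round(object@fstat, 3)),
      ", p = ", format(object@pModel, digits = 3), "\n", sep = "")
  print(object@coefficients, digits = 4)
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario: ", object@nTips, " tips, seed ", object@seed,
      ", ", object@genesPerTaxon, " genes x ", object@geneLengthCodons,
      " codons per taxon\n", sep = "")
})
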