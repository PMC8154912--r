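# Expected distortion: codon-usage-weighted average physicochemical cost of
# one round of background mutation,
#   D = sum_{i,j} P(c_i) P(Y = c_j | X = c_i) d(aa_i, aa_j),
# with P over the 61 sense codons and d the property-scale cost matrix
# (zero for synonymous changes).

#' Expected distortion of a codon usage profile
#'
#' Computes D for one profile, kernel and distortion matrix. The sum runs
#' over sense source codons weighted by usage; mutations into stop codons
#' have no defined amino-acid cost and are handled by \code{stopPolicy}:
#' \code{"exclude"} (default) lets them contribute 0, \code{"max_penalty"}
#' charges the largest cost present in the distortion matrix as a nonsense
#' penalty.
#'
#' @param profile a [CodonUsageProfile-class].
#' @param kernel a [MutationKernel-class].
#' @param dmat a [DistortionMatrix-class].
#' @param code genetic code shared by all inputs.
#' @param stopPolicy \code{"exclude"} or \code{"max_penalty"}.
#' @return non-negative scalar D in the scale's native squared units
#'   (or native units for absolute-difference matrices).
#' @examples
#' prof <- usageFromCounts(c(AAA = 3, ATG = 1))
#' dm <- buildDistortionMatrix(builtinScales("hydropathy")[[1]])
#' expectedDistortion(prof, buildMutationKernel(2.5), dm)
#' @export
expectedDistortion <- function(profile, kernel, dmat,
                               code = standardGeneticCode(),
                               stopPolicy = c("exclude", "max_penalty")) {
  stopPolicy <- match.arg(stopPolicy)
  stopifnot(is(profile, "CodonUsageProfile"), is(kernel, "MutationKernel"),
            is(dmat, "DistortionMatrix"))
  sense <- senseCodons(code)
  p <- codonFreq(profile)
  if (!identical(names(p), sense))
    stop("profile and genetic code disagree on the sense codons")
  cost <- .codonCostMatrix(dmat, code, stopPolicy)
  q <- kernelProb(kernel)[sense, , drop = FALSE]
  sum(p * rowSums(q * cost))
}

# codon-level 61 x 64 cost matrix: rows sense source codons, columns all
# target codons; stop targets get 0 (exclude) or max(d) (max_penalty)
.codonCostMatrix <- function(dmat, code, stopPolicy) {
  sense <- senseCodons(code)
  d <- distortionCost(dmat)
  aa_from <- code[sense]
  cost <- matrix(0, length(sense), 64L, dimnames = list(sense, CODONS))
  target_sense <- code[CODONS] != STOP
  cost[, target_sense] <- d[aa_from, code[CODONS[target_sense]]]
  if (stopPolicy == "max_penalty")
    cost[, !target_sense] <- max(d)
  cost
}

#' Four-scale distortion panel for one taxon
#'
#' Computes expected distortion once per property scale, yielding the four
#' measures D_hyd, D_pol, D_vol, D_pI for one codon usage profile.
#'
#' @param profile a [CodonUsageProfile-class].
#' @param kernel a [MutationKernel-class].
#' @param scales named list of [PropertyScale-class] objects; default the
#'   four built-in scales.
#' @param code genetic code.
#' @param stopPolicy passed to [expectedDistortion()].
#' @param form distortion matrix functional form, see
#'   [buildDistortionMatrix()].
#' @return one-row data.frame: taxon_id, kappa, mu, D_hyd, D_pol, D_vol,
#'   D_pI, stop_policy.
#' @export
distortionPanel <- function(profile, kernel, scales = builtinScales(),
                            code = standardGeneticCode(),
                            stopPolicy = c("exclude", "max_penalty"),
                            form = c("squared", "absolute")) {
  stopPolicy <- match.arg(stopPolicy)
  form <- match.arg(form)
  dmats <- lapply(scales, buildDistortionMatrix, code = code, form = form)
  D <- vapply(dmats, function(dm)
    expectedDistortion(profile, kernel, dm, code, stopPolicy), numeric(1))
  out <- data.frame(taxon_id = taxonId(profile),
                    kappa = kernelKappa(kernel), mu = kernelMu(kernel),
                    stringsAsFactors = FALSE)
  out[paste0("D_", .scaleAbbrev(names(scales)))] <- as.list(unname(D))
  out$stop_policy <- stopPolicy
  out
}

.scaleAbbrev <- function(names) {
  ab <- c(hydropathy = "hyd", polar_requirement = "pol",
          molecular_volume = "vol", isoelectric_point = "pI")
  out <- unname(ab[names])
  out[is.na(out)] <- names[is.na(out)]
  out
}

#' Distortion across a range of ti/tv ratios
#'
#' Recomputes the distortion panel for each kappa with mu held fixed, to
#' probe how sensitive the measures are to the assumed transition bias.
#'
#' @param profile a [CodonUsageProfile-class].
#' @param kappaValues positive ti/tv ratios; default the 2.5-10 sweep.
#' @param scales,code,stopPolicy,form as in [distortionPanel()].
#' @param mu mutation probability held fixed across the sweep.
#' @return data.frame with one row per kappa, ordered by kappa.
#' @export
kappaSweep <- function(profile, kappaValues = c(2.5, 5, 7.5, 10),
                       scales = builtinScales(),
                       code = standardGeneticCode(),
                       stopPolicy = c("exclude", "max_penalty"),
                       form = c("squared", "absolute"), mu = 1) {
  if (length(kappaValues) == 0L) stop("kappaValues must be non-empty")
  if (any(!is.finite(kappaValues)) || any(kappaValues <= 0))
    stop("all kappa values must be positive and finite")
  stopPolicy <- match.arg(stopPolicy)
  form <- match.arg(form)
  kappaValues <- sort(kappaValues)
  rows <- lapply(kappaValues, function(k)
    distortionPanel(profile, buildMutationKernel(k, mu), scales, code,
                    stopPolicy, form))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
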