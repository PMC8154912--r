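# Two-parameter (kappa, mu) background mutation model over codons.
#
# A codon keeps its identity with probability 1 - mu. With probability mu it
# suffers exactly one single-nucleotide substitution; the event is a
# transition with probability kappa/(1+kappa) and a transversion with
# probability 1/(1+kappa), spread uniformly over the 3 transition and 6
# transversion neighbors respectively. Codon pairs differing at more than
# one position have probability zero.

#' Build the codon mutation kernel
#'
#' @param kappa transition/transversion rate ratio, > 0. The main-analysis
#'   default is 2.5, at which roughly 71\% of mutations are transitions.
#' @param mu per-codon mutation probability in (0, 1]. Expected distortion is
#'   linear in \code{mu}, so for between-taxon comparison its value is
#'   immaterial; the default 1 puts distortion on the per-mutation scale.
#' @return a [MutationKernel-class] with a 64 x 64 row-stochastic matrix.
#' @examples
#' k <- buildMutationKernel(kappa = 2.5)
#' kernelProb(k)["AAA", "GAA"]   # (2.5/3.5) * (1/3)
#' transitionMassFraction(k)     # 2.5/3.5, about 0.714
#' @export
buildMutationKernel <- function(kappa = 2.5, mu = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0)
    stop("kappa must be a single positive number")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) ||
      mu <= 0 || mu > 1)
    stop("mu must be a single number in (0, 1]")
  q <- matrix(0, 64L, 64L, dimnames = list(CODONS, CODONS))
  p_ti <- mu * kappa / (1 + kappa) / 3  # per transition neighbor
  p_tv <- mu * 1 / (1 + kappa) / 6     # per transversion neighbor
  for (ci in CODONS) {
    nb <- singleNtNeighbors(ci)
    is_ti <- nb$class == "transition"
    q[ci, nb$codon[is_ti]] <- p_ti
    q[ci, nb$codon[!is_ti]] <- p_tv
  }
  diag(q) <- 1 - mu
  new("MutationKernel", prob = q, kappa = kappa, mu = mu)
}

#' Conditional probability matrix of a kernel
#' @param x a [MutationKernel-class].
#' @return 64 x 64 named numeric matrix, rows = source codon.
#' @export
kernelProb <- function(x) {
  stopifnot(is(x, "MutationKernel"))
  x@prob
}

#' Kernel parameters
#' @param x a [MutationKernel-class].
#' @return numeric scalar.
#' @rdname kernelParams
#' @export
kernelKappa <- function(x) {
  stopifnot(is(x, "MutationKernel"))
  x@kappa
}

#' @rdname kernelParams
#' @export
kernelMu <- function(x) {
  stopifnot(is(x, "MutationKernel"))
  x@mu
}

#' Fraction of mutation probability mass on transitions
#'
#' For any source codon, the off-diagonal probability mass assigned to
#' transition-class changes divided by the total off-diagonal mass. Under
#' this model the fraction is identical across codons and equals
#' kappa / (1 + kappa): about 0.714 at kappa = 2.5.
#'
#' @param kernel a [MutationKernel-class].
#' @return a number in (0, 1).
#' @export
transitionMassFraction <- function(kernel) {
  stopifnot(is(kernel, "MutationKernel"))
  q <- kernelProb(kernel)
  fractions <- vapply(CODONS, function(ci) {
    nb <- singleNtNeighbors(ci)
    ti <- sum(q[ci, nb$codon[nb$class == "transition"]])
    # sum the off-diagonal entries directly: subtracting the diagonal from
    # the row total cancels catastrophically at small mu
    off <- sum(q[ci, setdiff(CODONS, ci)])
    ti / off
  }, numeric(1))
  if (diff(range(fractions)) > 1e-12)
    stop("transition fraction unexpectedly varies across codons")
  unname(fractions[1])
}

#' Write a kernel as a labeled TSV matrix
#'
#' Exports the 64 x 64 conditional probability matrix with codon row and
#' column labels, for inspection and external cross-checks.
#'
#' @param kernel a [MutationKernel-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeKernelTsv <- function(kernel, path) {
  q <- kernelProb(kernel)
  df <- data.frame(codon = rownames(q), q, check.names = FALSE)
  .writeTsvAtomic(df, path)
}
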