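# Genetic code, substitution classes, property scales, distortion matrices.

NUCLEOTIDES <- c("A", "C", "G", "T")
PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' The 64 codons in lexicographic (A < C < G < T) order
#' @keywords internal
CODONS <- as.vector(outer(outer(NUCLEOTIDES, NUCLEOTIDES,
                                function(a, b) paste0(a, b)),
                          NUCLEOTIDES, paste0))
CODONS <- sort(CODONS)

#' The 20 canonical amino acids, 1-letter IUPAC codes
#' @keywords internal
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Symbol used for stop codons in the code table
#' @export
STOP <- "*"

#' The standard genetic code
#'
#' Returns the standard (NCBI translation table 1) genetic code as a named
#' character vector mapping each of the 64 codons to a 1-letter amino acid,
#' with stop codons (TAA, TAG, TGA) mapped to \code{STOP} (\code{"*"}).
#' Codons are ordered lexicographically over A < C < G < T.
#'
#' @return named character vector of length 64.
#' @examples
#' code <- standardGeneticCode()
#' code[["ATG"]]           # "M"
#' sum(code != STOP)       # 61 sense codons
#' @export
standardGeneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  code <- setNames(as.character(gc[CODONS]), CODONS)
  stopifnot(!anyNA(code), sum(code == STOP) == 3L)
  code
}

#' Sense codons of a genetic code
#'
#' @param code a genetic code as returned by [standardGeneticCode()].
#' @return character vector of codons that encode an amino acid.
#' @export
senseCodons <- function(code = standardGeneticCode()) {
  names(code)[code != STOP]
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purines (A, G) or pyrimidines (C, T); the remaining
#' eight ordered base pairs are transversions.
#'
#' @param from,to single nucleotides in \code{A, C, G, T}; must differ.
#' @return \code{"transition"} or \code{"transversion"}.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("A", "C")  # transversion
#' @export
classifySubstitution <- function(from, to) {
  if (!is.character(from) || !is.character(to) ||
      length(from) != 1L || length(to) != 1L ||
      !(from %in% NUCLEOTIDES) || !(to %in% NUCLEOTIDES))
    stop("'from' and 'to' must be single nucleotides in {A, C, G, T}")
  if (from == to)
    stop("identical bases do not form a substitution")
  same_class <- (from %in% PURINES) == (to %in% PURINES)
  if (same_class) "transition" else "transversion"
}

#' Single-nucleotide neighbors of a codon
#'
#' Enumerates the 9 codons reachable by exactly one base substitution
#' (3 positions x 3 alternative bases). For every codon exactly 3 neighbors
#' are transitions and 6 are transversions.
#'
#' @param codon a length-3 string over \code{A, C, G, T}.
#' @return data.frame with columns \code{codon}, \code{position},
#'   \code{class} (\code{transition}/\code{transversion}).
#' @examples
#' nb <- singleNtNeighbors("AAA")
#' table(nb$class)   # 3 transitions, 6 transversions
#' @export
singleNtNeighbors <- function(codon) {
  bases <- .checkCodon(codon)
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(NUCLEOTIDES, bases[pos])) {
      nb <- bases
      nb[pos] <- alt
      k <- k + 1L
      out[[k]] <- data.frame(
        codon = paste(nb, collapse = ""),
        position = pos,
        class = classifySubstitution(bases[pos], alt),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.checkCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("codon must be a single length-3 string")
  bases <- strsplit(codon, "")[[1]]
  if (!all(bases %in% NUCLEOTIDES))
    stop("codon must be composed of A, C, G, T: ", codon)
  bases
}

#' Construct a PropertyScale
#'
#' @param name scale identifier.
#' @param values named numeric vector over the 20 canonical amino acids.
#' @return a [PropertyScale-class] object.
#' @export
propertyScale <- function(name, values) {
  new("PropertyScale", name = name, values = values[order(names(values))])
}

#' Read a property scale from a two-column TSV
#'
#' The file has columns \code{aa} (1-letter amino acid) and \code{value};
#' lines starting with \code{#} are comments. This is also the format the
#' built-in scales are shipped in, so user-supplied scales are drop-in
#' replacements.
#'
#' @param path TSV file path.
#' @param name scale identifier; default the file base name.
#' @return a [PropertyScale-class] object.
#' @export
readPropertyScale <- function(path, name = sub("\\.tsv$", "", basename(path))) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("aa", "value") %in% names(tab)))
    stop("scale file must have columns 'aa' and 'value': ", path)
  propertyScale(name, setNames(as.numeric(tab$value), tab$aa))
}

#' The four built-in amino-acid property scales
#'
#' Loads the polar requirement (Woese), hydropathy (Kyte-Doolittle),
#' molecular volume (Grantham) and isoelectric point scales shipped with the
#' package, the classic quartet of genetic-code error-cost studies.
#'
#' @param which subset of scale names; default all four.
#' @return named list of [PropertyScale-class] objects in the order
#'   hydropathy, polar_requirement, molecular_volume, isoelectric_point.
#' @export
builtinScales <- function(which = c("hydropathy", "polar_requirement",
                                    "molecular_volume", "isoelectric_point")) {
  which <- match.arg(which, several.ok = TRUE)
  out <- lapply(which, function(w) {
    path <- system.file("extdata", paste0(w, ".tsv"),
                        package = "codonDistortion", mustWork = TRUE)
    readPropertyScale(path, name = w)
  })
  setNames(out, which)
}

#' Build a distortion matrix from a property scale
#'
#' The cost of mistaking amino acid i for amino acid j is the squared
#' (default) or absolute difference of their property values. Synonymous
#' pairs (i = j) cost zero by construction; the matrix is symmetric and
#' non-negative.
#'
#' @param scale a [PropertyScale-class].
#' @param code a genetic code; used to check scale coverage.
#' @param form \code{"squared"} (default) or \code{"absolute"} difference.
#' @return a [DistortionMatrix-class].
#' @examples
#' dm <- buildDistortionMatrix(builtinScales("hydropathy")[[1]])
#' distortionCost(dm)["A", "V"]   # (1.8 - 4.2)^2
#' @export
buildDistortionMatrix <- function(scale, code = standardGeneticCode(),
                                  form = c("squared", "absolute")) {
  form <- match.arg(form)
  stopifnot(is(scale, "PropertyScale"))
  used <- unique(code[code != STOP])
  missing_aa <- setdiff(used, names(scale@values))
  if (length(missing_aa))
    stop("property scale '", scale@name, "' misses amino acids: ",
         paste(missing_aa, collapse = ", "))
  v <- scale@values[AMINO_ACIDS]
  diff <- outer(v, v, "-")
  d <- if (form == "squared") diff^2 else abs(diff)
  dimnames(d) <- list(AMINO_ACIDS, AMINO_ACIDS)
  new("DistortionMatrix", d = d, scaleName = scale@name, form = form)
}

#' Pairwise amino-acid costs of a DistortionMatrix
#' @param x a [DistortionMatrix-class].
#' @return 20 x 20 named numeric matrix.
#' @export
distortionCost <- function(x) {
  stopifnot(is(x, "DistortionMatrix"))
  x@d
}

#' Values of a PropertyScale
#' @param x a [PropertyScale-class].
#' @return named numeric vector over the 20 amino acids.
#' @export
scaleValues <- function(x) {
  stopifnot(is(x, "PropertyScale"))
  x@values
}

#' Name of a PropertyScale or DistortionMatrix
#' @param x a [PropertyScale-class] or [DistortionMatrix-class].
#' @return character scalar.
#' @export
scaleName <- function(x) {
  if (is(x, "PropertyScale")) x@name
  else if (is(x, "DistortionMatrix")) x@scaleName
  else stop("no scale name for class ", class(x))
}
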