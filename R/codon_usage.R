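# Codon usage and GC-content extraction from CDS sequences.
#
# Reading policy: frame is taken as position 1 of each record; records whose
# length is not a multiple of 3 are skipped entirely; within retained
# records, codons containing non-ACGT symbols are skipped individually.
# RNA input (U) is mapped to T on read.

#' Read CDS sequences from a FASTA file
#'
#' Reads nucleotide sequences, uppercases them and maps U to T so RNA input
#' is handled transparently. Ambiguity codes are kept and dealt with by the
#' counting policy.
#'
#' @param path FASTA file path.
#' @return a \code{Biostrings::DNAStringSet}.
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  Biostrings::DNAStringSet(setNames(toupper(seqs), names(raw)))
}

#' Count in-frame codons over a CDS sequence set
#'
#' Each record whose length is a multiple of 3 contributes its in-frame
#' codons; in-frame triplets containing non-ACGT symbols are skipped
#' individually. Records with length not divisible by 3 are skipped entirely
#' and counted in the skip log.
#'
#' @param records a \code{Biostrings::DNAStringSet} (or character vector) of
#'   CDS sequences.
#' @return list with \code{counts} (named numeric over the 64 codons),
#'   \code{nUsed}, \code{nSkipped}.
#' @examples
#' countCodons(c("ATGAAATAA"))$counts[c("ATG", "AAA", "TAA")]
#' @export
countCodons <- function(records) {
  records <- .asDNAStringSet(records)
  if (length(records) == 0L) stop("empty CDS sequence set")
  in_frame <- Biostrings::width(records) %% 3L == 0L &
    Biostrings::width(records) > 0L
  kept <- records[in_frame]
  counts <- setNames(numeric(64L), CODONS)
  if (length(kept)) {
    # step = 3 walks the reading frame; triplets with ambiguity codes fall
    # into no ACGT bin, which implements the per-codon skip policy
    m <- Biostrings::oligonucleotideFrequency(kept, width = 3L, step = 3L)
    tot <- colSums(m)
    counts[names(tot)] <- tot
  }
  list(counts = counts,
       nUsed = sum(in_frame),
       nSkipped = sum(!in_frame))
}

.asDNAStringSet <- function(records) {
  if (is(records, "DNAStringSet")) return(records)
  if (is.character(records)) {
    seqs <- chartr("u", "t", tolower(records))
    return(Biostrings::DNAStringSet(toupper(seqs)))
  }
  stop("records must be a DNAStringSet or character vector")
}

#' Codon usage distribution from codon counts
#'
#' Restricts counts to the sense codons of the code and renormalizes them to
#' sum to 1. Stop-codon counts are retained in the profile's count vector
#' for diagnostics but carry no frequency, since stop codons have no
#' amino-acid property value.
#'
#' @param counts named numeric vector of codon counts (the 64 codons, or a
#'   subset; missing codons count 0).
#' @param code a genetic code, default the standard code.
#' @param taxonId taxon identifier stored in the profile.
#' @param gc GC fraction to store; default recomputed from the counts'
#'   nucleotide composition.
#' @param nUsed,nSkipped sequence bookkeeping carried into the profile.
#' @return a [CodonUsageProfile-class].
#' @export
usageFromCounts <- function(counts, code = standardGeneticCode(),
                            taxonId = "taxon", gc = NULL,
                            nUsed = 0L, nSkipped = 0L) {
  full <- setNames(numeric(64L), CODONS)
  unknown <- setdiff(names(counts), CODONS)
  if (length(unknown))
    stop("unknown codons in counts: ", paste(unknown, collapse = ", "))
  full[names(counts)] <- counts
  sense <- senseCodons(code)
  total <- sum(full[sense])
  if (total <= 0) stop("no sense-codon counts: cannot form a usage profile")
  freq <- full[sense] / total
  if (is.null(gc)) gc <- .gcFromCodonCounts(full)
  new("CodonUsageProfile", taxonId = taxonId, counts = full, freq = freq,
      gc = gc, nUsed = as.integer(nUsed), nSkipped = as.integer(nSkipped))
}

.gcFromCodonCounts <- function(counts) {
  per_base <- vapply(strsplit(CODONS, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  sum(counts * per_base) / (3 * sum(counts))
}

#' GC-content of a CDS sequence set
#'
#' (#G + #C) / (#A + #C + #G + #T) over all bases of the records; ambiguous
#' symbols are excluded from both numerator and denominator.
#'
#' @param records a \code{Biostrings::DNAStringSet} or character vector.
#' @return GC fraction in [0, 1].
#' @examples
#' gcContent("ATGC")  # 0.5
#' @export
gcContent <- function(records) {
  records <- .asDNAStringSet(records)
  if (length(records) == 0L) stop("empty CDS sequence set")
  lf <- Biostrings::letterFrequency(records, letters = c("A", "C", "G", "T"))
  tot <- sum(lf)
  if (tot == 0) stop("no unambiguous A/C/G/T bases in input")
  sum(lf[, c("C", "G")]) / tot
}

#' Codon usage profile straight from a FASTA file
#'
#' Convenience wrapper: read CDS, count in-frame codons, compute GC over the
#' retained (in-frame) records, and build the profile.
#'
#' @param path FASTA file path.
#' @param taxonId taxon identifier; default the file base name.
#' @param code genetic code.
#' @return a [CodonUsageProfile-class].
#' @export
codonUsageFromFasta <- function(path, taxonId = sub("\\.(fa|fasta|fna)$", "",
                                                    basename(path)),
                                code = standardGeneticCode()) {
  records <- readCdsFasta(path)
  cc <- countCodons(records)
  retained <- records[Biostrings::width(records) %% 3L == 0L &
                        Biostrings::width(records) > 0L]
  usageFromCounts(cc$counts, code = code, taxonId = taxonId,
                  gc = gcContent(retained),
                  nUsed = cc$nUsed, nSkipped = cc$nSkipped)
}

#' Accessors for CodonUsageProfile
#' @param x a [CodonUsageProfile-class].
#' @return \code{codonFreq}: named frequencies over the 61 sense codons;
#'   \code{codonCounts}: named counts over all 64 codons; \code{profileGc}:
#'   GC fraction; \code{taxonId}: identifier.
#' @rdname profileAccessors
#' @export
codonFreq <- function(x) {
  stopifnot(is(x, "CodonUsageProfile"))
  x@freq
}

#' @rdname profileAccessors
#' @export
codonCounts <- function(x) {
  stopifnot(is(x, "CodonUsageProfile"))
  x@counts
}

#' @rdname profileAccessors
#' @export
profileGc <- function(x) {
  stopifnot(is(x, "CodonUsageProfile"))
  x@gc
}

#' @rdname profileAccessors
#' @export
taxonId <- function(x) {
  stopifnot(is(x, "CodonUsageProfile"))
  x@taxonId
}

#' Write per-taxon codon usage as TSV
#'
#' Emits 64 rows (codon, count, frequency) with \code{NA} frequency for stop
#' codons.
#'
#' @param profile a [CodonUsageProfile-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeUsageTsv <- function(profile, path) {
  freq <- rep(NA_real_, 64L)
  names(freq) <- CODONS
  freq[names(codonFreq(profile))] <- codonFreq(profile)
  df <- data.frame(codon = CODONS, count = codonCounts(profile), freq = freq,
                   row.names = NULL)
  .writeTsvAtomic(df, path)
}
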