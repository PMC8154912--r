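# Independent oracles and small fixtures shared across tests.
# Everything here is built with elementary scalar logic on purpose: these
# implementations must not share code paths with the package.

# all 64 codons, assembled by explicit nested loops
oracleCodons <- local({
  nts <- c("A", "C", "G", "T")
  out <- character(0)
  for (a in nts) for (b in nts) for (d in nts) out <- c(out, paste0(a, b, d))
  sort(out)
})

# transition test by explicit set membership
oracleIsTransition <- function(x, y) {
  (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
}

# independent 64 x 64 kernel from pairwise string comparison
oracleKernel <- function(kappa, mu) {
  q <- matrix(0, 64, 64, dimnames = list(oracleCodons, oracleCodons))
  for (ci in oracleCodons) {
    bi <- strsplit(ci, "")[[1]]
    for (cj in oracleCodons) {
      bj <- strsplit(cj, "")[[1]]
      diffs <- which(bi != bj)
      if (length(diffs) == 0) {
        q[ci, cj] <- 1 - mu
      } else if (length(diffs) == 1) {
        pos <- diffs[1]
        q[ci, cj] <- if (oracleIsTransition(bi[pos], bj[pos]))
          mu * kappa / (1 + kappa) / 3
        else
          mu / (1 + kappa) / 6
      }
    }
  }
  q
}

# naive expected distortion: loop over source codons, summing
# p_i * q_ij * d(aa_i, aa_j) with every ingredient built independently
oracleDistortion <- function(p, kappa, mu, values, stopPolicy = "exclude",
                             form = "squared") {
  code <- sapply(oracleCodons, function(cdn)
    as.character(Biostrings::GENETIC_CODE[[cdn]]))
  q <- oracleKernel(kappa, mu)
  dmax <- 0
  for (a in names(values)) for (b in names(values)) {
    dd <- if (form == "squared") (values[[a]] - values[[b]])^2
          else abs(values[[a]] - values[[b]])
    dmax <- max(dmax, dd)
  }
  D <- 0
  for (ci in names(p)) {
    aai <- code[[ci]]
    for (cj in oracleCodons) {
      aaj <- code[[cj]]
      d <- if (aaj == "*") {
        if (stopPolicy == "max_penalty") dmax else 0
      } else if (aai == aaj) 0
      else if (form == "squared") (values[[aai]] - values[[aaj]])^2
      else abs(values[[aai]] - values[[aaj]])
      D <- D + p[[ci]] * q[ci, cj] * d
    }
  }
  D
}

# random usage profile over the sense codons (Dirichlet via gammas)
randomProfile <- function(alpha = 1) {
  sense <- senseCodons()
  g <- rgamma(length(sense), shape = alpha)
  usageFromCounts(setNames(round(1e6 * g / sum(g)), sense))
}

# star phylogeny: n tips all attached to the root with branch length len;
# a zero root edge marks it as rooted under ape's convention
starTree <- function(n, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr$root.edge <- 0
  tr
}

# direct (non-whitened) GLS estimates by explicit matrix inversion
oracleGls <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- solve(XtVi %*% X)
  beta <- A %*% XtVi %*% y
  e <- y - X %*% beta
  sigma2 <- as.numeric(t(e) %*% Vi %*% e) / (length(y) - ncol(X))
  list(beta = as.vector(beta), se = unname(sqrt(sigma2 * diag(A))),
       sigma2 = sigma2)
}

# toy two-amino-acid scale padded to full coverage with a constant
toyScale <- function(aa1 = "A", aa2 = "V", v1 = 0, v2 = 1, fill = 0) {
  vals <- setNames(rep(fill, 20),
                   c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  vals[aa1] <- v1
  vals[aa2] <- v2
  propertyScale("toy", vals)
}
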