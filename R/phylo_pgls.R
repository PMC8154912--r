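# Phylogenetic generalized least squares under a Brownian-motion covariance.
#
# V[i, j] is the branch length shared by the root-to-tip paths of tips i and
# j; GLS is solved by Cholesky whitening of V. R-squared is the generalized
# form against the GLS intercept-only null, and F = (R2/df1)/((1-R2)/df2).

#' Brownian-motion covariance of a phylogeny
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' depth of their most recent common ancestor (the shared part of their
#' root-to-tip paths); the variance of a tip is its root-to-tip distance.
#'
#' @param tree a rooted \code{ape::phylo} with non-negative branch lengths
#'   and at least 3 tips.
#' @return symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
brownianCovariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (ape::Ntip(tree) < 3L) stop("tree must have at least 3 tips")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are invalid")
  ape::vcv.phylo(tree)
}

#' Assemble a comparative dataset
#'
#' @param tree rooted \code{ape::phylo}; tip labels must match
#'   \code{traits$taxon_id} exactly (1:1).
#' @param traits data.frame with a \code{taxon_id} column and numeric trait
#'   columns.
#' @return a [ComparativeDataset-class] with traits ordered as the tips.
#' @export
comparativeDataset <- function(tree, traits) {
  obj <- new("ComparativeDataset", tree = tree,
             traits = traits[match(tree$tip.label, traits$taxon_id), ,
                             drop = FALSE])
  rownames(obj@traits) <- NULL
  obj
}

#' Accessors for ComparativeDataset
#' @param x a [ComparativeDataset-class].
#' @rdname datasetAccessors
#' @return \code{datasetTree}: the phylogeny; \code{datasetTraits}: the
#'   tip-ordered trait table.
#' @export
datasetTree <- function(x) {
  stopifnot(is(x, "ComparativeDataset"))
  x@tree
}

#' @rdname datasetAccessors
#' @export
datasetTraits <- function(x) {
  stopifnot(is(x, "ComparativeDataset"))
  x@traits
}

# Cholesky factor of V with the one-shot jitter policy: degenerate trees
# (duplicate tips, zero terminal branches) get a single diagonal bump of
# 1e-10 * trace(V)/n before failing for good.
.cholV <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- V + diag(1e-10 * sum(diag(V)) / nrow(V), nrow(V))
    ch <- tryCatch(chol(V), error = function(e)
      stop("phylogenetic covariance is not positive definite"))
  }
  ch
}

# Core GLS via whitening: solve L z = y with V = L L' (L lower triangular),
# regress whitened y on whitened X by QR.
.glsCore <- function(y, X, V) {
  L <- t(.cholV(V))  # lower triangular
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, X)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X))
    stop("design matrix is collinear after whitening")
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  XtViX_inv <- chol2inv(qr.R(qrX))
  list(beta = beta, resid_w = resid_w, XtViX_inv = XtViX_inv,
       yw = yw, Xw = Xw, L = L)
}

#' Fit one phylogenetic generalized least squares model
#'
#' Estimates beta = (X' V^-1 X)^-1 X' V^-1 y with V the Brownian covariance
#' of the tree, via Cholesky whitening. Reports per-term standard errors
#' from sigma2 (X' V^-1 X)^-1 with sigma2 = e' V^-1 e / (n - k), two-sided
#' Student-t p-values, the generalized R-squared against the GLS
#' intercept-only mean, and the model F statistic. Standardized partial
#' coefficients come from refitting after Z-transforming response and
#' predictors (unweighted mean/sd).
#'
#' @param dataset a [ComparativeDataset-class].
#' @param response name of the response column in the trait table.
#' @param predictors character vector of predictor column names; default the
#'   four environmental predictors \code{gc}, \code{temperature},
#'   \code{nacl}, \code{ph}.
#' @return a [PGLSResult-class].
#' @export
pglsFit <- function(dataset, response,
                    predictors = c("gc", "temperature", "nacl", "ph")) {
  stopifnot(is(dataset, "ComparativeDataset"))
  traits <- datasetTraits(dataset)
  missing_cols <- setdiff(c(response, predictors), names(traits))
  if (length(missing_cols))
    stop("trait table misses columns: ", paste(missing_cols, collapse = ", "))
  y <- traits[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(traits[, predictors, drop = FALSE]))
  if (anyNA(y) || anyNA(X))
    stop("missing values among response or predictors")
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more tips than coefficients")
  V <- brownianCovariance(datasetTree(dataset))

  fit <- .glsCore(y, X, V)
  sse <- sum(fit$resid_w^2)              # e' V^-1 e
  sigma2 <- sse / (n - k)
  se <- sqrt(sigma2 * diag(fit$XtViX_inv))
  tval <- as.vector(fit$beta) / se
  pval <- 2 * pt(abs(tval), df = n - k, lower.tail = FALSE)

  # GLS intercept-only null for the generalized R-squared
  null_fit <- .glsCore(y, matrix(1, n, 1), V)
  sse0 <- sum(null_fit$resid_w^2)
  r2 <- 1 - sse / sse0
  df1 <- k - 1L
  df2 <- n - k
  fstat <- (r2 / df1) / ((1 - r2) / df2)
  p_model <- pf(fstat, df1, df2, lower.tail = FALSE)

  beta_std <- c(NA_real_,
                .standardizedBetas(y, traits[, predictors, drop = FALSE], V))
  coefs <- data.frame(term = colnames(X), beta = as.vector(fit$beta),
                      se = se, t = tval, p = pval, beta_std = beta_std,
                      row.names = NULL, stringsAsFactors = FALSE)
  new("PGLSResult", response = response, coefficients = coefs,
      r2 = r2, fstat = fstat, df1 = as.integer(df1), df2 = as.integer(df2),
      pModel = p_model, sigma2 = sigma2, n = as.integer(n))
}

.zscore <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("zero-variance variable cannot be Z-transformed")
  (v - mean(v)) / s
}

.standardizedBetas <- function(y, Xpred, V) {
  yz <- .zscore(y)
  Xz <- vapply(Xpred, .zscore, numeric(length(y)))
  fit <- .glsCore(yz, cbind(1, Xz), V)
  setNames(as.vector(fit$beta)[-1], colnames(Xpred))
}

#' Standardized partial coefficients of a PGLS model
#'
#' Z-transforms the response and every predictor (unweighted mean and
#' standard deviation) and refits the model, returning the slope
#' coefficients only. These are the scale-free effect sizes comparable
#' across predictors.
#'
#' @inheritParams pglsFit
#' @return named numeric vector of standardized slopes.
#' @export
pglsStandardizedBetas <- function(dataset, response,
                                  predictors = c("gc", "temperature",
                                                 "nacl", "ph")) {
  fit <- pglsFit(dataset, response, predictors)
  coefs <- pglsCoefficients(fit)
  setNames(coefs$beta_std[-1], coefs$term[-1])
}

#' Accessors for PGLSResult
#' @param x a [PGLSResult-class].
#' @rdname pglsAccessors
#' @return \code{pglsCoefficients}: per-term data.frame (term, beta, se, t,
#'   p, beta_std); \code{pglsSummaryRow}: one-row data.frame with response,
#'   r2, f, df1, df2, p_model, n.
#' @export
pglsCoefficients <- function(x) {
  stopifnot(is(x, "PGLSResult"))
  x@coefficients
}

#' @rdname pglsAccessors
#' @export
pglsSummaryRow <- function(x) {
  stopifnot(is(x, "PGLSResult"))
  data.frame(response = x@response, r2 = x@r2, f = x@fstat,
             df1 = x@df1, df2 = x@df2, p_model = x@pModel, n = x@n,
             stringsAsFactors = FALSE)
}

#' Fit the four distortion regressions
#'
#' One PGLS per distortion response (D_hyd, D_pol, D_vol, D_pI) against the
#' four predictors (GC fraction, temperature, NaCl, pH), mirroring a
#' four-model comparative analysis. With 64 taxa each model has the
#' F(4, 59) shape.
#'
#' @param dataset a [ComparativeDataset-class] whose traits contain the four
#'   responses and four predictors.
#' @param responses response column names; default the four D measures.
#' @param predictors predictor column names.
#' @return named list of [PGLSResult-class], one per response.
#' @export
runFullAnalysis <- function(dataset,
                            responses = c("D_hyd", "D_pol", "D_vol", "D_pI"),
                            predictors = c("gc", "temperature", "nacl",
                                           "ph")) {
  setNames(lapply(responses, function(r) pglsFit(dataset, r, predictors)),
           responses)
}

#' Long-format coefficient table of a full analysis
#'
#' @param fits named list of [PGLSResult-class] from [runFullAnalysis()].
#' @return data.frame with columns response, term, beta, se, t, p, beta_std.
#' @export
pglsResultsTable <- function(fits) {
  rows <- lapply(names(fits), function(r)
    cbind(response = r, pglsCoefficients(fits[[r]])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-summary table of a full analysis
#'
#' @param fits named list of [PGLSResult-class].
#' @return data.frame with one row per model: response, r2, f, df1, df2,
#'   p_model, n.
#' @export
pglsModelSummary <- function(fits) {
  out <- do.call(rbind, lapply(fits, pglsSummaryRow))
  rownames(out) <- NULL
  out
}
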