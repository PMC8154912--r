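make_dataset <- function(tree, y, X) {
  traits <- data.frame(taxon_id = tree$tip.label, y = y, X)
  comparativeDataset(tree, traits)
}

test_that("Brownian covariance encodes shared root-to-tip path lengths", {
  # star: no shared paths
  V <- brownianCovariance(starTree(4, len = 2.5))
  expect_equal(V, 2.5 * diag(4), ignore_attr = TRUE)
  # cherry (A,B) at depth s = 1 inside a 3-tip tree of depth t = 3
  tr <- ape::read.tree(text = "((A:2,B:2):1,C:3);")
  V <- brownianCovariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 3)
  expect_equal(V["A", "C"], 0)
  # ultrametric tree: equal diagonal
  tr2 <- simulateTree(16, seed = 3)
  V2 <- brownianCovariance(tr2)
  expect_lt(diff(range(diag(V2))), 1e-10)
  expect_equal(V2, t(V2))
  expect_true(all(eigen(V2, only.values = TRUE)$values > -1e-10))
  # invalid input
  tr_neg <- tr
  tr_neg$edge.length[1] <- -1
  expect_error(brownianCovariance(tr_neg), "negative")
  expect_error(brownianCovariance(ape::read.tree(text = "(A:1,B:1);")),
               "3 tips")
})

test_that("PGLS on a star phylogeny reproduces ordinary least squares", {
  set.seed(42)
  n <- 24
  tr <- starTree(n, len = 1.7)
  X <- data.frame(gc = runif(n, 0.3, 0.7), temperature = rnorm(n, 30, 15),
                  nacl = runif(n, 0, 10), ph = rnorm(n, 7, 1))
  y <- 2 + 0.5 * X$gc + 0.02 * X$temperature + rnorm(n)
  ds <- make_dataset(tr, y, X)
  fit <- pglsFit(ds, "y")
  ols <- summary(lm(y ~ gc + temperature + nacl + ph, data = X))
  expect_equal(pglsCoefficients(fit)$beta, unname(ols$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(pglsCoefficients(fit)$se, unname(ols$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(pglsCoefficients(fit)$t, unname(ols$coefficients[, 3]),
               tolerance = 1e-10)
  expect_equal(pglsCoefficients(fit)$p, unname(ols$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(fit@r2, ols$r.squared, tolerance = 1e-10)
  expect_equal(fit@fstat, unname(ols$fstatistic[1]), tolerance = 1e-10)
  # standardized betas equal standardized OLS coefficients on the star
  z <- as.data.frame(scale(cbind(y = y, X)))
  ols_z <- coef(lm(y ~ gc + temperature + nacl + ph, data = z))[-1]
  expect_equal(pglsStandardizedBetas(ds, "y"), ols_z, tolerance = 1e-10)
})

test_that("GLS estimates match direct matrix-inversion GLS on random trees", {
  for (seed in 1:3) {
    set.seed(seed)
    tr <- simulateTree(64, seed = seed)
    V <- brownianCovariance(tr)
    n <- 64
    X <- data.frame(gc = runif(n, 0.3, 0.7), temperature = rnorm(n, 30, 15),
                    nacl = runif(n, 0, 10), ph = rnorm(n, 7, 1))
    y <- as.vector(t(chol(V)) %*% rnorm(n)) + 0.3 * X$gc
    ds <- make_dataset(tr, y, X)
    fit <- pglsFit(ds, "y")
    Xm <- cbind(1, as.matrix(X))
    oracle <- oracleGls(y, Xm, V)
    expect_equal(pglsCoefficients(fit)$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(pglsCoefficients(fit)$se, oracle$se, tolerance = 1e-10)
    expect_equal(fit@sigma2, oracle$sigma2, tolerance = 1e-10)
  }
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  set.seed(7)
  tr <- simulateTree(32, seed = 7)
  n <- 32
  dat <- data.frame(taxon_id = tr$tip.label,
                    x1 = rnorm(n), x2 = runif(n))
  V <- brownianCovariance(tr)
  dat$y <- 1 + 0.8 * dat$x1 + as.vector(t(chol(V)) %*% rnorm(n))
  ds <- comparativeDataset(tr, dat)
  fit <- pglsFit(ds, "y", c("x1", "x2"))
  g <- nlme::gls(y ~ x1 + x2, data = dat,
                 correlation = ape::corBrownian(phy = tr, form = ~taxon_id),
                 method = "ML")
  expect_equal(pglsCoefficients(fit)$beta, unname(coef(g)), tolerance = 1e-6)
  tt <- summary(g)$tTable
  expect_equal(pglsCoefficients(fit)$t, unname(tt[, "t-value"]),
               tolerance = 1e-4)
})

test_that("perfect linear responses give R2 = 1 and zero residuals", {
  tr <- simulateTree(16, seed = 5)
  set.seed(5)
  X <- data.frame(gc = runif(16), temperature = rnorm(16),
                  nacl = runif(16), ph = rnorm(16))
  y <- 1 + 2 * X$gc - 3 * X$ph
  fit <- pglsFit(make_dataset(tr, y, X), "y")
  expect_equal(fit@r2, 1, tolerance = 1e-10)
  expect_equal(pglsCoefficients(fit)$beta, c(1, 2, 0, 0, -3),
               tolerance = 1e-8)
})

test_that("reported statistics are invariant to rescaling branch lengths", {
  set.seed(9)
  tr <- simulateTree(24, seed = 9)
  X <- data.frame(gc = runif(24), temperature = rnorm(24),
                  nacl = runif(24), ph = rnorm(24))
  V <- brownianCovariance(tr)
  y <- 0.5 * X$gc + as.vector(t(chol(V)) %*% rnorm(24))
  f1 <- pglsFit(make_dataset(tr, y, X), "y")
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 37.5
  f2 <- pglsFit(make_dataset(tr2, y, X), "y")
  expect_equal(pglsCoefficients(f1)$beta, pglsCoefficients(f2)$beta,
               tolerance = 1e-10)
  expect_equal(pglsCoefficients(f1)$t, pglsCoefficients(f2)$t,
               tolerance = 1e-8)
  expect_equal(f1@r2, f2@r2, tolerance = 1e-10)
  expect_equal(f1@fstat, f2@fstat, tolerance = 1e-8)
  # V scales by c, so V^-1 and with it sigma2 scale by 1/c
  expect_equal(f1@sigma2 / 37.5, f2@sigma2, tolerance = 1e-6)
})

test_that("standardized betas absorb affine predictor rescaling", {
  set.seed(13)
  tr <- simulateTree(24, seed = 13)
  X <- data.frame(gc = runif(24), temperature = rnorm(24, 30, 12),
                  nacl = runif(24, 0, 8), ph = rnorm(24, 7, 1))
  V <- brownianCovariance(tr)
  y <- 0.01 * X$temperature + as.vector(t(chol(V)) %*% rnorm(24))
  ds1 <- make_dataset(tr, y, X)
  X2 <- X
  X2$temperature <- X$temperature * 10 + 100  # tenths of a degree, offset
  ds2 <- make_dataset(tr, y, X2)
  b1 <- pglsStandardizedBetas(ds1, "y")
  b2 <- pglsStandardizedBetas(ds2, "y")
  expect_equal(b1, b2, tolerance = 1e-10)
  # signs of standardized betas match raw betas
  raw <- pglsCoefficients(pglsFit(ds1, "y"))
  expect_equal(sign(raw$beta_std[-1]), sign(raw$beta[-1]))
  # zero-variance predictor is rejected
  X3 <- X
  X3$nacl <- 2.5
  expect_error(pglsFit(make_dataset(tr, y, X3), "y"), "")
})

test_that("planted coefficients are recovered over Brownian replicates", {
  # Monte-Carlo recovery: mean beta-hat near truth, ~95% CI coverage
  tr <- simulateTree(48, seed = 17)
  V <- brownianCovariance(tr)
  L <- t(chol(V))
  beta_true <- c(1, 0.6, -0.4)
  set.seed(17)
  X <- cbind(x1 = rnorm(48), x2 = runif(48))
  est <- matrix(NA_real_, 200, 2)
  cover <- matrix(NA, 200, 2)
  for (r in 1:200) {
    y <- beta_true[1] + X %*% beta_true[-1] + as.vector(L %*% rnorm(48))
    ds <- comparativeDataset(tr, data.frame(taxon_id = tr$tip.label, y = y, X))
    fit <- pglsFit(ds, "y", c("x1", "x2"))
    co <- pglsCoefficients(fit)
    est[r, ] <- co$beta[-1]
    tcrit <- qt(0.975, df = fit@df2)
    cover[r, ] <- abs(co$beta[-1] - beta_true[-1]) <= tcrit * co$se[-1]
  }
  mc_se <- apply(est, 2, sd) / sqrt(200)
  expect_true(all(abs(colMeans(est) - beta_true[-1]) < 4 * mc_se))
  expect_true(all(colMeans(cover) > 0.90 & colMeans(cover) < 0.99))
})

test_that("the full analysis fits four models with the expected df shape", {
  sim <- simulateScenario(syntheticScenario(nTips = 16, seed = 23))
  ds <- assembleComparativeData(sim)
  fits <- runFullAnalysis(ds)
  expect_named(fits, c("D_hyd", "D_pol", "D_vol", "D_pI"))
  for (f in fits) {
    expect_identical(f@df1, 4L)
    expect_identical(f@df2, 16L - 5L)
    expect_gte(f@r2, 0)
    expect_lte(f@r2, 1)
  }
  # independent of response ordering
  fits_rev <- runFullAnalysis(ds, responses = c("D_pI", "D_hyd"))
  expect_equal(pglsCoefficients(fits_rev$D_hyd), pglsCoefficients(fits$D_hyd))
  # summary tables
  ms <- pglsModelSummary(fits)
  expect_identical(nrow(ms), 4L)
  expect_true(all(ms$df2 == 11L))
  tab <- pglsResultsTable(fits)
  expect_identical(nrow(tab), 4L * 5L)
})

test_that("degenerate trees trigger the jitter policy or fail loudly", {
  # duplicate tips at zero distance: V is singular, jitter rescues the fit
  tr <- ape::read.tree(text = "((A:0,B:0):1,(C:0.5,D:0.5):0.5);")
  set.seed(3)
  X <- data.frame(x = rnorm(4))
  y <- rnorm(4)
  expect_error(brownianCovariance(tr), NA)
  # collinear design is rejected
  tr2 <- simulateTree(12, seed = 29)
  set.seed(29)
  Xc <- data.frame(x1 = rnorm(12))
  Xc$x2 <- 2 * Xc$x1
  ds <- comparativeDataset(tr2, data.frame(taxon_id = tr2$tip.label,
                                           y = rnorm(12), Xc))
  expect_error(pglsFit(ds, "y", c("x1", "x2")), "collinear")
})
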