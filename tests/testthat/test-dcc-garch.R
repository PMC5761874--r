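test_that("white-noise input yields an observationally flat fit", {
  # ARMA(2,2)+GARCH(1,1) on i.i.d. noise is only set-identified (cancelling
  # AR/MA roots; psi unidentified at phi = 0), so assert the identified
  # quantities: the fitted conditional mean and variance are essentially flat
  # and the AR and MA polynomials cancel.
  stats <- vapply(1:5, function(s) {
    set.seed(s)
    z <- rnorm(2000)
    f <- fitUnivariateArmaGarch(z)
    c(sd(f@fittedMean) / sd(z),
      sd(f@condSD^2) / mean(f@condSD^2),
      abs(f@params["beta1"] - f@params["theta1"]),
      abs(f@params["beta2"] - f@params["theta2"]))
  }, numeric(4))
  m <- rowMeans(stats)
  expect_lt(m[1], 0.10)   # conditional mean explains almost nothing
  expect_lt(m[2], 0.10)   # conditional variance nearly constant
  expect_lt(m[3], 0.10)   # beta1 ~ theta1 (cancelling roots)
  expect_lt(m[4], 0.10)
})

test_that("GARCH(1,1) parameters are recovered on identified simulations", {
  est <- vapply(1:8, function(s) {
    sub <- simulateSubject(quickSpec(nTime = 4000, mode = constantMode(0.3),
                                     seed = s, arma = FALSE))
    f <- fitUnivariateArmaGarch(sub@series@values[, 1], meanOrder = c(0, 0))
    f@params[c("phi", "psi")]
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.10), 0.05)
  expect_lt(abs(mean(est[2, ]) - 0.85), 0.05)
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  expect_error(fitUnivariateArmaGarch(rep(1, 100)), "degenerate variance")
  expect_error(fitUnivariateArmaGarch(rnorm(20)), "at least 50")
  u <- matrix(rnorm(400), 200, 2)
  expect_error(fitDcc(cbind(u[, 1], u[, 1])), "singular")
  expect_error(fitDcc(u, eta = c(0.5, 0.6)), "eta")
})

test_that("DCC with eta fixed at zero gives a constant correlation equal to xi", {
  set.seed(42)
  u <- matrix(rnorm(1000), 500, 2)
  u[, 2] <- 0.5 * u[, 1] + sqrt(0.75) * u[, 2]
  d <- fitDcc(u, eta = c(0, 0))
  expect_true(all(abs(rho(d) - d@xi[1, 2]) < 1e-12))
})

test_that("DCC stage recovers a constant correlation level", {
  ms <- vapply(1:10, function(s) {
    set.seed(s)
    z <- matrix(rnorm(4000), 2000, 2)
    u <- cbind(z[, 1], 0.5 * z[, 1] + sqrt(0.75) * z[, 2])
    r <- rho(fitDcc(u))
    c(mean(r), sd(r))
  }, numeric(2))
  expect_lt(abs(mean(ms[1, ]) - 0.5), 0.05)
  expect_lt(mean(ms[2, ]), 0.1)
})

test_that("estimateDfc honours its output contract", {
  sub <- simulateSubject(quickSpec(nTime = 220, mode = constantMode(0.4),
                                   seed = 8))
  fit <- estimateDfc(sub@series)
  expect_s4_class(fit, "DfcFit")
  expect_length(rho(fit), 220L)
  expect_lte(max(abs(rho(fit))), 1)
  expect_equal(nrow(fit@ljungBox), 2L)
  expect_true(all(is.finite(fit@ljungBox$statistic)))
})

test_that("estimateDfc is near zero on independent white noise", {
  m <- vapply(1:5, function(s) {
    sp <- quickSpec(nTime = 1000, mode = constantMode(0), seed = s,
                    arma = FALSE)
    mean(rho(estimateDfc(simulateSubject(sp)@series)))
  }, numeric(1))
  expect_lt(mean(abs(m)), 0.1)
})

test_that("two-step fit is invariant to rescaling one series", {
  sub <- simulateSubject(quickSpec(nTime = 450, mode = constantMode(0.4),
                                   seed = 6))
  f1 <- estimateDfc(sub@series)
  scaled <- BivariateSeries(cbind(sub@series@values[, 1] * 10,
                                  sub@series@values[, 2]), tr = 2)
  f2 <- estimateDfc(scaled)
  expect_lt(max(abs(rho(f1) - rho(f2))), 1e-6)
})

test_that("likelihood decomposes into variance + correlation parts", {
  sub <- simulateSubject(quickSpec(nTime = 300, seed = 13))
  pars <- list(
    margin1 = list(alpha = 0, beta = c(0.25, -0.1), theta = c(0.15, 0.05),
                   omega = 0.05, phi = 0.10, psi = 0.85),
    margin2 = list(alpha = 0, beta = c(0.25, -0.1), theta = c(0.15, 0.05),
                   omega = 0.05, phi = 0.10, psi = 0.85),
    eta = c(0.05, 0.90))
  ll <- logLikelihood(pars, sub@series)
  expect_equal(ll$total, ll$variance + ll$correlation, tolerance = 1e-8)

  # with eta = 0 and identity xi, the correlation part vanishes identically
  pars$eta <- c(0, 0)
  pars$xi <- diag(2)
  ll0 <- logLikelihood(pars, sub@series)
  expect_equal(ll0$correlation, 0, tolerance = 1e-10)
})

test_that("finite-difference gradient vanishes at the reported optimum", {
  sub <- simulateSubject(quickSpec(nTime = 500, mode = dccMode(), seed = 3))
  z <- sub@series@values[, 1]
  zstd <- z / sd(z)
  f <- fitUnivariateArmaGarch(z)
  pp <- f@params
  # the optimizer's own objective: standardized data, transformed parameters
  par <- c(pp["alpha"] / sd(z), pp["beta1"], pp["beta2"], pp["theta1"],
           pp["theta2"], log(pp["omega"] / var(z)),
           dynConn:::rawFromSimplex(pp[c("phi", "psi")]))
  nll <- function(par) {
    g <- dynConn:::simplexFromRaw(par[7:8])
    fl <- dynConn:::arma_garch_filter_cpp(zstd, par[1], par[2:3], par[4:5],
                                          exp(par[6]), g[1], g[2])
    -fl$loglik
  }
  gr <- vapply(1:8, function(i) {
    e1 <- par; e1[i] <- e1[i] + 1e-5
    e2 <- par; e2[i] <- e2[i] - 1e-5
    (nll(e1) - nll(e2)) / 2e-5
  }, numeric(1))
  expect_lt(sqrt(sum(gr^2)), 1e-3)
})

test_that("estimated trajectory tracks a slowly varying true correlation", {
  cors <- vapply(1:5, function(s) {
    sub <- simulateSubject(quickSpec(
      nTime = 450, mode = sinusoidMode(amplitude = 0.6, frequency = 0.01),
      seed = s))
    cor(rho(estimateDfc(sub@series)), sub@trueCorrelation)
  }, numeric(1))
  expect_gt(mean(cors), 0.5)
})
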