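#' Fit a univariate ARMA-GARCH(1,1) model by Gaussian quasi-likelihood
#'
#' First step of the two-step DCC estimator: each series gets an ARMA mean
#' (default order (2,2)) with a GARCH(1,1) conditional variance
#' \eqn{\sigma^2_t = \omega + \phi \epsilon^2_{t-1} + \psi \sigma^2_{t-1}}.
#' Parameters maximize the variance part of the Gaussian quasi-likelihood
#' under the stationarity constraints (omega > 0; phi, psi >= 0;
#' phi + psi < 1), enforced by reparameterization (log for omega,
#' logistic-simplex for (phi, psi)). Optimization is BFGS from a fixed set of
#' starting points, so the fit is deterministic given the input.
#'
#' @param z numeric series with positive variance.
#' @param meanOrder integer(2) ARMA order (p, q), default c(2, 2).
#' @param restarts number of extra starting points beyond the default start.
#' @param reltol optimizer tolerance on the objective.
#' @return An \linkS4class{UnivariateFit}. If no start converges, the best
#'   attempt is returned with \code{converged = FALSE} and a warning.
#' @export
#' @examples
#' fit <- fitUnivariateArmaGarch(as.numeric(arima.sim(list(ar = 0.3), 400)))
#' fit@params
fitUnivariateArmaGarch <- function(z, meanOrder = c(2L, 2L), restarts = 3L,
                                   reltol = 1e-10) {
  z <- as.numeric(z)
  if (length(z) < 50L) stop("need at least 50 observations")
  if (anyNA(z)) stop("series contains missing values")
  vz <- var(z)
  if (vz == 0) stop("degenerate variance: input series is constant")
  p <- as.integer(meanOrder[1]); q <- as.integer(meanOrder[2])

  # standardize for optimizer conditioning; the fit is mapped back below, so
  # results are exactly invariant to positive rescaling of the input
  sdz <- sqrt(vz)
  z <- z / sdz
  vz <- 1

  unpack <- function(par) {
    list(alpha = par[1],
         beta = if (p) par[1 + seq_len(p)] else numeric(),
         theta = if (q) par[1 + p + seq_len(q)] else numeric(),
         omega = exp(par[2 + p + q]),
         gpar = simplexFromRaw(par[(3 + p + q):(4 + p + q)]))
  }

  # lag polynomial 1 - c1 x - ... - ck x^k has all roots outside the unit
  # circle (AR stationarity / MA invertibility)
  rootsOutside <- function(coef)
    all(Mod(polyroot(c(1, -coef))) > 1 + 1e-6)

  negll <- function(par) {
    u <- unpack(par)
    if (p && !rootsOutside(u$beta)) return(1e10)
    if (q && !rootsOutside(u$theta)) return(1e10)
    f <- arma_garch_filter_cpp(z, u$alpha, u$beta, u$theta,
                               u$omega, u$gpar[1], u$gpar[2])
    if (!f$ok || !is.finite(f$loglik)) return(1e10)
    -f$loglik
  }

  # deterministic start table: vary persistence and the news/decay split
  starts <- list(
    c(0.90, 0.10 / 0.90), c(0.50, 0.50), c(0.95, 0.05 / 0.95), c(0.20, 0.50))
  base <- c(mean(z), rep(0, p + q), log(0.5 * vz))
  best <- NULL
  for (i in seq_len(min(1L + restarts, length(starts)))) {
    s <- starts[[i]]
    par0 <- c(base, stats::qlogis(s[1]), stats::qlogis(s[2]))
    opt <- try(stats::optim(par0, negll, method = "BFGS",
                            control = list(reltol = reltol, maxit = 1000,
                                           ndeps = rep(1e-6, length(par0)))),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("ARMA-GARCH optimization failed from every start")
  if (best$value >= 1e10)
    stop("ARMA-GARCH optimization never reached a feasible point")

  u <- unpack(best$par)
  f <- arma_garch_filter_cpp(z, u$alpha, u$beta, u$theta,
                             u$omega, u$gpar[1], u$gpar[2])
  params <- c(alpha = unname(u$alpha) * sdz,
              if (p) stats::setNames(u$beta, paste0("beta", seq_len(p))),
              if (q) stats::setNames(u$theta, paste0("theta", seq_len(q))),
              omega = unname(u$omega) * sdz^2,
              phi = unname(u$gpar[1]), psi = unname(u$gpar[2]))
  converged <- best$convergence == 0L
  if (!converged)
    warning("optimizer did not report convergence; returning best attempt")
  sig <- sqrt(f$sig2)
  nEff <- length(z) - f$m
  new("UnivariateFit", params = params, fittedMean = f$mu * sdz,
      residuals = f$eps * sdz, condSD = sig * sdz, stdResid = f$eps / sig,
      loglik = f$loglik - nEff * log(sdz), converged = converged,
      meanOrder = c(p, q))
}

#' Fit the DCC correlation stage to standardized residuals
#'
#' Second step of the two-step estimator. The unconditional correlation Xi is
#' the sample correlation of the standardized residuals; (eta1, eta2)
#' maximize the correlation part of the Gaussian quasi-likelihood over the
#' simplex eta1, eta2 >= 0, eta1 + eta2 < 1 (logistic-simplex
#' reparameterization, BFGS, deterministic restarts). The recursion starts at
#' Q_1 = Xi and is driven by the lagged outer product of the residuals.
#'
#' @param u T x 2 matrix of standardized residuals (approximately zero mean,
#'   unit variance columns).
#' @param tr sampling interval in seconds, attached to the output trajectory.
#' @param eta optional fixed c(eta1, eta2); when supplied no optimization is
#'   performed (useful for the constant-correlation special case eta = 0).
#' @param reltol optimizer tolerance.
#' @return A \linkS4class{DccFit} carrying the full correlation trajectory.
#' @export
fitDcc <- function(u, tr = 2, eta = NULL, reltol = 1e-10) {
  u <- as.matrix(u)
  if (ncol(u) != 2L) stop("u must have exactly two columns")
  if (anyNA(u)) stop("u contains missing values")
  xi <- cor(u)
  if (!is.finite(xi[1, 2]) || abs(xi[1, 2]) >= 1 - 1e-10)
    stop("correlation matrix of residuals is singular (collinear columns)")

  filt <- function(e) dcc_filter_cpp(u, e[1], e[2],
                                     xi[1, 1], xi[1, 2], xi[2, 2])

  boundary <- FALSE
  if (is.null(eta)) {
    negll <- function(raw) {
      e <- simplexFromRaw(raw)
      f <- filt(e)
      if (!f$ok || !is.finite(f$loglik)) return(1e10)
      -f$loglik
    }
    starts <- list(c(0.05, 0.90), c(0.20, 0.60), c(0.02, 0.02))
    best <- NULL
    for (s in starts) {
      opt <- try(stats::optim(rawFromSimplex(s), negll, method = "BFGS",
                              control = list(reltol = reltol, maxit = 1000,
                                             ndeps = rep(1e-6, 2))),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) stop("DCC optimization failed from every start")
    eta <- simplexFromRaw(best$par)
    boundary <- sum(eta) > 0.999 || any(eta < 1e-6)
    if (sum(eta) > 0.999)
      warning("DCC optimum pinned near the persistence boundary eta1 + eta2 = 1")
  } else {
    eta <- as.numeric(eta)
    if (any(eta < 0) || sum(eta) >= 1)
      stop("fixed eta must satisfy eta1, eta2 >= 0 and eta1 + eta2 < 1")
  }

  f <- filt(eta)
  if (!f$ok) stop("DCC filter failed at the chosen parameters")
  new("DccFit", eta = unname(eta), xi = xi,
      q = cbind(q11 = f$q11, q12 = f$q12, q22 = f$q22),
      dfc = DfcSeries(f$rho, tr = tr), loglik = f$loglik,
      boundary = boundary)
}

#' Estimate dynamic functional connectivity for a network pair
#'
#' Composes the two estimation steps: a univariate ARMA-GARCH fit per series,
#' then the DCC correlation stage on the standardized residuals. Ljung-Box
#' statistics (lag 10) of the standardized residuals are reported as a
#' residual-whiteness diagnostic.
#'
#' @param series a \linkS4class{BivariateSeries}.
#' @param meanOrder ARMA order for both margins, default c(2, 2).
#' @param eta optional fixed DCC parameters (see \code{\link{fitDcc}}).
#' @param ... passed to \code{\link{fitUnivariateArmaGarch}}.
#' @return A \linkS4class{DfcFit}.
#' @export
#' @examples
#' sub <- simulateSubject(SimulationSpec(nTime = 200,
#'                                       mode = constantMode(0.4), seed = 2))
#' fit <- estimateDfc(sub@series)
#' mean(rho(fit))
estimateDfc <- function(series, meanOrder = c(2L, 2L), eta = NULL, ...) {
  stopifnot(is(series, "BivariateSeries"))
  validObject(series)
  fits <- vector("list", 2)
  for (j in 1:2) {
    fits[[j]] <- tryCatch(
      fitUnivariateArmaGarch(series@values[, j], meanOrder = meanOrder, ...),
      error = function(e) stop("univariate stage failed for series ", j,
                               " (", series@labels[j], "): ",
                               conditionMessage(e), call. = FALSE))
  }
  u <- cbind(fits[[1]]@stdResid, fits[[2]]@stdResid)
  dcc <- tryCatch(fitDcc(u, tr = series@tr, eta = eta),
                  error = function(e) stop("DCC stage failed: ",
                                           conditionMessage(e), call. = FALSE))
  lb <- do.call(rbind, lapply(1:2, function(j) {
    bt <- stats::Box.test(fits[[j]]@stdResid, lag = 10, type = "Ljung-Box")
    data.frame(series = series@labels[j], statistic = unname(bt$statistic),
               df = unname(bt$parameter), p_value = unname(bt$p.value))
  }))
  new("DfcFit", dfc = dcc@dfc, marginFits = fits, dcc = dcc,
      ljungBox = lb, labels = series@labels)
}

#' Gaussian quasi-log-likelihood of the full DCC-GARCH model
#'
#' Evaluates the joint likelihood at given parameters and returns its exact
#' decomposition into a variance part (sum of the two univariate GARCH
#' likelihoods) and a correlation part, whose sum is the total.
#'
#' @param params list with elements \code{margin1}, \code{margin2} (each a
#'   list with alpha, beta, theta, omega, phi, psi), \code{eta} (numeric(2))
#'   and optionally \code{xi} (2 x 2 matrix; defaults to the sample
#'   correlation of the implied standardized residuals).
#' @param series a \linkS4class{BivariateSeries}.
#' @return list with \code{total}, \code{variance}, \code{correlation}.
#' @export
logLikelihood <- function(params, series) {
  stopifnot(is(series, "BivariateSeries"))
  uList <- vector("list", 2)
  varLL <- 0
  for (j in 1:2) {
    m <- params[[paste0("margin", j)]]
    if (m$omega <= 0 || m$phi < 0 || m$psi < 0 || m$phi + m$psi >= 1)
      stop("variance parameters outside the constraint region")
    f <- arma_garch_filter_cpp(series@values[, j], m$alpha,
                               as.numeric(m$beta), as.numeric(m$theta),
                               m$omega, m$phi, m$psi)
    if (!f$ok) stop("variance filter failed for series ", j)
    varLL <- varLL + f$loglik
    uList[[j]] <- f$eps / sqrt(f$sig2)
  }
  u <- cbind(uList[[1]], uList[[2]])
  eta <- params$eta
  if (any(eta < 0) || sum(eta) >= 1)
    stop("eta outside the constraint region")
  xi <- if (!is.null(params$xi)) params$xi else cor(u)
  if (abs(xi[1, 2]) >= 1) stop("correlation matrix is singular")
  f <- dcc_filter_cpp(u, eta[1], eta[2], xi[1, 1], xi[1, 2], xi[2, 2])
  if (!f$ok) stop("encountered a non-positive-definite correlation matrix")
  list(total = varLL + f$loglik, variance = varLL, correlation = f$loglik)
}
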