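#' @import methods
#' @importFrom stats var cor
NULL

#' Canonical names of the 17 dFC features
#'
#' Order used in every feature vector and feature table: four temporal
#' features (mean, variance, proportion of anticorrelated volumes,
#' zero-crossing rate), six spectral-moment features and seven
#' spectral-shape features.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' dfcFeatureNames()
dfcFeatureNames <- function() {
  c("MV", "VAR", "PAV", "ZC",
    "SCO", "SPR", "SKW", "KURT", "SMED", "SRO",
    "PEAK", "CREST", "FLUX", "SLOPE", "FLAT", "PSE", "ALFF_dFC")
}

# ---------------------------------------------------------------------------
# BivariateSeries
# ---------------------------------------------------------------------------

#' Bivariate network time-course pair
#'
#' Holds two aligned BOLD-like time courses sampled every \code{tr} seconds,
#' the observation vector of the dynamic conditional correlation model.
#'
#' @slot values T x 2 numeric matrix, one column per network.
#' @slot tr sampling interval in seconds.
#' @slot labels names of the two networks.
#' @export
setClass("BivariateSeries",
  representation(values = "matrix", tr = "numeric", labels = "character"))

setValidity("BivariateSeries", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "'values' must be a numeric matrix with exactly 2 columns")
  if (nrow(v) < 50L)
    msg <- c(msg, "need at least 50 time points to identify ARMA(2,2)+GARCH(1,1)")
  if (anyNA(v)) msg <- c(msg, "'values' must not contain missing values")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number of seconds")
  if (length(object@labels) != 2L)
    msg <- c(msg, "'labels' must name the two networks")
  if (is.numeric(v) && ncol(v) == 2L && !anyNA(v) &&
      (var(v[, 1]) == 0 || var(v[, 2]) == 0))
    msg <- c(msg, "both columns must have nonzero sample variance")
  if (length(msg)) msg else TRUE
})

#' Construct a BivariateSeries
#'
#' @param values T x 2 numeric matrix (or two-column data.frame).
#' @param tr sampling interval in seconds (default 2, the usual fMRI TR).
#' @param labels character(2), network names.
#' @return A \linkS4class{BivariateSeries}.
#' @export
#' @examples
#' z <- matrix(rnorm(200), ncol = 2)
#' BivariateSeries(z, tr = 2, labels = c("DMN", "MEM"))
BivariateSeries <- function(values, tr = 2, labels = c("roi1", "roi2")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(colnames(values)) && missing(labels)) labels <- colnames(values)
  colnames(values) <- labels
  new("BivariateSeries", values = values, tr = as.numeric(tr),
      labels = as.character(labels))
}

# ---------------------------------------------------------------------------
# DfcSeries
# ---------------------------------------------------------------------------

#' Dynamic functional connectivity trajectory
#'
#' A time-resolved correlation rho_t in [-1, 1], one value per acquisition.
#'
#' @slot rho numeric vector of conditional correlations.
#' @slot tr sampling interval in seconds.
#' @export
setClass("DfcSeries", representation(rho = "numeric", tr = "numeric"))

setValidity("DfcSeries", function(object) {
  msg <- character()
  if (anyNA(object@rho)) msg <- c(msg, "'rho' must not contain missing values")
  else if (any(abs(object@rho) > 1 + 1e-12))
    msg <- c(msg, "all correlations must lie in [-1, 1]")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a DfcSeries
#'
#' @param rho numeric vector of correlations in [-1, 1].
#' @param tr sampling interval in seconds.
#' @return A \linkS4class{DfcSeries}.
#' @export
DfcSeries <- function(rho, tr = 2) {
  new("DfcSeries", rho = as.numeric(rho), tr = as.numeric(tr))
}

# ---------------------------------------------------------------------------
# Model fits
# ---------------------------------------------------------------------------

#' Univariate ARMA-GARCH fit
#'
#' @slot params named numeric: alpha, beta1..p, theta1..q, omega, phi, psi.
#' @slot fittedMean conditional mean sequence mu_t.
#' @slot residuals mean-model residuals eps_t.
#' @slot condSD conditional standard deviations sigma_t.
#' @slot stdResid standardized residuals u_t = eps_t / sigma_t.
#' @slot loglik Gaussian quasi-log-likelihood (variance part).
#' @slot converged logical optimizer convergence flag.
#' @slot meanOrder integer(2), ARMA orders (p, q).
#' @export
setClass("UnivariateFit",
  representation(params = "numeric", fittedMean = "numeric",
                 residuals = "numeric", condSD = "numeric",
                 stdResid = "numeric", loglik = "numeric",
                 converged = "logical", meanOrder = "integer"))

setValidity("UnivariateFit", function(object) {
  p <- object@params
  msg <- character()
  if (!all(c("omega", "phi", "psi") %in% names(p)))
    msg <- c(msg, "params must include omega, phi, psi")
  else {
    if (p["omega"] <= 0) msg <- c(msg, "omega must be positive")
    if (p["phi"] < 0 || p["psi"] < 0 || p["phi"] + p["psi"] >= 1)
      msg <- c(msg, "GARCH parameters must satisfy phi, psi >= 0, phi + psi < 1")
  }
  if (any(object@condSD <= 0)) msg <- c(msg, "conditional SDs must be positive")
  n <- length(object@residuals)
  if (length(object@condSD) != n || length(object@stdResid) != n ||
      length(object@fittedMean) != n)
    msg <- c(msg, "sequence slots must share one length")
  if (length(msg)) msg else TRUE
})

#' DCC correlation-stage fit
#'
#' @slot eta numeric(2): the DCC news and decay parameters (eta1, eta2).
#' @slot xi 2 x 2 unconditional correlation matrix of standardized residuals.
#' @slot q T x 3 matrix of the Q_t components (q11, q12, q22).
#' @slot dfc the estimated correlation trajectory as a \linkS4class{DfcSeries}.
#' @slot loglik correlation part of the Gaussian quasi-log-likelihood.
#' @slot boundary TRUE if the optimum was pinned near the simplex boundary.
#' @export
setClass("DccFit",
  representation(eta = "numeric", xi = "matrix", q = "matrix",
                 dfc = "DfcSeries", loglik = "numeric", boundary = "logical"))

setValidity("DccFit", function(object) {
  msg <- character()
  e <- object@eta
  if (length(e) != 2L || any(e < 0) || sum(e) >= 1)
    msg <- c(msg, "eta must satisfy eta1, eta2 >= 0 and eta1 + eta2 < 1")
  if (!all(dim(object@xi) == c(2L, 2L)) ||
      abs(object@xi[1, 2] - object@xi[2, 1]) > 1e-12)
    msg <- c(msg, "xi must be a symmetric 2 x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Full two-step dFC fit
#'
#' Bundle returned by \code{\link{estimateDfc}}: the dFC trajectory, the two
#' marginal ARMA-GARCH fits, the DCC stage and Ljung-Box diagnostics of the
#' standardized residuals.
#'
#' @slot dfc estimated \linkS4class{DfcSeries}.
#' @slot marginFits list of two \linkS4class{UnivariateFit}s.
#' @slot dcc the \linkS4class{DccFit}.
#' @slot ljungBox data.frame of Ljung-Box statistics (lag 10) per margin.
#' @slot labels the two network names.
#' @export
setClass("DfcFit",
  representation(dfc = "DfcSeries", marginFits = "list", dcc = "DccFit",
                 ljungBox = "data.frame", labels = "character"))

# ---------------------------------------------------------------------------
# Spectrum
# ---------------------------------------------------------------------------

#' Welch power spectrum of a dFC trajectory
#'
#' One-sided averaged modified periodogram plus the per-segment magnitude
#' spectra that the averaging consumed (needed for spectral flux).
#'
#' @slot freqs frequency grid in Hz, ascending from 0 to Nyquist.
#' @slot power power spectral density per bin (units^2 per Hz).
#' @slot df bin width in Hz.
#' @slot tr sampling interval of the underlying trajectory, seconds.
#' @slot segMags S x K matrix of per-segment magnitude spectra.
#' @slot meanRemoved whether the trajectory mean was removed before analysis.
#' @slot settings list of Welch settings (segment length, overlap, taper).
#' @export
setClass("DfcSpectrum",
  representation(freqs = "numeric", power = "numeric", df = "numeric",
                 tr = "numeric", segMags = "matrix", meanRemoved = "logical",
                 settings = "list"))

setValidity("DfcSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power must have equal length")
  if (any(object@power < -1e-12)) msg <- c(msg, "power must be nonnegative")
  if (length(object@freqs) && object@freqs[1] != 0)
    msg <- c(msg, "frequency grid must start at 0 (DC bin retained)")
  if (is.unsorted(object@freqs)) msg <- c(msg, "freqs must be ascending")
  if (length(msg)) msg else TRUE
})

#' Construct a DfcSpectrum directly
#'
#' Mainly useful for closed-form test cases; ordinary use goes through
#' \code{\link{welchSpectrum}}.
#'
#' @param freqs,power frequency grid (Hz, starting at 0) and PSD values.
#' @param tr sampling interval in seconds.
#' @param segMags optional per-segment magnitude matrix; defaults to a single
#'   segment equal to the averaged magnitude spectrum.
#' @param meanRemoved logical flag.
#' @param settings list of provenance settings.
#' @return A \linkS4class{DfcSpectrum}.
#' @export
DfcSpectrum <- function(freqs, power, tr = 2, segMags = NULL,
                        meanRemoved = FALSE, settings = list()) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (is.null(segMags)) segMags <- matrix(sqrt(pmax(power, 0)), nrow = 1)
  df <- if (length(freqs) > 1) freqs[2] - freqs[1] else NA_real_
  new("DfcSpectrum", freqs = freqs, power = power, df = df, tr = as.numeric(tr),
      segMags = segMags, meanRemoved = meanRemoved, settings = settings)
}

# ---------------------------------------------------------------------------
# Feature vector
# ---------------------------------------------------------------------------

#' The 17-feature dFC descriptor for one subject and network pair
#'
#' @slot values named numeric of length 17 in \code{\link{dfcFeatureNames}}
#'   order; undefined features (e.g. skewness of a zero-spread spectrum) are
#'   reported as NA, never fabricated.
#' @slot provenance list of every setting used (zero-crossing threshold,
#'   Welch settings, ALFF band, peak bin count).
#' @export
setClass("DfcFeatures",
  representation(values = "numeric", provenance = "list"))

setValidity("DfcFeatures", function(object) {
  if (!identical(names(object@values), dfcFeatureNames()))
    return("values must be named exactly by dfcFeatureNames()")
  TRUE
})

# ---------------------------------------------------------------------------
# Simulation specs
# ---------------------------------------------------------------------------

#' Specification of one simulated subject
#'
#' Defines the generative ARMA(2,2) means, GARCH(1,1) conditional variances
#' and the correlation regime (DCC recursion or a deterministically
#' prescribed trajectory) for a bivariate series.
#'
#' @slot nTime number of recorded time points T.
#' @slot tr sampling interval in seconds.
#' @slot meanParams list of two lists with elements alpha, beta (length 2),
#'   theta (length 2).
#' @slot varParams list of two lists with elements omega, phi, psi.
#' @slot mode list with element \code{type} in \{"dcc", "constant",
#'   "sinusoid", "step"\} plus its parameters.
#' @slot seed integer seed.
#' @export
setClass("SimulationSpec",
  representation(nTime = "integer", tr = "numeric", meanParams = "list",
                 varParams = "list", mode = "list", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nTime < 1L) msg <- c(msg, "nTime must be positive")
  for (j in 1:2) {
    vp <- object@varParams[[j]]
    if (vp$omega <= 0) msg <- c(msg, "omega must be positive")
    if (vp$phi < 0 || vp$psi < 0 || vp$phi + vp$psi >= 1)
      msg <- c(msg, "non-stationary variance parameters: need phi + psi < 1")
  }
  m <- object@mode
  msg <- c(msg, switch(m$type,
    dcc = {
      ok <- m$eta[1] >= 0 && m$eta[2] >= 0 && sum(m$eta) < 1
      xi <- m$xi
      okxi <- all(dim(xi) == 2L) && abs(xi[1, 2]) <= 1 &&
        all(diag(xi) == 1) && abs(xi[1, 2] - xi[2, 1]) < 1e-12
      c(if (!ok) "need eta1, eta2 >= 0 and eta1 + eta2 < 1",
        if (!okxi) "xi must be a valid 2 x 2 correlation matrix")
    },
    constant = if (abs(m$rho) > 1) "|rho| must be <= 1",
    sinusoid = if (abs(m$offset) + abs(m$amplitude) > 1)
      "|offset| + |amplitude| must be <= 1 so that |rho(t)| <= 1",
    step = if (max(abs(c(m$rho_before, m$rho_after))) > 1)
      "|rho| must be <= 1 in both regimes",
    "unknown correlation mode"))
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' Defaults describe a realistic resting-state dFC regime: T = 450 samples at
#' TR = 2 s (a 15-minute scan), a mildly autocorrelated ARMA(2,2) mean,
#' persistent but stationary GARCH(1,1) variances, and a DCC-driven
#' correlation.
#'
#' @param nTime number of recorded time points.
#' @param tr sampling interval in seconds.
#' @param meanParams list of two lists (alpha, beta, theta); a single list is
#'   recycled to both series.
#' @param varParams list of two lists (omega, phi, psi); recycled likewise.
#' @param mode correlation regime, from \code{\link{dccMode}},
#'   \code{\link{constantMode}}, \code{\link{sinusoidMode}} or
#'   \code{\link{stepMode}}.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationSpec}.
#' @export
#' @examples
#' spec <- SimulationSpec(nTime = 300, mode = constantMode(0.5), seed = 1)
SimulationSpec <- function(nTime = 450L, tr = 2,
                           meanParams = list(alpha = 0, beta = c(0.25, -0.1),
                                             theta = c(0.15, 0.05)),
                           varParams = list(omega = 0.05, phi = 0.10,
                                            psi = 0.85),
                           mode = dccMode(), seed = 1L) {
  if (!is.null(meanParams$alpha)) meanParams <- list(meanParams, meanParams)
  if (!is.null(varParams$omega)) varParams <- list(varParams, varParams)
  new("SimulationSpec", nTime = as.integer(nTime), tr = as.numeric(tr),
      meanParams = meanParams, varParams = varParams, mode = mode,
      seed = as.integer(seed))
}

#' Correlation regimes for simulation
#'
#' \code{dccMode} draws the correlation from the DCC recursion itself;
#' the other three prescribe a deterministic trajectory rho(t) that is
#' recorded exactly as ground truth.
#'
#' @param eta1,eta2 DCC news/decay parameters, eta1 + eta2 < 1.
#' @param xi 2 x 2 unconditional correlation matrix.
#' @param rho constant correlation level.
#' @param amplitude,frequency,offset sinusoid rho(t) = offset +
#'   amplitude * sin(2 pi frequency t TR); frequency in Hz.
#' @param rho_before,rho_after,change_point step regime: correlation switches
#'   from \code{rho_before} to \code{rho_after} at sample \code{change_point}.
#' @return A mode list for \code{\link{SimulationSpec}}.
#' @export
dccMode <- function(eta1 = 0.05, eta2 = 0.90,
                    xi = matrix(c(1, 0.3, 0.3, 1), 2)) {
  list(type = "dcc", eta = c(eta1, eta2), xi = xi)
}

#' @rdname dccMode
#' @export
constantMode <- function(rho = 0.3) list(type = "constant", rho = rho)

#' @rdname dccMode
#' @export
sinusoidMode <- function(amplitude = 0.5, frequency = 0.01, offset = 0) {
  list(type = "sinusoid", amplitude = amplitude, frequency = frequency,
       offset = offset)
}

#' @rdname dccMode
#' @export
stepMode <- function(rho_before = 0.6, rho_after = -0.2, change_point = 225L) {
  list(type = "step", rho_before = rho_before, rho_after = rho_after,
       change_point = as.integer(change_point))
}

#' One simulated subject with known ground truth
#'
#' @slot series the generated \linkS4class{BivariateSeries}.
#' @slot trueCorrelation the exact correlation trajectory rho(t), length T.
#' @slot spec the \linkS4class{SimulationSpec} that produced it.
#' @export
setClass("SimulatedSubject",
  representation(series = "BivariateSeries", trueCorrelation = "numeric",
                 spec = "SimulationSpec"))

setValidity("SimulatedSubject", function(object) {
  if (length(object@trueCorrelation) != nrow(object@series@values))
    return("series and trueCorrelation must both have length T")
  if (any(abs(object@trueCorrelation) > 1 + 1e-12))
    return("|true correlation| must be <= 1 everywhere")
  TRUE
})

#' Specification of a two-group synthetic cohort
#'
#' @slot nPerGroup integer(2): subjects in group 0 and group 1.
#' @slot featureEffects named list; names are feature names from
#'   \code{\link{dfcFeatureNames}}, values are lists with elements
#'   \code{group0} and \code{group1}, each a correlation-mode list that
#'   replaces the base spec's mode for that group.
#' @slot baseSpec shared \linkS4class{SimulationSpec}.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", featureEffects = "list",
                 baseSpec = "SimulationSpec", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 2L))
    msg <- c(msg, "need at least 2 subjects per group")
  fe <- object@featureEffects
  if (length(fe)) {
    if (is.null(names(fe)) || !all(names(fe) %in% dfcFeatureNames()))
      msg <- c(msg, "featureEffects names must be dFC feature names")
    bad <- !vapply(fe, function(x)
      is.list(x) && all(c("group0", "group1") %in% names(x)), TRUE)
    if (any(bad)) msg <- c(msg, "each effect needs group0 and group1 settings")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nPerGroup integer(2); defaults to the 23 control / 25 patient
#'   layout typical of single-site clinical resting-state studies.
#' @param featureEffects see \linkS4class{CohortSpec}; empty list means the
#'   two groups are generatively identical (a null cohort).
#' @param baseSpec shared subject-level spec.
#' @param seed integer seed.
#' @return A \linkS4class{CohortSpec}.
#' @export
CohortSpec <- function(nPerGroup = c(23L, 25L), featureEffects = list(),
                       baseSpec = SimulationSpec(), seed = 1L) {
  new("CohortSpec", nPerGroup = as.integer(nPerGroup),
      featureEffects = featureEffects, baseSpec = baseSpec,
      seed = as.integer(seed))
}

#' A generated cohort
#'
#' @slot subjects list of \linkS4class{SimulatedSubject}.
#' @slot manifest data.frame with columns subject_id, label.
#' @slot spec the \linkS4class{CohortSpec}.
#' @export
setClass("SimulatedCohort",
  representation(subjects = "list", manifest = "data.frame",
                 spec = "CohortSpec"))
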