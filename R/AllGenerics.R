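#' Accessors for dynConn objects
#'
#' @param x an object from this package.
#' @return \code{rho} returns the correlation trajectory; \code{samplingInterval}
#'   the TR in seconds; \code{nTimepoints} the series length;
#'   \code{featureValues} the named 17-feature vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setMethod("rho", "DfcSeries", function(x) x@rho)

#' @rdname accessors
#' @export
setMethod("rho", "DfcFit", function(x) x@dfc@rho)

#' @rdname accessors
#' @export
setMethod("rho", "DccFit", function(x) x@dfc@rho)

#' @rdname accessors
#' @export
setMethod("samplingInterval", "DfcSeries", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("samplingInterval", "BivariateSeries", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("samplingInterval", "DfcSpectrum", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("nTimepoints", "DfcSeries", function(x) length(x@rho))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "BivariateSeries", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("featureValues", "DfcFeatures", function(x) x@values)

setMethod("show", "BivariateSeries", function(object) {
  cat("BivariateSeries:", paste(object@labels, collapse = " ~ "),
      sprintf("| T = %d, TR = %g s\n", nrow(object@values), object@tr))
})

setMethod("show", "DfcSeries", function(object) {
  r <- object@rho
  cat(sprintf("DfcSeries: T = %d, TR = %g s | mean %.3f, range [%.3f, %.3f]\n",
              length(r), object@tr, mean(r), min(r), max(r)))
})

setMethod("show", "UnivariateFit", function(object) {
  cat("UnivariateFit (ARMA(", object@meanOrder[1], ",", object@meanOrder[2],
      ")-GARCH(1,1))\n", sep = "")
  print(round(object@params, 4))
  cat(sprintf("logLik (variance part): %.3f | converged: %s\n",
              object@loglik, object@converged))
})

setMethod("show", "DccFit", function(object) {
  cat(sprintf("DccFit: eta1 = %.4f, eta2 = %.4f, xi12 = %.4f | logLik %.3f%s\n",
              object@eta[1], object@eta[2], object@xi[1, 2], object@loglik,
              if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "DfcFit", function(object) {
  cat("DfcFit:", paste(object@labels, collapse = " ~ "), "\n")
  show(object@dfc)
  show(object@dcc)
})

setMethod("show", "DfcSpectrum", function(object) {
  cat(sprintf(
    "DfcSpectrum: %d bins, df = %.4g Hz, Nyquist = %.3g Hz, %d segments%s\n",
    length(object@freqs), object@df, max(object@freqs), nrow(object@segMags),
    if (object@meanRemoved) " (mean removed)" else ""))
})

setMethod("show", "DfcFeatures", function(object) {
  cat("DfcFeatures (17 temporal + spectral dFC features):\n")
  print(round(object@values, 4))
})

setMethod("show", "SimulatedCohort", function(object) {
  tab <- table(object@manifest$label)
  cat("SimulatedCohort:", nrow(object@manifest), "subjects (",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), ")\n")
})
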