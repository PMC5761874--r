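#' Temporal features of a dFC trajectory
#'
#' Computes the four time-domain features: mean value (MV), unbiased sample
#' variance (VAR), proportion of anticorrelated volumes (PAV, the fraction of
#' time points with strictly negative dFC) and zero-crossing rate (ZC, the
#' fraction of the T - 1 consecutive pairs whose product is negative and
#' whose jump is at least \code{c}; the threshold suppresses sign flips due
#' to low-level noise).
#'
#' @param dfc a \linkS4class{DfcSeries} (or bare numeric vector).
#' @param c zero-crossing noise threshold, default 0.001.
#' @return Named numeric: MV, VAR, PAV, ZC.
#' @export
#' @examples
#' temporalFeatures(DfcSeries(c(0.4, -0.4, 0.4, -0.4)))
temporalFeatures <- function(dfc, c = 0.001) {
  r <- if (is(dfc, "DfcSeries")) dfc@rho else as.numeric(dfc)
  n <- length(r)
  if (n < 2L) stop("need at least 2 time points for VAR and ZC")
  if (c < 0) stop("'c' must be nonnegative")
  mv <- mean(r)
  d <- r[-1] - r[-n]
  cross <- (r[-n] * r[-1] < 0) & (abs(d) >= c)
  c(MV = mv,
    VAR = sum((r - mv)^2) / (n - 1),
    PAV = mean(r < 0),
    ZC = sum(cross) / (n - 1))
}

#' Welch power spectral density of a dFC trajectory
#'
#' Averaged modified periodogram over Hann-tapered overlapping segments,
#' one-sided, normalized so that the integrated PSD approximates the signal's
#' mean square (Parseval). Per-segment magnitude spectra are retained for the
#' spectral-flux feature.
#'
#' @param dfc a \linkS4class{DfcSeries} or numeric vector.
#' @param tr sampling interval in seconds (taken from the object if given).
#' @param segmentLength samples per segment; default \code{min(T, 128)},
#'   which keeps at least 3 segments at typical resting-state lengths while
#'   resolving the 0.01 Hz band edge.
#' @param overlap fractional segment overlap in [0, 1), default 0.5.
#' @param removeMean subtract the trajectory mean before analysis (used for
#'   the dominant-frequency and low-frequency-amplitude features, where a DC
#'   peak is uninformative).
#' @return A \linkS4class{DfcSpectrum}.
#' @export
#' @examples
#' s <- welchSpectrum(DfcSeries(sin(2 * pi * 0.05 * 2 * (0:299)), tr = 2))
#' s@freqs[which.max(s@power)]
welchSpectrum <- function(dfc, tr = NULL, segmentLength = NULL, overlap = 0.5,
                          removeMean = FALSE) {
  if (is(dfc, "DfcSeries")) {
    x <- dfc@rho
    if (is.null(tr)) tr <- dfc@tr
  } else {
    x <- as.numeric(dfc)
    if (is.null(tr)) tr <- 2
  }
  n <- length(x)
  if (is.null(segmentLength)) segmentLength <- min(n, 128L)
  segmentLength <- as.integer(segmentLength)
  if (segmentLength < 8L) stop("segment length must be at least 8 samples")
  if (n < segmentLength)
    stop("series (", n, ") is shorter than one segment (", segmentLength,
         "); choose a smaller segment length")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (removeMean) x <- x - mean(x)

  fs <- 1 / tr
  # symmetric Hann taper: reversal-symmetric, so time-reversing the
  # trajectory leaves the averaged spectrum unchanged
  w <- 0.5 * (1 - cos(2 * pi * seq(0, segmentLength - 1) / (segmentLength - 1)))
  U <- sum(w^2)
  hop <- max(1L, as.integer(round(segmentLength * (1 - overlap))))
  starts <- seq(1L, n - segmentLength + 1L, by = hop)

  seg <- vapply(starts,
                function(s) x[s:(s + segmentLength - 1L)] * w,
                numeric(segmentLength))
  ft <- stats::mvfft(seg)
  K <- segmentLength %/% 2L + 1L
  psdSeg <- (Mod(ft[seq_len(K), , drop = FALSE])^2) / (fs * U)
  # one-sided: double everything except DC (and Nyquist when n is even)
  scale <- rep(2, K); scale[1] <- 1
  if (segmentLength %% 2L == 0L) scale[K] <- 1
  psdSeg <- psdSeg * scale

  power <- rowMeans(psdSeg)
  freqs <- (seq_len(K) - 1L) * fs / segmentLength
  new("DfcSpectrum", freqs = freqs, power = power, df = fs / segmentLength,
      tr = tr, segMags = t(sqrt(psdSeg)), meanRemoved = removeMean,
      settings = list(segment_length = segmentLength, overlap = overlap,
                      taper = "hann", n_segments = length(starts)))
}

# magnitude weights for the moment/shape features: sqrt of the PSD
specMags <- function(spec) sqrt(pmax(spec@power, 0))

#' Spectral-moment features
#'
#' Spectral centroid (SCO), spread (SPR), skewness (SKW), excess kurtosis
#' (KURT), median frequency (SMED: smallest frequency at which the cumulative
#' magnitude reaches half the total) and rolloff (SRO: smallest frequency
#' reaching 85\% of the total), all with the magnitude spectrum as weights.
#' SPR is the second central spectral moment; SKW and KURT normalize by
#' SPR^1.5 and SPR^2 respectively. A spectrum with zero spread leaves SKW and
#' KURT undefined (NA).
#'
#' @param spec a \linkS4class{DfcSpectrum}.
#' @return Named numeric: SCO, SPR, SKW, KURT, SMED, SRO (frequencies in Hz).
#' @export
spectralMomentFeatures <- function(spec) {
  stopifnot(is(spec, "DfcSpectrum"))
  M <- specMags(spec)
  f <- spec@freqs
  tot <- sum(M)
  if (tot <= 0) stop("all-zero spectrum: spectral moments are undefined")
  sco <- sum(f * M) / tot
  spr <- sum((f - sco)^2 * M) / tot
  if (spr > 0) {
    skw <- (sum((f - sco)^3 * M) / tot) / spr^1.5
    kurt <- (sum((f - sco)^4 * M) / tot) / spr^2 - 3
  } else {
    skw <- NA_real_; kurt <- NA_real_
  }
  cum <- cumsum(M)
  c(SCO = sco, SPR = spr, SKW = skw, KURT = kurt,
    SMED = f[which(cum >= 0.5 * tot)[1]],
    SRO = f[which(cum >= 0.85 * tot)[1]])
}

#' Spectral-shape features
#'
#' On the mean-retained spectrum: spectral crest (CREST, max over arithmetic
#' mean of the magnitudes), flatness (FLAT, geometric over arithmetic mean;
#' zero if any magnitude is zero), power spectral entropy (PSE, Shannon
#' entropy in bits of the unit-sum-normalized PSD), spectral slope (SLOPE,
#' least-squares slope of magnitude on frequency) and flux (FLUX, mean L2
#' distance between unit-sum-normalized magnitude spectra of consecutive
#' Welch segments). On the mean-removed spectrum with the DC bin excluded:
#' dominant frequency (PEAK, the frequency of the maximum PSD inside the
#' equal-width frequency bin with the largest average power) and the
#' low-frequency fluctuation amplitude (ALFF_dFC, mean square-root PSD over
#' the band, default 0.01-0.08 Hz).
#'
#' @param spec mean-retained \linkS4class{DfcSpectrum}.
#' @param specMeanRemoved mean-removed \linkS4class{DfcSpectrum} for
#'   PEAK/ALFF; defaults to \code{spec} if it already has
#'   \code{meanRemoved = TRUE}.
#' @param band numeric(2), ALFF band in Hz.
#' @param peakBins number of equal-width frequency bins for PEAK, default 8.
#' @return Named numeric: PEAK, CREST, FLUX, SLOPE, FLAT, PSE, ALFF_dFC.
#' @export
spectralShapeFeatures <- function(spec, specMeanRemoved = NULL,
                                  band = c(0.01, 0.08), peakBins = 8L) {
  stopifnot(is(spec, "DfcSpectrum"))
  if (is.null(specMeanRemoved)) {
    if (!spec@meanRemoved)
      stop("supply a mean-removed spectrum for PEAK and ALFF_dFC")
    specMeanRemoved <- spec
  }
  M <- specMags(spec)
  f <- spec@freqs
  am <- mean(M)
  if (am <= 0) stop("all-zero spectrum: shape features are undefined")
  crest <- max(M) / am
  flat <- if (any(M == 0)) 0 else exp(mean(log(M))) / am
  p <- spec@power / sum(spec@power)
  pse <- -sum(ifelse(p > 0, p * log2(p), 0))
  slope <- sum((f - mean(f)) * (M - am)) / sum((f - mean(f))^2)

  segs <- spec@segMags
  flux <- if (nrow(segs) >= 2L) {
    tots <- rowSums(segs)
    norm <- segs / ifelse(tots > 0, tots, 1)
    mean(sqrt(rowSums((norm[-1, , drop = FALSE] -
                         norm[-nrow(norm), , drop = FALSE])^2)))
  } else NA_real_

  f0 <- specMeanRemoved@freqs
  p0 <- specMeanRemoved@power
  keep <- f0 > 0
  f0 <- f0[keep]; p0 <- p0[keep]
  nyq <- 1 / (2 * specMeanRemoved@tr)
  if (all(p0 <= 0)) {
    peak <- NA_real_
  } else {
    breaks <- seq(0, nyq, length.out = peakBins + 1L)
    bin <- findInterval(f0, breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    avg <- tapply(p0, bin, mean)
    top <- as.integer(names(avg)[which.max(avg)])
    inbin <- bin == top
    peak <- f0[inbin][which.max(p0[inbin])]
  }
  if (band[1] >= band[2] || band[2] <= 0)
    stop("ALFF band must be a nonempty frequency interval")
  inband <- f0 >= band[1] & f0 <= band[2]
  if (!any(inband)) stop("ALFF band contains no frequency bins")
  alff <- mean(sqrt(pmax(p0[inband], 0)))

  c(PEAK = unname(peak), CREST = crest, FLUX = flux, SLOPE = slope,
    FLAT = flat, PSE = pse, ALFF_dFC = alff)
}

#' Extract the full 17-feature dFC descriptor
#'
#' Runs the temporal features and two Welch passes (mean retained for the
#' moment and shape features; mean removed for PEAK and ALFF_dFC, whose DC
#' peak carries no information) and assembles the
#' \linkS4class{DfcFeatures} vector. Features that are undefined on a given
#' trajectory (e.g. spectral moments of an exactly-zero series) are reported
#' as NA; the rest of the vector is still produced.
#'
#' @param dfc a \linkS4class{DfcSeries}.
#' @param c zero-crossing threshold, default 0.001.
#' @param segmentLength,overlap Welch settings (see
#'   \code{\link{welchSpectrum}}).
#' @param band ALFF band in Hz, default c(0.01, 0.08).
#' @param peakBins PEAK bin count, default 8.
#' @return A \linkS4class{DfcFeatures}.
#' @export
#' @examples
#' dfc <- DfcSeries(0.3 + 0.2 * sin(2 * pi * 0.02 * 2 * (0:449)), tr = 2)
#' featureValues(extractFeatureVector(dfc))
extractFeatureVector <- function(dfc, c = 0.001, segmentLength = NULL,
                                 overlap = 0.5, band = c(0.01, 0.08),
                                 peakBins = 8L) {
  stopifnot(is(dfc, "DfcSeries"))
  tf <- temporalFeatures(dfc, c = c)
  spec <- welchSpectrum(dfc, segmentLength = segmentLength, overlap = overlap,
                        removeMean = FALSE)
  spec0 <- welchSpectrum(dfc, segmentLength = segmentLength, overlap = overlap,
                         removeMean = TRUE)
  na6 <- c(SCO = NA_real_, SPR = NA_real_, SKW = NA_real_, KURT = NA_real_,
           SMED = NA_real_, SRO = NA_real_)
  mom <- tryCatch(spectralMomentFeatures(spec), error = function(e) na6)
  shp <- tryCatch(
    spectralShapeFeatures(spec, spec0, band = band, peakBins = peakBins),
    error = function(e) {
      alff <- if (all(spec0@power <= 0)) 0 else NA_real_
      c(PEAK = NA_real_, CREST = NA_real_, FLUX = NA_real_, SLOPE = NA_real_,
        FLAT = NA_real_, PSE = NA_real_, ALFF_dFC = alff)
    })
  vals <- c(tf, mom, shp)[dfcFeatureNames()]
  names(vals) <- dfcFeatureNames()
  new("DfcFeatures", values = vals,
      provenance = list(c = c, welch = spec@settings, band = band,
                        peak_bins = as.integer(peakBins),
                        tr = dfc@tr, n_time = length(dfc@rho)))
}
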