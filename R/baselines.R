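#' Static functional connectivity
#'
#' Full-length Pearson correlation between the two network time courses, the
#' classical static-FC estimate that the dynamic features are compared
#' against.
#'
#' @param series a \linkS4class{BivariateSeries} or T x 2 numeric matrix.
#' @return A single correlation in [-1, 1].
#' @export
staticFC <- function(series) {
  v <- if (is(series, "BivariateSeries")) series@values else as.matrix(series)
  if (var(v[, 1]) == 0 || var(v[, 2]) == 0)
    stop("static FC undefined: a column is constant")
  cor(v[, 1], v[, 2])
}

#' Sliding-window dynamic functional connectivity
#'
#' Pearson correlation inside a rectangular window slid across the series
#' (default 80 s with 50\% overlap). The hop is rounded to the nearest sample
#' (minimum 1) and trailing partial windows are discarded. Returns the
#' windowed correlation series plus its mean (SW_Mean) and unbiased variance
#' (SW_Var), the two summaries commonly used in sliding-window dFC analysis.
#'
#' @param series a \linkS4class{BivariateSeries}.
#' @param windowSeconds window length in seconds, default 80.
#' @param overlap fractional overlap in [0, 1), default 0.5.
#' @return list with \code{window_rho}, \code{center_s} (window centers in
#'   seconds), \code{SW_Mean}, \code{SW_Var}, and the window/hop sizes in
#'   samples.
#' @export
#' @examples
#' sub <- simulateSubject(SimulationSpec(nTime = 300,
#'                                       mode = constantMode(0.8), seed = 1))
#' slidingWindowDfc(sub@series)$SW_Mean
slidingWindowDfc <- function(series, windowSeconds = 80, overlap = 0.5) {
  stopifnot(is(series, "BivariateSeries"))
  v <- series@values
  n <- nrow(v)
  w <- as.integer(round(windowSeconds / series@tr))
  if (w < 3L) stop("window must span at least 3 samples")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (w > n) stop("window (", w, " samples) is longer than the series (", n, ")")
  hop <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(1L, n - w + 1L, by = hop)
  r <- vapply(starts, function(s) {
    seg <- v[s:(s + w - 1L), ]
    cor(seg[, 1], seg[, 2])
  }, numeric(1))
  list(window_rho = r,
       center_s = (starts - 1 + (w - 1) / 2) * series@tr,
       SW_Mean = mean(r),
       SW_Var = var(r),
       window_samples = w, hop_samples = hop)
}
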