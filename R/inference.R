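#' BCa bootstrap confidence interval for a difference in group means
#'
#' Ordinary nonparametric bootstrap (default 1000 resamples) of
#' \code{mean(x) - mean(y)}, resampling each group independently, with
#' bias-corrected and accelerated interval endpoints. The bias-correction
#' factor z0 comes from the fraction of bootstrap statistics below the
#' observed value; the acceleration factor from the jackknife skewness of the
#' statistic (leave-one-out over both groups). A two-sided p-value is
#' obtained by interval inversion: the smallest alpha at which the BCa
#' interval excludes zero, found by bisection.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param B number of bootstrap resamples, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param z0,accel optional overrides of the bias-correction and acceleration
#'   factors; setting both to 0 reduces the interval to the plain percentile
#'   interval of the same bootstrap draws.
#' @return list with observed_diff, boot_samples, z0, a, ci (lo, hi), level,
#'   p_value, B, degenerate flag.
#' @export
#' @examples
#' res <- bcaDiffMeans(rnorm(25, 1), rnorm(23, 0), B = 500, seed = 1)
#' res$ci
bcaDiffMeans <- function(x, y, B = 1000L, level = 0.95, seed = NULL,
                         z0 = NULL, accel = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 observations")
  if (B < 100L) stop("need at least 100 bootstrap resamples")
  obs <- mean(x) - mean(y)

  stat <- withSeed(seed, {
    bx <- rowMeans(matrix(x[sample.int(nx, nx * B, replace = TRUE)], B))
    by <- rowMeans(matrix(y[sample.int(ny, ny * B, replace = TRUE)], B))
    bx - by
  })

  degenerate <- var(stat) == 0
  if (is.null(z0)) {
    fr <- (sum(stat < obs) + 0.5 * sum(stat == obs)) / B
    fr <- min(max(fr, 0.5 / B), 1 - 0.5 / B)
    z0 <- stats::qnorm(fr)
  }
  if (is.null(accel)) {
    # jackknife over the combined sample, recomputing the group means
    jk <- c(vapply(seq_len(nx), function(i) mean(x[-i]) - mean(y), 0),
            vapply(seq_len(ny), function(i) mean(x) - mean(y[-i]), 0))
    d <- mean(jk) - jk
    denom <- sum(d^2)^1.5
    accel <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  }

  bcaCI <- function(alpha) {
    if (degenerate) return(c(stat[1], stat[1]))
    if (z0 == 0 && accel == 0) {
      # exact percentile reduction
      a1 <- alpha / 2; a2 <- 1 - alpha / 2
    } else {
      zlo <- stats::qnorm(alpha / 2); zhi <- stats::qnorm(1 - alpha / 2)
      a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - accel * (z0 + zlo)))
      a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - accel * (z0 + zhi)))
    }
    unname(stats::quantile(stat, c(a1, a2), names = FALSE))
  }

  alpha <- 1 - level
  ci <- bcaCI(alpha)

  excludes0 <- function(alpha) {
    ci <- bcaCI(alpha)
    ci[1] > 0 || ci[2] < 0
  }
  if (degenerate) {
    p <- if (stat[1] == 0) 1 else 0
  } else if (excludes0(1e-6)) {
    p <- 1e-6
  } else if (!excludes0(1 - 1e-6)) {
    p <- 1
  } else {
    lo <- 1e-6; hi <- 1 - 1e-6
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (excludes0(mid)) hi <- mid else lo <- mid
    }
    p <- hi
  }

  list(observed_diff = obs, boot_samples = stat, z0 = z0, a = accel,
       ci = ci, level = level, p_value = p, B = as.integer(B),
       degenerate = degenerate)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values with enforced monotonicity, and rejection flags
#' at level \code{q}.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q FDR level, default 0.05.
#' @return list with \code{adjusted} and logical \code{rejected}.
#' @export
#' @examples
#' bhFdr(c(0.001, 0.02, 0.04, 0.2))
bhFdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Compare dFC features between two groups
#'
#' One BCa bootstrap interval per feature (and network pair, if present) for
#' the difference in group means, with BH-FDR control across the whole family
#' of tests (optionally per network pair). The sign convention is
#' \code{mean(group A) - mean(group B)} where group A is the first level of
#' \code{groups} (e.g. healthy controls), so positive differences mean larger
#' values in group A. Missing feature values are dropped pairwise-complete
#' and the per-test sample sizes reported.
#'
#' @param features numeric matrix, rows = features (rownames required),
#'   columns = subjects; or a SummarizedExperiment whose first assay is such
#'   a matrix with a \code{label} column in its colData.
#' @param labels subject group labels (ignored for a SummarizedExperiment).
#' @param groups character(2) giving the order (A, B) of the comparison;
#'   default: sorted unique labels.
#' @param pair optional character vector assigning each row to a network
#'   pair (used for per-pair FDR families and carried into the report).
#' @param B,level bootstrap settings.
#' @param q FDR level, default 0.05.
#' @param family \code{"all"} (one FDR family across every test, default) or
#'   \code{"per-pair"}.
#' @param seed integer seed; per-test seeds are derived from it.
#' @return data.frame: feature, pair, n_A, n_B, diff, ci_lo, ci_hi, p_raw,
#'   p_adj, rejected.
#' @export
compareGroups <- function(features, labels = NULL, groups = NULL, pair = NULL,
                          B = 1000L, level = 0.95, q = 0.05,
                          family = c("all", "per-pair"), seed = 1L) {
  family <- match.arg(family)
  if (is(features, "SummarizedExperiment")) {
    labels <- SummarizedExperiment::colData(features)$label
    if (is.null(pair) &&
        "pair" %in% names(SummarizedExperiment::rowData(features)))
      pair <- SummarizedExperiment::rowData(features)$pair
    features <- SummarizedExperiment::assay(features)
  }
  features <- as.matrix(features)
  if (is.null(rownames(features))) stop("feature rows must be named")
  if (is.null(labels) || length(labels) != ncol(features))
    stop("need one group label per subject column")
  if (is.null(groups)) groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  inA <- labels == groups[1]; inB <- labels == groups[2]
  if (sum(inA) < 2L || sum(inB) < 2L)
    stop("each group needs at least 2 subjects")
  if (is.null(pair)) pair <- rep(NA_character_, nrow(features))

  rows <- lapply(seq_len(nrow(features)), function(i) {
    xa <- features[i, inA]; xb <- features[i, inB]
    nA <- sum(!is.na(xa)); nB <- sum(!is.na(xb))
    if (nA < 2L || nB < 2L) {
      # feature undefined for (almost) every subject: report, exclude from FDR
      return(data.frame(feature = rownames(features)[i], pair = pair[i],
                        n_A = nA, n_B = nB, diff = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    res <- bcaDiffMeans(xa[!is.na(xa)], xb[!is.na(xb)], B = B, level = level,
                        seed = childSeed(seed, i))
    data.frame(feature = rownames(features)[i], pair = pair[i],
               n_A = nA, n_B = nB,
               diff = res$observed_diff, ci_lo = res$ci[1], ci_hi = res$ci[2],
               p_raw = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  out$p_adj <- NA_real_; out$rejected <- NA
  fams <- if (family == "all" || all(is.na(out$pair)))
    list(seq_len(nrow(out))) else split(seq_len(nrow(out)), out$pair)
  for (idx in fams) {
    ok <- idx[!is.na(out$p_raw[idx])]
    if (!length(ok)) next
    fdr <- bhFdr(out$p_raw[ok], q = q)
    out$p_adj[ok] <- fdr$adjusted
    out$rejected[ok] <- fdr$rejected
  }
  out
}
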