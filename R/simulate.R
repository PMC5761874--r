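#' Simulate one bivariate subject with known time-varying correlation
#'
#' Generates a pair of BOLD-like time courses from the generative
#' ARMA(2,2)-GARCH(1,1)-DCC model with Gaussian innovations. In
#' \code{"dcc"} mode the correlation follows the DCC recursion itself and the
#' realized trajectory is recorded as ground truth; in the deterministic
#' modes (\code{"constant"}, \code{"sinusoid"}, \code{"step"}) the prescribed
#' rho(t) is imposed exactly at every time point by Cholesky factorization of
#' the 2 x 2 correlation, so the ground truth is known independently of the
#' DCC dynamics. A burn-in of 200 samples is generated and discarded so that
#' initial-condition transients never reach the recorded series; conditional
#' variances start at the unconditional level omega / (1 - phi - psi) and the
#' DCC recursion at Q_1 = Xi.
#'
#' @param spec a \code{\link{SimulationSpec}}.
#' @param burnin number of leading samples to discard (default 200).
#' @return A \linkS4class{SimulatedSubject}: the series, the exact
#'   correlation trajectory, and the spec.
#' @export
#' @examples
#' sub <- simulateSubject(SimulationSpec(nTime = 300,
#'                                       mode = constantMode(0.5), seed = 7))
#' cor(sub@series@values[, 1], sub@series@values[, 2])
simulateSubject <- function(spec, burnin = 200L) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  nT <- spec@nTime
  tot <- nT + as.integer(burnin)
  mode <- spec@mode

  withSeed(spec@seed, {
    zs <- matrix(stats::rnorm(tot * 2), tot, 2)

    u <- matrix(0, tot, 2)
    if (mode$type == "dcc") {
      eta1 <- mode$eta[1]; eta2 <- mode$eta[2]; xi <- mode$xi
      rhoAll <- numeric(tot)
      q11 <- xi[1, 1]; q12 <- xi[1, 2]; q22 <- xi[2, 2]
      for (t in seq_len(tot)) {
        if (t > 1) {
          w <- 1 - eta1 - eta2
          q11 <- w * xi[1, 1] + eta1 * u[t - 1, 1]^2 + eta2 * q11
          q12 <- w * xi[1, 2] + eta1 * u[t - 1, 1] * u[t - 1, 2] + eta2 * q12
          q22 <- w * xi[2, 2] + eta1 * u[t - 1, 2]^2 + eta2 * q22
        }
        r <- q12 / sqrt(q11 * q22)
        rhoAll[t] <- r
        u[t, 1] <- zs[t, 1]
        u[t, 2] <- r * zs[t, 1] + sqrt(1 - r^2) * zs[t, 2]
      }
    } else {
      rhoRec <- switch(mode$type,
        constant = rep(mode$rho, nT),
        sinusoid = mode$offset + mode$amplitude *
          sin(2 * pi * mode$frequency * (seq_len(nT) - 1L) * spec@tr),
        step = ifelse(seq_len(nT) < mode$change_point,
                      mode$rho_before, mode$rho_after))
      if (any(abs(rhoRec) > 1))
        stop("prescribed correlation trajectory leaves [-1, 1]")
      rhoAll <- c(rep(rhoRec[1], tot - nT), rhoRec)
      u[, 1] <- zs[, 1]
      u[, 2] <- rhoAll * zs[, 1] + sqrt(1 - rhoAll^2) * zs[, 2]
    }

    vals <- matrix(0, tot, 2)
    for (j in 1:2) {
      vp <- spec@varParams[[j]]
      mp <- spec@meanParams[[j]]
      sig2 <- vp$omega / (1 - vp$phi - vp$psi)
      eps <- numeric(tot)
      for (t in seq_len(tot)) {
        if (t > 1)
          sig2 <- vp$omega + vp$phi * eps[t - 1]^2 + vp$psi * sig2
        eps[t] <- sqrt(sig2) * u[t, j]
      }
      bsum <- sum(mp$beta)
      z0 <- if (abs(1 - bsum) > 1e-8) mp$alpha / (1 - bsum) else 0
      zlag <- c(z0, z0); elag <- c(0, 0)
      for (t in seq_len(tot)) {
        zt <- mp$alpha + mp$beta[1] * zlag[1] + mp$beta[2] * zlag[2] -
          mp$theta[1] * elag[1] - mp$theta[2] * elag[2] + eps[t]
        vals[t, j] <- zt
        zlag <- c(zt, zlag[1]); elag <- c(eps[t], elag[1])
      }
    }

    keep <- (tot - nT + 1L):tot
    series <- BivariateSeries(vals[keep, , drop = FALSE], tr = spec@tr)
    new("SimulatedSubject", series = series,
        trueCorrelation = rhoAll[keep], spec = spec)
  })
}

# Apply one group's effect settings to the base correlation mode: a full mode
# list (has $type) replaces it, a partial list modifies fields in place.
applyModeEffect <- function(mode, effect) {
  if (is.null(effect)) return(mode)
  if (!is.null(effect$type)) return(effect)
  mode[names(effect)] <- effect
  mode
}

#' Generate a two-group cohort with prescribed feature effects
#'
#' The two groups share the base spec; each entry of
#' \code{featureEffects} overrides the correlation regime per group, so the
#' groups differ only in the named generative settings. An empty effect list
#' yields a null cohort (identical generative distributions). Subject seeds
#' are derived deterministically from the cohort seed.
#'
#' @param cohort a \code{\link{CohortSpec}}.
#' @param labels character(2) group labels, default healthy controls vs.
#'   temporal lobe epilepsy.
#' @param requireEffect if TRUE, an empty \code{featureEffects} list is an
#'   error (caller demanded a nonzero effect).
#' @return A \linkS4class{SimulatedCohort}.
#' @export
#' @examples
#' coh <- generateCohort(CohortSpec(nPerGroup = c(5, 5), seed = 3))
#' table(coh@manifest$label)
generateCohort <- function(cohort, labels = c("HC", "TLE"),
                           requireEffect = FALSE) {
  stopifnot(is(cohort, "CohortSpec"))
  validObject(cohort)
  if (requireEffect && length(cohort@featureEffects) == 0L)
    stop("a nonzero effect was demanded but featureEffects is empty")

  base <- cohort@baseSpec
  modes <- list(base@mode, base@mode)
  for (eff in cohort@featureEffects) {
    modes[[1]] <- applyModeEffect(modes[[1]], eff$group0)
    modes[[2]] <- applyModeEffect(modes[[2]], eff$group1)
  }

  n <- cohort@nPerGroup
  subjects <- vector("list", sum(n))
  ids <- character(sum(n)); labs <- character(sum(n))
  k <- 0L
  for (g in 1:2) {
    for (i in seq_len(n[g])) {
      k <- k + 1L
      spec <- base
      spec@mode <- modes[[g]]
      spec@seed <- childSeed(cohort@seed, k)
      validObject(spec)
      subjects[[k]] <- simulateSubject(spec)
      ids[k] <- sprintf("sub%03d", k)
      labs[k] <- labels[g]
    }
  }
  manifest <- data.frame(subject_id = ids, label = labs,
                         stringsAsFactors = FALSE)
  new("SimulatedCohort", subjects = subjects, manifest = manifest,
      spec = cohort)
}
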