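---
title: "Temporal and spectral analysis of dynamic functional connectivity with dynConn"
author: "dynConn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal and spectral analysis of dynamic functional connectivity with dynConn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynConn)
```

## The problem

Resting-state fMRI studies usually summarize the coupling between two brain
networks by a single Pearson correlation over the whole scan (static
functional connectivity, sFC). Coupling, however, fluctuates within a scan,
and those fluctuations — dynamic functional connectivity (dFC) — carry
information that a single correlation discards. dynConn implements a complete
workbench for the model-based alternative: estimate a time-varying
conditional correlation between two network time courses, summarize its
temporal and spectral behaviour in 17 interpretable features, test
group differences in those features, and use them for subject-level
classification against sliding-window and static baselines.

## The model

Let $Z_t = (Z_{1t}, Z_{2t})'$ be the two network time courses, sampled every
TR seconds. Each margin follows an ARMA(2,2) mean,

$$\mu_{jt} = \alpha_j + \beta_{1j} Z_{j,t-1} + \beta_{2j} Z_{j,t-2}
 - \theta_{1j} \epsilon_{j,t-1} - \theta_{2j} \epsilon_{j,t-2},$$

with innovations $\epsilon_t = Z_t - \mu_t$ whose conditional covariance is
$\Sigma_t = D_t R_t D_t$, $D_t = \mathrm{diag}(\sigma_{1t}, \sigma_{2t})$.
The conditional variances are GARCH(1,1),

$$\sigma^2_{jt} = \omega_j + \phi_j \epsilon^2_{j,t-1} + \psi_j \sigma^2_{j,t-1},$$

and the conditional correlation follows the DCC(1,1) recursion on the
standardized residuals $u_t = D_t^{-1}\epsilon_t$:

$$Q_t = (1 - \eta_1 - \eta_2)\,\Xi + \eta_1 u_{t-1}u_{t-1}' + \eta_2 Q_{t-1},
\qquad R_t = \mathrm{diag}(Q_t)^{-1/2} Q_t\, \mathrm{diag}(Q_t)^{-1/2}.$$

The off-diagonal of $R_t$ is the dFC trajectory $\rho_t \in [-1, 1]$, one
value per acquisition; the normalization of $Q_t$ guarantees the bounds by
construction. $\Xi$ is the unconditional correlation of $u_t$ and
$0 \le \eta_1 + \eta_2 < 1$ keeps the recursion stationary.

Both recursions are written in their *lagged* form (driven by
$\epsilon_{t-1}$ and $u_{t-1}u_{t-1}'$). Contemporaneous variants would make
$\sigma_t$ and $Q_t$ functions of the observation they are supposed to
predict, leaving the one-step-ahead Gaussian likelihood ill-posed.

### Two-step estimation

The Gaussian quasi-likelihood separates into a variance part (two univariate
ARMA-GARCH likelihoods) plus a correlation part, so estimation proceeds in
two steps: `fitUnivariateArmaGarch()` maximizes each margin's variance
likelihood, then `fitDcc()` sets $\Xi$ to the sample correlation of the
standardized residuals and maximizes the correlation likelihood over
$(\eta_1, \eta_2)$. `estimateDfc()` composes the steps and reports lag-10
Ljung–Box statistics of the standardized residuals as a whiteness
diagnostic. `logLikelihood()` evaluates the full decomposition; its variance
and correlation parts sum to the total identically.

Numerical choices, all deliberate:

* constraints ($\omega > 0$; $\phi, \psi \ge 0$, $\phi + \psi < 1$; the same
  simplex for $(\eta_1, \eta_2)$) are enforced by reparameterization — log
  for $\omega$, a logistic-simplex map for the persistence pairs — so the
  optimizer works unconstrained;
* ARMA stationarity and invertibility are enforced through the roots of the
  lag polynomials, not coefficient sums;
* BFGS from a fixed table of starting points (varying persistence and
  news/decay split), relative tolerance 1e-10 and 1e-6 numerical-gradient
  steps, so fits are deterministic given the input and the
  finite-difference gradient at the reported optimum is negligible;
* each series is standardized internally and the fit mapped back, making the
  two-step estimate exactly invariant to rescaling either input series —
  correlation is scale-free and the estimator honours that;
* presample values: the first $\max(p, q)$ observations are conditioned on
  ($\epsilon = 0$), $\sigma^2_0$ is the sample variance of the mean-model
  residuals, $Q_1 = \Xi$, and the likelihood is accumulated only over fully
  filtered time points.

One identification caveat matters for interpretation: on data with no
conditional-mean or variance dynamics (e.g. white noise), ARMA(2,2) has
cancelling AR/MA root ridges and $\psi$ is unidentified when $\phi = 0$.
Individual coefficients are then arbitrary along the ridge even though the
fitted conditional mean and variance — and hence the dFC trajectory — are
unaffected. The test suite therefore checks identified quantities (flatness
of the fitted moments, recovery of identified simulations), not raw
coefficients of unidentified fits.

## The 17 dFC features

`extractFeatureVector()` computes, per subject and network pair
(`dfcFeatureNames()` gives the canonical order):

**Temporal** — mean value MV; unbiased variance VAR; proportion of
anticorrelated volumes PAV (fraction of time points with strictly negative
$\rho_t$; exact zeros do not count); zero-crossing rate ZC, the fraction of
the $T-1$ consecutive pairs with $\rho_t \rho_{t+1} < 0$ *and*
$|\rho_{t+1}-\rho_t| \ge c$. The threshold $c$ (default 0.001) suppresses
sign flips caused by low-level noise around zero.

**Spectral**, from Welch power spectra of the trajectory — spectral centroid
SCO, spread SPR, skewness SKW, excess kurtosis KURT (magnitude-weighted
central moments of the frequency distribution; SPR is the second central
moment, and SKW/KURT normalize by SPR$^{1.5}$ and SPR$^2$); median frequency
SMED and rolloff SRO (smallest frequencies reaching 50% and 85% of the
cumulative magnitude; ties resolved to the first qualifying bin; returned in
Hz); dominant frequency PEAK; spectral crest CREST and flatness FLAT (max /
arithmetic mean and geometric / arithmetic mean of the magnitudes); spectral
flux FLUX; spectral slope SLOPE (least-squares slope of magnitude on
frequency); power spectral entropy PSE; and ALFF_dFC, the mean square-root
power over the 0.01–0.08 Hz band, the classical low-frequency fluctuation
band of resting-state fMRI.

Conventions that the formulas leave open were fixed once and recorded in
every output's provenance block:

* **Welch settings.** Symmetric Hann taper, segment length
  $\min(T, 128)$ samples, 50% overlap, one-sided spectrum. At typical scan
  lengths ($T \approx 300$–450 at TR = 2 s) this yields 3–6 segments while
  still resolving the 0.01 Hz ALFF band edge. Normalization satisfies
  Parseval: the integrated PSD matches the signal mean square to within a
  few percent. The *symmetric* Hann window is reversal-symmetric, which
  makes every spectral feature except FLUX exactly invariant to time
  reversal of the trajectory whenever the segment grid tiles the series
  symmetrically ((T − segment) divisible by the hop).
* **Magnitude vs power.** Moment features, SMED/SRO, CREST, FLAT and SLOPE
  weight by the magnitude spectrum $M_k = \sqrt{\mathrm{PSD}_k}$; PSE uses
  the unit-sum-normalized power spectrum; ALFF uses $\sqrt{\mathrm{PSD}}$.
* **Entropy base.** PSE is reported in bits (log base 2); any base is
  monotone-equivalent, one was fixed for reproducibility. A flat K-bin
  spectrum gives the maximum $\log_2 K$.
* **Two spectral passes.** A DC peak is meaningful for the distributional
  features (a strongly positive mean correlation *should* concentrate mass
  at 0 Hz) but uninformative for PEAK and ALFF, so those two are computed
  from a second Welch pass on the mean-removed trajectory with the DC bin
  excluded.
* **PEAK binning.** The Nyquist range is divided into 8 equal-width bins
  (configurable); PEAK is the frequency of the maximum PSD inside the bin
  with the largest average power, which is robust to isolated noisy bins.
* **FLUX.** Welch's averaging consumes per-segment spectra; FLUX is defined
  on exactly those, as the mean L2 distance between unit-sum-normalized
  magnitude spectra of consecutive segments, making it amplitude-invariant.
  It needs at least two segments and is reported as NA otherwise (e.g.
  $T < 1.5 \times$ segment length).
* **Degenerate inputs.** An all-zero spectrum leaves the moment features
  undefined; zero spread leaves SKW/KURT undefined. Undefined features are
  reported as NA, never fabricated, and the rest of the vector is still
  produced.

```{r features-example}
dfc <- DfcSeries(0.2 + 0.5 * sin(2 * pi * 0.01 * 2 * (0:449)), tr = 2)
round(featureValues(extractFeatureVector(dfc)), 4)
```

## Baselines

`staticFC()` is the full-length Pearson correlation. `slidingWindowDfc()`
computes windowed Pearson correlations (default 80 s windows, 50% overlap,
rectangular taper — the sliding-window literature's default) and their mean
and unbiased variance (SW-Mean, SW-Var). Hops are rounded to the nearest
sample with a minimum of 1 and trailing partial windows are discarded.

## Group inference

`bcaDiffMeans()` bootstraps the difference in group means (1000 resamples by
default, resampling each group independently — the stratified, two-sample
scheme) and forms bias-corrected and accelerated (BCa) intervals: the bias
correction $z_0$ comes from the fraction of bootstrap statistics below the
observed value, the acceleration $a$ from leave-one-out jackknife skewness
across both groups. With $z_0 = a = 0$ the interval reduces exactly to the
percentile interval. Because only intervals are defined, two-sided p-values
are obtained by interval inversion — the smallest $\alpha$ at which the BCa
interval excludes zero, found by bisection. `compareGroups()` applies this
per feature with the sign convention mean(group A) − mean(group B) (group A
first, e.g. controls), then controls the false discovery rate with
Benjamini–Hochberg at $q = 0.05$ across the whole family of feature ×
network-pair tests by default (`family = "per-pair"` restricts the family).
Features undefined for nearly all subjects are reported but excluded from
the FDR family. BCa intervals are anti-conservative at very small group
sizes ($n \lesssim 10$ per group); the calibration checks in the test suite
use the intended cohort scale (about 20 per group).

## Classification

`repeatedCv()` runs repeated stratified 5-fold cross-validation (30
replications by default) of a random forest on the 17-feature vector.
Random-forest tuning uses a two-dimensional grid — features-per-split
$\in \{1, \lceil\sqrt p\rceil, \lceil p/3\rceil, p\}$ × minimum node size
$\in \{1, 3, 5\}$, the two standard knobs — by inner cross-validation
*within each training fold*; test folds never touch tuning or fitting.
Forest size is fixed at 500 trees rather than tuned. `runModelComparison()`
evaluates seven designs on *identical fold assignments per repetition*
(a paired comparison): the dFC-feature forest, forests on static FC, on the
sliding-window mean, variance, and both, a logistic classifier on static FC
alone, and the majority-class null. Summaries report the mean accuracy over
replicates with both normal-theory and percentile 95% intervals, since
either convention is defensible for "a CI over replicates".

`conditionalImportance()` implements conditional permutation importance:
for each tree, each feature is permuted among the tree's out-of-bag samples
*within strata* built from the tree's own split points on every feature
whose absolute correlation with it exceeds 0.2 (the customary threshold for
this procedure; configurable). This removes the credit a feature inherits
purely through correlation — the dFC features are strongly collinear, which
is exactly why marginal importance misleads there. With no conditioning
features (or `threshold = Inf`) it reduces to ordinary marginal permutation
importance. Scores are mean decreases in out-of-bag accuracy averaged over
several independently grown forests.

## The synthetic cohort generator

No public single-subject network time courses accompany this kind of
clinical resting-state study, so `simulateSubject()` and `generateCohort()`
define the study conditions for every test: bivariate series of
$T = 450$ samples at TR = 2 s (a 15-minute scan), ARMA(2,2) means with mild
autocorrelation, persistent but stationary GARCH(1,1) variances
($\omega = 0.05, \phi = 0.10, \psi = 0.85$), Gaussian innovations (matching
the Gaussian quasi-likelihood), and a correlation regime that is either the
DCC recursion itself or a deterministically prescribed trajectory
(constant, sinusoid, or step) imposed exactly by Cholesky factorization of
the $2\times2$ correlation at each time point — so ground truth is known
independently of the model being tested. A 200-sample burn-in is discarded;
variances start at their unconditional level and $Q_1 = \Xi$. The default
cohort layout is 23 + 25 subjects, the scale of a single-site clinical
comparison.

What the generator does *not* emulate — and hence what passing tests do not
establish about real fMRI: hemodynamic convolution, scanner drift and
low-frequency noise, head motion and its censoring, non-neural physiology,
and spatial structure. The generator validates the estimator and the
statistical machinery, not the preprocessing upstream of them.

Problem sizes used by the checks (chosen as the smallest sizes at which each
property is cleanly identified): parameter recovery uses 50 series of
$T = 4000$ (long series, because GARCH persistence is weakly identified at
scan length); trajectory tracking uses 20 scans of $T = 450$; bootstrap
coverage uses 500 replicates at $n = 25/23$ with 1000 resamples; null
calibration uses cohorts of 20 + 20 subjects.

## Known limitations

* Bivariate only: no multivariate DCC across more than two networks, no
  higher-order DCC or GARCH, no non-Gaussian likelihoods, no
  stochastic-volatility alternatives.
* The two-step point estimate of $\rho_t$ is conditioned on in feature
  extraction; uncertainty in the trajectory does not propagate into the
  features (a hierarchical or bootstrap-the-series treatment would, at
  substantial cost).
* ARMA/GARCH orders are configurable but not selected automatically;
  (2,2)/(1,1) is the default.
* Welch spectra assume spectral properties are stable within the scan;
  time-varying spectral tracking is out of scope.
* Input is tabular network time courses; image preprocessing and network
  extraction live upstream.
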