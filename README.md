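# dynConn

Temporal and spectral analysis of dynamic functional connectivity (dFC)
between resting-state network time courses.

Static functional connectivity — one Pearson correlation per scan — ignores
the within-scan fluctuations of network coupling. dynConn estimates coupling
as a *time-varying conditional correlation* with a two-step
ARMA(2,2)–GARCH(1,1)–DCC model, turns the resulting trajectory into 17
interpretable temporal and spectral features, compares patient and control
groups with BCa bootstrap confidence intervals under FDR control, and
classifies subjects with repeated cross-validated random forests (including
conditional permutation importance for the strongly collinear features).
Sliding-window and static-FC baselines, a synthetic cohort generator with
known ground truth, file I/O, a pipeline driver and a small CLI are included.
It is aimed at neuroimaging researchers working with extracted network or
ROI time courses (the imaging preprocessing itself lives upstream).

## The model

For a pair of network time courses $Z_t = (Z_{1t}, Z_{2t})'$ sampled every
TR seconds:

- ARMA(2,2) conditional means $\mu_{jt}$;
- GARCH(1,1) conditional variances
  $\sigma^2_{jt} = \omega_j + \phi_j \epsilon^2_{j,t-1} + \psi_j \sigma^2_{j,t-1}$;
- DCC(1,1) conditional correlation on standardized residuals
  $u_t$:
  $Q_t = (1-\eta_1-\eta_2)\Xi + \eta_1 u_{t-1}u_{t-1}' + \eta_2 Q_{t-1}$,
  $R_t = \mathrm{diag}(Q_t)^{-1/2} Q_t\, \mathrm{diag}(Q_t)^{-1/2}$.

The off-diagonal of $R_t$ is the dFC trajectory $\rho_t \in [-1,1]$. The
feature set summarizes $\rho_t$ in the time domain (mean, variance,
proportion of anticorrelated volumes, zero-crossing rate) and, via Welch
power spectra, in the frequency domain (spectral centroid, spread, skewness,
kurtosis, median frequency, rolloff, dominant frequency, crest, flux, slope,
flatness, entropy, and low-frequency fluctuation amplitude in the
0.01–0.08 Hz band). See the methods vignette
(`vignettes/dynConn-methods.Rmd`) for every definition and convention.

## Worked example

Simulate one subject whose true correlation oscillates (amplitude 0.5 around
0.2 at 0.01 Hz), estimate its dFC and extract the features:

```r
library(dynConn)

spec <- SimulationSpec(nTime = 450,
                       mode = sinusoidMode(amplitude = 0.5,
                                           frequency = 0.01, offset = 0.2),
                       seed = 42)
sub <- simulateSubject(spec)
fit <- estimateDfc(sub@series)
fit
#> DfcFit: roi1 ~ roi2
#> DfcSeries: T = 450, TR = 2 s | mean 0.176, range [-0.435, 0.704]
#> DccFit: eta1 = 0.1453, eta2 = 0.7154, xi12 = 0.1779 | logLik 20.968

cor(rho(fit), sub@trueCorrelation)
#> [1] 0.687

round(featureValues(extractFeatureVector(fit@dfc)), 4)
#>       MV      VAR      PAV       ZC      SCO      SPR      SKW     KURT
#>   0.1763   0.0534   0.2422   0.1069   0.0620   0.0049   1.1997   0.2627
#>     SMED      SRO     PEAK    CREST     FLUX    SLOPE     FLAT      PSE
#>   0.0312   0.1484   0.0117   6.5528   0.0874  -4.2564   0.6497   3.4847
#> ALFF_dFC
#>   0.5785
```

The estimated trajectory tracks the planted oscillation (correlation 0.69
with the ground truth). PEAK lands at 0.0117 Hz, one frequency bin from the
planted 0.01 Hz; MV ≈ 0.18 matches the planted mean offset 0.2; PAV says the
networks were anticorrelated in 24% of volumes. The static baseline
collapses all of this to a single number:

```r
staticFC(sub@series)
#> [1] 0.157
sw <- slidingWindowDfc(sub@series)   # 80 s windows, 50% overlap
c(sw$SW_Mean, sw$SW_Var)
#> [1] 0.196 0.0289
```

Cohort-level analysis goes through `generateCohort()` (or a manifest of CSV
time-course files), `extractCohortFeatures()`, `compareGroups()` (BCa
intervals + FDR) and `runModelComparison()` (seven classifiers on paired
folds); `runPipeline()` chains everything and writes CSV artifacts with JSON
settings sidecars. A command-line front end with `simulate`, `fit-dfc`,
`features`, `compare-groups`, `classify` and `report` subcommands is
installed at `inst/cli/dynconn.R`.

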