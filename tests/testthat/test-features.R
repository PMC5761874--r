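test_that("temporal features match hand-computable cases", {
  f <- temporalFeatures(DfcSeries(rep(0.5, 4)))
  expect_equal(unname(f), c(0.5, 0, 0, 0))

  f <- temporalFeatures(DfcSeries(c(0.4, -0.4, 0.4, -0.4)))
  expect_equal(f[["MV"]], 0)
  expect_equal(f[["PAV"]], 0.5)
  expect_equal(f[["ZC"]], 1)

  # crossings smaller than the threshold c are suppressed as noise
  f <- temporalFeatures(DfcSeries(c(0.0004, -0.0004, 0.0004)), c = 0.001)
  expect_equal(f[["ZC"]], 0)

  expect_error(temporalFeatures(DfcSeries(0.2)), "at least 2")
})

test_that("Welch spectrum satisfies Parseval and localizes a sinusoid", {
  set.seed(2)
  x <- rnorm(1024)
  s <- welchSpectrum(DfcSeries(tanh(x / 3), tr = 2))
  xs <- tanh(x / 3)
  expect_lt(abs(sum(s@power) * s@df - mean(xs^2)) / mean(xs^2), 0.10)

  tt <- (0:511) * 2
  s2 <- welchSpectrum(0.3 * sin(2 * pi * 0.10 * tt), tr = 2,
                      removeMean = TRUE)
  expect_lt(abs(s2@freqs[which.max(s2@power)] - 0.10), s2@df + 1e-12)

  s3 <- welchSpectrum(rep(0.7, 200), tr = 2, removeMean = TRUE)
  expect_true(all(s3@power == 0))

  expect_error(welchSpectrum(rnorm(64), segmentLength = 128), "shorter")
})

test_that("delta spectrum gives point-mass spectral features", {
  K <- 32L
  freqs <- seq(0, 0.25, length.out = K)
  power <- numeric(K); power[17] <- 4     # all mass at freqs[17] = 0.129...
  sp <- DfcSpectrum(freqs, power, tr = 2)
  m <- spectralMomentFeatures(sp)
  expect_equal(m[["SCO"]], freqs[17])
  expect_equal(m[["SPR"]], 0)
  expect_true(is.na(m[["SKW"]]) && is.na(m[["KURT"]]))
  expect_equal(m[["SMED"]], freqs[17])
  expect_equal(m[["SRO"]], freqs[17])

  sh <- spectralShapeFeatures(sp, sp)
  expect_equal(sh[["CREST"]], K)
  expect_equal(sh[["FLAT"]], 0)
  expect_equal(sh[["PSE"]], 0)
})

test_that("flat spectrum gives the discrete-uniform closed forms", {
  K <- 64L
  freqs <- seq(0, 0.25, length.out = K)
  sp <- DfcSpectrum(freqs, rep(2, K), tr = 2,
                    segMags = matrix(sqrt(2), 3, K))
  m <- spectralMomentFeatures(sp)
  expect_equal(m[["SCO"]], mean(freqs))
  expect_equal(m[["SKW"]], 0)
  # excess kurtosis of a discrete uniform over K points
  expect_equal(m[["KURT"]], -(6 / 5) * (K^2 + 1) / (K^2 - 1))

  sh <- spectralShapeFeatures(sp, sp)
  expect_equal(sh[["CREST"]], 1)
  expect_equal(sh[["FLAT"]], 1)
  expect_equal(sh[["PSE"]], log2(K))
  expect_equal(sh[["SLOPE"]], 0)
  expect_equal(sh[["FLUX"]], 0)   # identical segments

  K2 <- 100L
  sp2 <- DfcSpectrum(seq(0, 0.25, length.out = K2), rep(1, K2), tr = 2)
  m2 <- spectralMomentFeatures(sp2)
  expect_equal(m2[["SRO"]], sp2@freqs[85])  # first bin with cumulative >= 85%
  expect_equal(m2[["SMED"]], sp2@freqs[50])
})

test_that("low-frequency oscillations dominate ALFF within the default band", {
  tt <- (0:449) * 2
  inband <- extractFeatureVector(DfcSeries(0.4 * sin(2 * pi * 0.05 * tt)))
  outband <- extractFeatureVector(DfcSeries(0.4 * sin(2 * pi * 0.20 * tt)))
  expect_gt(featureValues(inband)[["ALFF_dFC"]],
            5 * featureValues(outband)[["ALFF_dFC"]])
  # and PEAK finds the oscillation frequency
  expect_lt(abs(featureValues(inband)[["PEAK"]] - 0.05), 0.004)
  expect_lt(abs(featureValues(outband)[["PEAK"]] - 0.20), 0.004)
})

test_that("constant trajectories produce the degenerate feature pattern", {
  fv <- featureValues(extractFeatureVector(DfcSeries(rep(0.3, 300), tr = 2)))
  expect_equal(fv[["MV"]], 0.3)
  expect_equal(fv[["VAR"]], 0)
  expect_equal(fv[["PAV"]], 0)
  expect_equal(fv[["ALFF_dFC"]], 0)
  expect_true(is.na(fv[["PEAK"]]))
  expect_equal(fv[["SMED"]], 0)  # spectrum is concentrated at DC
})

test_that("feature vectors match the independent direct-formula oracle", {
  for (s in 1:20) {
    dfc <- randomDfc(n = 64 + 17 * s, seed = s)
    got <- featureValues(extractFeatureVector(dfc))
    want <- oracleFeatures(dfc@rho, tr = 2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("every feature vector is complete, named and within bounds", {
  fv <- extractFeatureVector(randomDfc(300, seed = 4))
  v <- featureValues(fv)
  expect_identical(names(v), dfcFeatureNames())
  expect_length(v, 17L)
  expect_true(all(is.finite(v)))
  nyq <- 0.25
  K <- length(welchSpectrum(randomDfc(300, seed = 4))@freqs)
  expect_true(v[["PAV"]] >= 0 && v[["PAV"]] <= 1)
  expect_true(v[["ZC"]] >= 0 && v[["ZC"]] <= 1)
  expect_gte(v[["VAR"]], 0)
  expect_true(v[["FLAT"]] >= 0 && v[["FLAT"]] <= 1)
  expect_true(v[["PSE"]] >= 0 && v[["PSE"]] <= log2(K))
  expect_true(v[["CREST"]] >= 1 && v[["CREST"]] <= K)
  expect_true(all(v[c("SCO", "SMED", "SRO", "PEAK")] >= 0 &
                    v[c("SCO", "SMED", "SRO", "PEAK")] <= nyq))
  expect_true(is.list(fv@provenance) && !is.null(fv@provenance$welch))
})

test_that("features respond to amplitude scaling exactly as dimensional analysis predicts", {
  dfc <- randomDfc(320, seed = 9)
  a <- 0.5
  v1 <- featureValues(extractFeatureVector(dfc))
  v2 <- featureValues(extractFeatureVector(DfcSeries(a * dfc@rho, tr = 2)))
  invariant <- c("PAV", "ZC", "SCO", "SPR", "SKW", "KURT", "SMED", "SRO",
                 "FLAT", "PSE", "CREST", "PEAK", "FLUX")
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-9)
  expect_equal(v2[["MV"]], a * v1[["MV"]], tolerance = 1e-12)
  expect_equal(v2[["VAR"]], a^2 * v1[["VAR"]], tolerance = 1e-12)
  expect_equal(v2[["ALFF_dFC"]], a * v1[["ALFF_dFC"]], tolerance = 1e-12)
  expect_equal(v2[["SLOPE"]], a * v1[["SLOPE"]], tolerance = 1e-12)
})

test_that("time reversal changes no feature except spectral flux", {
  # T chosen so the Welch segment grid tiles the series symmetrically
  dfc <- randomDfc(448, seed = 5)
  v1 <- featureValues(extractFeatureVector(dfc))
  v2 <- featureValues(extractFeatureVector(DfcSeries(rev(dfc@rho), tr = 2)))
  keep <- setdiff(dfcFeatureNames(), "FLUX")
  expect_equal(v2[keep], v1[keep], tolerance = 1e-9)
})
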