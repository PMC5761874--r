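test_that("identical samples give an interval containing zero", {
  r <- bcaDiffMeans(1:10, 1:10, B = 500, seed = 1)
  expect_lte(r$ci[1], 0)
  expect_gte(r$ci[2], 0)
  expect_gt(r$p_value, 0.5)
})

test_that("with z0 = a = 0 the BCa interval is the percentile interval", {
  set.seed(4)
  x <- rnorm(20, 1); y <- rnorm(18)
  r <- bcaDiffMeans(x, y, B = 800, seed = 7, z0 = 0, accel = 0)
  expect_equal(r$ci,
               unname(quantile(r$boot_samples, c(0.025, 0.975),
                               names = FALSE)))
})

test_that("BCa interval respects sign flips of the statistic", {
  set.seed(9)
  x <- rnorm(15, 0.8); y <- rnorm(15)
  r1 <- bcaDiffMeans(x, y, B = 1000, seed = 3)
  r2 <- bcaDiffMeans(-x, -y, B = 1000, seed = 3)
  # negating both samples negates and flips the interval (same resample
  # indices under the same seed)
  expect_equal(r2$ci, -rev(r1$ci), tolerance = 1e-10)
  expect_equal(r2$observed_diff, -r1$observed_diff)
})

test_that("BCa agrees with the reference bootstrap implementation", {
  skip_if_not_installed("boot")
  set.seed(11)
  x <- rnorm(25, 1); y <- rnorm(23)
  r <- bcaDiffMeans(x, y, B = 4000, seed = 5)
  dat <- data.frame(v = c(x, y), g = rep(c(1, 2), c(25, 23)))
  bo <- boot::boot(dat, function(d, i) {
    di <- d[i, ]; mean(di$v[di$g == 1]) - mean(di$v[di$g == 2])
  }, R = 4000, strata = dat$g)
  ci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  expect_equal(r$ci, ci, tolerance = 0.12)
})

test_that("degenerate bootstrap distributions are flagged", {
  r <- bcaDiffMeans(rep(2, 5), rep(2, 6), B = 200, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$ci, c(0, 0))
  expect_equal(r$p_value, 1)
})

test_that("BH adjustment matches the worked example and rejects two", {
  res <- bhFdr(c(0.001, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(res$adjusted, c(0.004, 0.04, 0.04 * 4 / 3, 0.2),
               tolerance = 1e-12)
  expect_equal(res$rejected, c(TRUE, TRUE, FALSE, FALSE))

  expect_equal(bhFdr(rep(0.5, 6))$rejected, rep(FALSE, 6))
  single <- bhFdr(0.01)
  expect_equal(single$adjusted, 0.01)
  expect_true(single$rejected)
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH matches a brute-force step-up oracle on random p-vectors", {
  set.seed(21)
  for (i in 1:200) {
    m <- sample(1:25, 1)
    p <- round(runif(m), 4)
    got <- bhFdr(p, q = 0.05)
    want <- oracleBH(p, q = 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$rejected, want$rejected)
  }
})

test_that("compareGroups reports the A-minus-B sign convention", {
  set.seed(2)
  f <- rbind(up = c(rnorm(10, 2), rnorm(10, 0)),
             dn = c(rnorm(10, -2), rnorm(10, 0)))
  colnames(f) <- sprintf("s%02d", 1:20)
  labels <- rep(c("HC", "TLE"), each = 10)
  out <- compareGroups(f, labels, groups = c("HC", "TLE"), B = 500, seed = 3)
  expect_gt(out$diff[out$feature == "up"], 0)
  expect_lt(out$diff[out$feature == "dn"], 0)
  expect_true(all(out$rejected))
  expect_true(all(out$p_adj >= out$p_raw))
})

test_that("compareGroups is deterministic and FDR-monotone", {
  set.seed(5)
  f <- matrix(rnorm(17 * 24), 17,
              dimnames = list(dfcFeatureNames(), sprintf("s%02d", 1:24)))
  labels <- rep(c("HC", "TLE"), each = 12)
  o1 <- compareGroups(f, labels, B = 300, seed = 9)
  o2 <- compareGroups(f, labels, B = 300, seed = 9)
  expect_identical(o1, o2)
  ord <- order(o1$p_raw)
  expect_true(all(diff(o1$p_adj[ord]) >= -1e-12))
})

test_that("null cohorts are rejected at no more than the nominal FDR rate", {
  # generative null: both groups share every setting; features estimated
  # end-to-end, then compared at q = 0.05
  rates <- vapply(1:4, function(rep) {
    coh <- generateCohort(CohortSpec(nPerGroup = c(20L, 20L),
                                     baseSpec = quickSpec(nTime = 150),
                                     seed = 100 + rep))
    ext <- suppressWarnings(
      extractCohortFeatures(lapply(coh@subjects, function(s) s@series),
                            coh@manifest$label))
    out <- compareGroups(ext$se, B = 1000, seed = rep)
    mean(out$rejected, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("a large injected anticorrelation shift is detected with power", {
  hits <- vapply(1:5, function(rep) {
    eff <- list(PAV = list(group0 = constantMode(0.3),
                           group1 = constantMode(-0.3)))
    coh <- generateCohort(CohortSpec(nPerGroup = c(12L, 12L),
                                     featureEffects = eff,
                                     baseSpec = quickSpec(nTime = 150),
                                     seed = 300 + rep))
    ext <- suppressWarnings(
      extractCohortFeatures(lapply(coh@subjects, function(s) s@series),
                            coh@manifest$label))
    out <- compareGroups(ext$se, B = 400, seed = rep)
    out$rejected[out$feature == "PAV"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
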