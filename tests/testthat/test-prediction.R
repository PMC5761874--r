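test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy(c(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(accuracy(c(TP = 3, TN = 2, FP = 1, FN = 4)), 0.5)
  expect_error(accuracy(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
  expect_error(accuracy(c(TP = 1, TN = 1)), "must name")
})

test_that("naive classifier predicts the training majority with fixed ties", {
  pred <- naiveClassifier(rep(c("HC", "TLE"), c(25, 23)), 10)
  expect_true(all(pred == "HC"))
  # balanced training: tie goes to the first label in sorted order
  expect_true(all(naiveClassifier(rep(c("b", "a"), 5), 4) == "a"))
  expect_true(all(naiveClassifier(rep("TLE", 7), 3) == "TLE"))
  expect_error(naiveClassifier(character(), 3), "empty")
})

test_that("naive CV accuracy equals the test-fold majority fraction exactly", {
  y <- factor(rep(c("HC", "TLE"), c(14, 11)))
  x <- matrix(rnorm(25 * 2), 25)
  st <- cvSettings(k = 5, repetitions = 3, numTrees = 10,
                   grid = data.frame(mtry = 1, nodesize = 1), seed = 4)
  folds <- dynConn:::foldMatrix(y, st)
  cv <- repeatedCv(x, y, "naive", st, folds = folds)
  for (i in seq_len(nrow(cv$records))) {
    r <- cv$records[i, ]
    te <- folds[r$repetition, ] == r$fold
    maj <- names(which.max(table(y[!te])))
    expect_identical(r$accuracy, mean(y[te] == maj))
  }
})

test_that("repeated CV produces the full structural record set", {
  sep <- separableFeatures(seed = 3)
  st <- cvSettings(k = 5, repetitions = 30, numTrees = 30,
                   grid = data.frame(mtry = 4, nodesize = 1), seed = 7)
  cv <- repeatedCv(sep$x, sep$y, "rf", st)
  expect_equal(nrow(cv$records), 150L)   # 5 folds x 30 repetitions
  expect_true(all(cv$records$accuracy >= 0 & cv$records$accuracy <= 1))
  # fold test sets partition the subjects within each repetition
  folds <- dynConn:::foldMatrix(sep$y, st)
  expect_true(all(apply(folds, 1, function(f) all(table(f) >= 8))))
  expect_gte(cv$summary$mean_accuracy, 0.95)
})

test_that("permuted labels give chance-level accuracy", {
  sep <- separableFeatures(seed = 5)
  set.seed(99)
  yperm <- sample(sep$y)
  st <- tinyCv(repetitions = 3, numTrees = 50, seed = 2)
  cv <- repeatedCv(sep$x, yperm, "rf", st)
  expect_lt(abs(cv$summary$mean_accuracy - 0.5), 0.15)
})

test_that("tuning happens strictly inside the training folds", {
  sep <- separableFeatures(seed = 11)
  tr <- seq_len(30); te <- 31:48
  st <- cvSettings(k = 5, repetitions = 1, numTrees = 30,
                   grid = data.frame(mtry = c(1, 4), nodesize = c(1, 3)),
                   seed = 5)
  f1 <- tunedRandomForest(sep$x[tr, ], sep$y[tr], st, seed = 10)
  f2 <- tunedRandomForest(sep$x[tr, ], sep$y[tr], st, seed = 10)
  # identical training data and seed give an identical model regardless of
  # anything that happens to the held-out samples
  expect_identical(f1$mtry, f2$mtry)
  expect_identical(predict(f1$model, sep$x[te, ]),
                   predict(f2$model, sep$x[te, ]))
})

test_that("model comparison runs all seven designs on shared folds", {
  set.seed(8)
  n <- 30
  y <- rep(c("HC", "TLE"), each = 15)
  fs <- list(dfc = matrix(rnorm(n * 5), n,
                          dimnames = list(NULL, paste0("f", 1:5))),
             sfc = rnorm(n), sw_mean = rnorm(n), sw_var = abs(rnorm(n)),
             labels = y)
  st <- tinyCv(repetitions = 2, numTrees = 20, seed = 3)
  out <- runModelComparison(fs, st)
  models <- c("rf_dfc", "rf_sfc", "logistic_sfc", "rf_sw_mean", "rf_sw_var",
              "rf_sw_meanvar", "naive")
  expect_setequal(unique(out$records$model), models)
  expect_equal(nrow(out$records), 7L * 2L * 5L)
  expect_equal(nrow(out$summary), 7L)
  # paired design: every model sees the same fold assignment per repetition
  expect_equal(dim(out$folds), c(2L, n))
  naive <- out$records[out$records$model == "naive", ]
  for (i in seq_len(nrow(naive))) {
    te <- out$folds[naive$repetition[i], ] == naive$fold[i]
    maj <- names(which.max(table(y[!te])))
    expect_identical(naive$accuracy[i], mean(y[te] == maj))
  }
  expect_error(runModelComparison(c(fs, list(sfc = rnorm(5)))[-2], st))
})

test_that("an advantage built into dFC features shows up in the comparison", {
  set.seed(13)
  n <- 40
  y <- rep(c("HC", "TLE"), each = 20)
  dfc <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  dfc[y == "TLE", 2] <- dfc[y == "TLE", 2] + 3   # e.g. a VAR-like shift
  fs <- list(dfc = dfc, sfc = rnorm(n), sw_mean = rnorm(n),
             sw_var = rnorm(n), labels = y)
  st <- cvSettings(k = 5, repetitions = 3, numTrees = 60,
                   grid = data.frame(mtry = 2, nodesize = 1), seed = 21)
  out <- runModelComparison(fs, st)
  acc <- function(m) out$summary$mean_accuracy[out$summary$model == m]
  expect_gte(acc("rf_dfc"), acc("rf_sfc") + 0.1)
  expect_gte(acc("rf_dfc"), acc("naive") + 0.1)
})

test_that("conditional importance separates copies and ignores noise", {
  set.seed(31)
  n <- 80
  x <- matrix(rnorm(n * 4), n,
              dimnames = list(NULL, c("inf", "copy", "n1", "n2")))
  y <- factor(rep(c("g0", "g1"), n / 2))
  x[y == "g1", "inf"] <- x[y == "g1", "inf"] + 2
  x[, "copy"] <- x[, "inf"]
  cond <- conditionalImportance(x, y, threshold = 0.2, numTrees = 150,
                                repetitions = 3, seed = 6)
  marg <- conditionalImportance(x, y, threshold = Inf, numTrees = 150,
                                repetitions = 3, seed = 6)
  imp <- function(d, f) d$importance[d$feature == f]
  # the defining property of the conditional scheme: a duplicated informative
  # feature loses the credit it inherits through correlation
  expect_lt(imp(cond, "copy"), imp(marg, "copy"))
  # independent noise scores in a band around zero either way
  expect_lt(abs(imp(cond, "n1")), 0.02)
  expect_lt(abs(imp(cond, "n2")), 0.02)
  expect_lt(abs(imp(marg, "n1")), 0.02)
})

test_that("a feature uncorrelated with the rest keeps its marginal importance", {
  set.seed(41)
  n <- 80
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("solo", "a", "b")))
  y <- factor(rep(c("g0", "g1"), n / 2))
  x[y == "g1", "solo"] <- x[y == "g1", "solo"] + 2
  cond <- conditionalImportance(x, y, threshold = 0.2, numTrees = 150,
                                repetitions = 3, seed = 9)
  marg <- conditionalImportance(x, y, threshold = Inf, numTrees = 150,
                                repetitions = 3, seed = 9)
  expect_equal(cond$importance[1], marg$importance[1], tolerance = 0.05)
})
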