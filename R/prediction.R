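#' Classification accuracy from confusion counts
#'
#' @param counts named numeric with elements TP, TN, FP, FN.
#' @return (TP + TN) / (TP + FP + FN + TN).
#' @export
#' @examples
#' accuracy(c(TP = 3, TN = 2, FP = 1, FN = 4))
accuracy <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts))) stop("counts must name TP, TN, FP, FN")
  counts <- counts[need]
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) stop("total count is zero: accuracy undefined")
  unname((counts["TP"] + counts["TN"]) / tot)
}

#' Majority-class (naive) classifier
#'
#' Predicts the most common class of the training labels for every test
#' sample; ties are broken by the first label in sorted order. Serves as the
#' null performance line in the model comparison.
#'
#' @param trainLabels factor or character training labels.
#' @param testSize number of predictions to emit.
#' @return character vector of length \code{testSize}.
#' @export
#' @examples
#' naiveClassifier(c(rep("HC", 25), rep("TLE", 23)), 10)
naiveClassifier <- function(trainLabels, testSize) {
  trainLabels <- as.character(trainLabels)
  if (!length(trainLabels)) stop("training labels are empty")
  tab <- table(trainLabels)
  winners <- names(tab)[tab == max(tab)]
  rep(sort(winners)[1], testSize)
}

#' Cross-validation settings
#'
#' @param k outer folds, default 5.
#' @param repetitions repeated CV replications, default 30.
#' @param grid data.frame with columns \code{mtry} and \code{nodesize}, the
#'   two-dimensional random-forest tuning grid; NULL (default) resolves at
#'   fit time to mtry in \{1, ceiling(sqrt(p)), ceiling(p/3), p\} crossed
#'   with nodesize in \{1, 3, 5\}.
#' @param innerK inner folds for the grid search, default 5.
#' @param numTrees trees per forest, default 500 (not tuned).
#' @param seed integer seed; all fold draws and forests derive from it.
#' @return list of settings.
#' @export
cvSettings <- function(k = 5L, repetitions = 30L, grid = NULL, innerK = 5L,
                       numTrees = 500L, seed = 1L) {
  stopifnot(k >= 2L, repetitions >= 1L, innerK >= 2L, numTrees >= 1L)
  if (!is.null(grid) && (!is.data.frame(grid) ||
      !all(c("mtry", "nodesize") %in% names(grid)) || nrow(grid) == 0L))
    stop("grid must be a nonempty data.frame with columns mtry and nodesize")
  list(k = as.integer(k), repetitions = as.integer(repetitions), grid = grid,
       innerK = as.integer(innerK), numTrees = as.integer(numTrees),
       seed = as.integer(seed))
}

defaultGrid <- function(p) {
  expand.grid(mtry = unique(pmin(p, c(1L, ceiling(sqrt(p)), ceiling(p / 3), p))),
              nodesize = c(1L, 3L, 5L))
}

# stratified k-fold assignment: within each class, shuffled indices are dealt
# out cyclically, so every fold holds every class whenever n_class >= k
stratifiedFolds <- function(labels, k, seed = NULL) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Fit a random forest with inner-CV grid search on the training data only
#'
#' Performs the two-dimensional grid search (features-per-split x minimum
#' node size) by stratified inner cross-validation within the training set,
#' then refits the winning configuration on the whole training set. Test
#' data never enter tuning or fitting, so held-out predictions are a
#' function of the training fold alone.
#'
#' @param xtr training feature matrix.
#' @param ytr training labels (factor).
#' @param settings from \code{\link{cvSettings}}.
#' @param seed integer seed for the inner folds and forests.
#' @return list with \code{model} (a randomForest), \code{mtry},
#'   \code{nodesize}.
#' @export
tunedRandomForest <- function(xtr, ytr, settings = cvSettings(), seed = 1L) {
  xtr <- as.matrix(xtr)
  ytr <- droplevels(as.factor(ytr))
  p <- ncol(xtr)
  grid <- if (is.null(settings$grid)) defaultGrid(p) else settings$grid
  grid$mtry <- pmin(grid$mtry, p)
  grid <- unique(grid)

  if (nrow(grid) > 1L) {
    innerK <- min(settings$innerK, min(table(ytr)))
    inner <- stratifiedFolds(ytr, innerK, seed = childSeed(seed, 1L))
    err <- vapply(seq_len(nrow(grid)), function(g) {
      miss <- 0L; tot <- 0L
      for (f in seq_len(innerK)) {
        tr <- inner != f
        fit <- withSeed(childSeed(seed, 100L + 10L * g + f),
          randomForest::randomForest(
            xtr[tr, , drop = FALSE], ytr[tr],
            ntree = settings$numTrees, mtry = grid$mtry[g],
            nodesize = grid$nodesize[g]))
        pred <- predict(fit, xtr[!tr, , drop = FALSE])
        miss <- miss + sum(pred != ytr[!tr]); tot <- tot + sum(!tr)
      }
      miss / tot
    }, numeric(1))
    best <- which.min(err)   # ties: first grid row
  } else best <- 1L

  model <- withSeed(childSeed(seed, 2L),
    randomForest::randomForest(xtr, ytr, ntree = settings$numTrees,
                               mtry = grid$mtry[best],
                               nodesize = grid$nodesize[best]))
  list(model = model, mtry = grid$mtry[best], nodesize = grid$nodesize[best])
}

fitPredictModel <- function(model, xtr, ytr, xte, settings, seed) {
  lev <- levels(ytr)
  switch(model,
    naive = naiveClassifier(ytr, nrow(xte)),
    logistic = {
      df <- data.frame(y = ytr == lev[2], xtr)
      fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
      pr <- stats::predict(fit, newdata = data.frame(xte), type = "response")
      ifelse(pr > 0.5, lev[2], lev[1])
    },
    rf = {
      fit <- tunedRandomForest(xtr, ytr, settings, seed = seed)
      as.character(predict(fit$model, xte))
    },
    stop("unknown model type: ", model))
}

#' Repeated stratified k-fold cross-validation
#'
#' The workhorse behind the model comparison: for each repetition a fresh
#' stratified fold assignment is drawn, each training fold is tuned and fit
#' (random forests get the inner grid search), and the held-out fold is
#' scored with classification accuracy.
#'
#' @param x feature matrix (subjects in rows).
#' @param y group labels.
#' @param model one of \code{"rf"}, \code{"logistic"}, \code{"naive"}.
#' @param settings from \code{\link{cvSettings}}.
#' @param folds optional precomputed repetitions x subjects fold matrix (for
#'   paired comparisons across models).
#' @return list with \code{records} (repetition, fold, accuracy) and
#'   \code{summary} (mean accuracy with normal-theory and percentile 95\%
#'   intervals over the repetition means).
#' @export
#' @examples
#' x <- matrix(rnorm(40 * 3), 40); y <- rep(c("a", "b"), 20)
#' x[y == "b", 1] <- x[y == "b", 1] + 4
#' repeatedCv(x, y, "rf",
#'            cvSettings(repetitions = 2, numTrees = 50,
#'                       grid = data.frame(mtry = 1, nodesize = 1)))$summary
repeatedCv <- function(x, y, model = c("rf", "logistic", "naive"),
                       settings = cvSettings(), folds = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (min(table(y)) < settings$k)
    stop("need at least k subjects in every class for stratified k-fold CV")
  if (is.null(folds)) folds <- foldMatrix(y, settings)

  recs <- vector("list", settings$repetitions * settings$k)
  i <- 0L
  for (r in seq_len(settings$repetitions)) {
    fr <- folds[r, ]
    for (f in seq_len(settings$k)) {
      te <- fr == f
      pred <- fitPredictModel(model, x[!te, , drop = FALSE], y[!te],
                              x[te, , drop = FALSE], settings,
                              seed = childSeed(settings$seed, 1000L * r + f))
      i <- i + 1L
      recs[[i]] <- data.frame(repetition = r, fold = f,
                              accuracy = mean(pred == as.character(y[te])))
    }
  }
  records <- do.call(rbind, recs)
  list(records = records, summary = summarizeCv(records, model))
}

foldMatrix <- function(y, settings) {
  t(vapply(seq_len(settings$repetitions), function(r)
    stratifiedFolds(y, settings$k, seed = childSeed(settings$seed, r)),
    integer(length(y))))
}

summarizeCv <- function(records, model) {
  repMeans <- tapply(records$accuracy, records$repetition, mean)
  m <- mean(repMeans)
  se <- stats::sd(repMeans) / sqrt(length(repMeans))
  pc <- if (length(repMeans) > 1)
    unname(stats::quantile(repMeans, c(0.025, 0.975))) else c(m, m)
  data.frame(model = model, mean_accuracy = m,
             ci_lo_normal = m - 1.96 * se, ci_hi_normal = m + 1.96 * se,
             ci_lo_percentile = pc[1], ci_hi_percentile = pc[2],
             repetitions = length(repMeans))
}

#' Compare the seven classifiers of the dFC workbench
#'
#' Runs repeated cross-validation for the proposed dFC-feature random forest
#' (\code{rf_dfc}) against the comparison estimators: random forest and
#' logistic classifiers on static FC (\code{rf_sfc}, \code{logistic_sfc}),
#' random forests on the sliding-window mean, variance and both
#' (\code{rf_sw_mean}, \code{rf_sw_var}, \code{rf_sw_meanvar}) and the
#' majority-class null (\code{naive}). Fold assignments are shared across
#' all models within each repetition, so the comparison is paired.
#'
#' @param featureSet list with elements \code{dfc} (subjects x features
#'   matrix), \code{sfc}, \code{sw_mean}, \code{sw_var} (numeric vectors) and
#'   \code{labels}.
#' @param settings from \code{\link{cvSettings}}.
#' @return list with \code{records} (model, repetition, fold, accuracy),
#'   \code{summary} (one row per model) and the shared \code{folds} matrix.
#' @export
runModelComparison <- function(featureSet, settings = cvSettings()) {
  need <- c("dfc", "sfc", "sw_mean", "sw_var", "labels")
  if (!all(need %in% names(featureSet)))
    stop("featureSet must contain: ", paste(need, collapse = ", "))
  y <- droplevels(as.factor(featureSet$labels))
  n <- length(y)
  dfc <- as.matrix(featureSet$dfc)
  if (nrow(dfc) != n || length(featureSet$sfc) != n ||
      length(featureSet$sw_mean) != n || length(featureSet$sw_var) != n)
    stop("mismatched subject sets across feature tables")

  designs <- list(
    rf_dfc = list(model = "rf", x = dfc),
    rf_sfc = list(model = "rf", x = cbind(sfc = featureSet$sfc)),
    logistic_sfc = list(model = "logistic", x = cbind(sfc = featureSet$sfc)),
    rf_sw_mean = list(model = "rf", x = cbind(sw_mean = featureSet$sw_mean)),
    rf_sw_var = list(model = "rf", x = cbind(sw_var = featureSet$sw_var)),
    rf_sw_meanvar = list(model = "rf",
                         x = cbind(sw_mean = featureSet$sw_mean,
                                   sw_var = featureSet$sw_var)),
    naive = list(model = "naive", x = cbind(dummy = rep(0, n))))

  folds <- foldMatrix(y, settings)
  recs <- list(); sums <- list()
  for (nm in names(designs)) {
    d <- designs[[nm]]
    cv <- repeatedCv(d$x, y, d$model, settings, folds = folds)
    cv$records$model <- nm
    recs[[nm]] <- cv$records[, c("model", "repetition", "fold", "accuracy")]
    s <- cv$summary; s$model <- nm
    sums[[nm]] <- s
  }
  list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
       summary = do.call(rbind, c(sums, make.row.names = FALSE)),
       folds = folds)
}
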