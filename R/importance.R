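# Predict classes for newdata with a single tree of a randomForest.
# Tree matrix columns: left daughter, right daughter, split var, split point,
# status (-1 = terminal), prediction (class index).
predictSingleTree <- function(tree, newdata, classes) {
  n <- nrow(newdata)
  out <- integer(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree[node, "status"] != -1L) {
      node <- if (newdata[i, tree[node, "split var"]] <= tree[node, "split point"])
        tree[node, "left daughter"] else tree[node, "right daughter"]
    }
    out[i] <- tree[node, "prediction"]
  }
  classes[out]
}

#' Conditional permutation variable importance for a random forest
#'
#' Mean decrease in out-of-bag accuracy when a feature is permuted
#' \emph{within strata of its correlated covariates}: for each tree, every
#' conditioning feature (absolute correlation with the target feature above
#' \code{threshold}) is cut at the split points that tree actually used, the
#' tree's out-of-bag samples are grouped by the resulting grid, and the
#' target feature is permuted within each cell. This removes the credit a
#' feature inherits purely through correlation with informative covariates;
#' with no conditioning features above the threshold (e.g.
#' \code{threshold = Inf}) the scheme reduces to ordinary marginal
#' permutation importance. Scores are averaged over \code{repetitions}
#' independently grown forests for stability.
#'
#' @param x subjects x features matrix (column names required).
#' @param y group labels.
#' @param threshold conditioning correlation threshold, default 0.2.
#' @param numTrees trees per forest, default 500.
#' @param repetitions forests to average over, default 5.
#' @param mtry,nodesize forest parameters (defaults: sqrt(p) and 1).
#' @param seed integer seed.
#' @return data.frame: feature, importance (mean decrease in OOB accuracy),
#'   plus the threshold used, as an attribute.
#' @export
#' @examples
#' x <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("a", "b", "c")))
#' y <- factor(rep(c("g0", "g1"), 30))
#' x[y == "g1", 1] <- x[y == "g1", 1] + 2
#' conditionalImportance(x, y, numTrees = 50, repetitions = 2)
conditionalImportance <- function(x, y, threshold = 0.2, numTrees = 500L,
                                  repetitions = 5L, mtry = NULL,
                                  nodesize = 1L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature columns must be named")
  y <- droplevels(as.factor(y))
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  condSets <- lapply(seq_len(p), function(j) {
    if (p == 1L || is.infinite(threshold)) return(integer())
    cc <- suppressWarnings(abs(cor(x[, j], x[, -j, drop = FALSE])))
    which(seq_len(p) != j)[!is.na(cc) & cc > threshold]
  })

  scores <- matrix(0, repetitions, p, dimnames = list(NULL, colnames(x)))
  for (r in seq_len(repetitions)) {
    rseed <- childSeed(seed, r)
    rf <- withSeed(rseed,
      randomForest::randomForest(x, y, ntree = numTrees, mtry = mtry,
                                 nodesize = nodesize, keep.inbag = TRUE,
                                 keep.forest = TRUE))
    classes <- rf$classes
    drops <- matrix(NA_real_, numTrees, p)
    withSeed(childSeed(rseed, 7L), {
      for (k in seq_len(numTrees)) {
        tree <- randomForest::getTree(rf, k, labelVar = FALSE)
        oob <- which(rf$inbag[, k] == 0L)
        if (length(oob) < 2L) next
        xo <- x[oob, , drop = FALSE]
        base <- mean(predictSingleTree(tree, xo, classes) ==
                       as.character(y[oob]))
        splitVars <- tree[tree[, "status"] != -1L, "split var"]
        for (j in seq_len(p)) {
          # strata: grid of this tree's split points on conditioning features
          strat <- rep(1L, length(oob))
          for (z in condSets[[j]]) {
            cuts <- sort(unique(tree[tree[, "status"] != -1L &
                                       tree[, "split var"] == z,
                                     "split point"]))
            if (length(cuts))
              strat <- strat * (length(cuts) + 2L) +
                findInterval(xo[, z], cuts)
          }
          xp <- xo
          for (s in unique(strat)) {
            idx <- which(strat == s)
            if (length(idx) > 1L) xp[idx, j] <- xp[sample(idx), j]
          }
          perm <- mean(predictSingleTree(tree, xp, classes) ==
                         as.character(y[oob]))
          drops[k, j] <- base - perm
        }
      }
    })
    scores[r, ] <- colMeans(drops, na.rm = TRUE)
  }
  out <- data.frame(feature = colnames(x), importance = colMeans(scores),
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "repetitions") <- repetitions
  out
}
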