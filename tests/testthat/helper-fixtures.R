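# Small fixtures shared across test files; everything is generated in code.

quickSpec <- function(nTime = 300, mode = constantMode(0.5), seed = 1,
                      arma = TRUE) {
  mp <- if (arma) list(alpha = 0, beta = c(0.25, -0.1), theta = c(0.15, 0.05))
        else list(alpha = 0, beta = c(0, 0), theta = c(0, 0))
  SimulationSpec(nTime = nTime, meanParams = mp,
                 varParams = list(omega = 0.05, phi = 0.10, psi = 0.85),
                 mode = mode, seed = seed)
}

randomDfc <- function(n = 200, tr = 2, seed = 1) {
  set.seed(seed)
  # smooth bounded trajectory with some negative excursions
  x <- stats::filter(rnorm(n + 40), rep(1 / 5, 5), sides = 1)
  x <- x[!is.na(x)][seq_len(n)]
  DfcSeries(tanh(x), tr = tr)
}

# separable two-class feature matrix for prediction sanity checks
separableFeatures <- function(n0 = 24, n1 = 24, p = 17, delta = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n0 + n1) * p), n0 + n1,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- factor(rep(c("HC", "TLE"), c(n0, n1)))
  x[y == "TLE", 1:3] <- x[y == "TLE", 1:3] + delta
  list(x = x, y = y)
}

tinyCv <- function(repetitions = 2, numTrees = 40, seed = 1)
  cvSettings(k = 5, repetitions = repetitions, numTrees = numTrees,
             grid = data.frame(mtry = 2, nodesize = 1), seed = seed)
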