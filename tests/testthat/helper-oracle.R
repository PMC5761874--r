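# Independent direct-formula oracle for the 17 dFC features.
# Deliberately written as plain loops over the defining sums, sharing no code
# with the package implementation, so agreement is a genuine dual-route check.

oracleWelch <- function(x, tr, seglen, overlap = 0.5, removeMean = FALSE) {
  if (removeMean) x <- x - sum(x) / length(x)
  fs <- 1 / tr
  N <- seglen
  w <- numeric(N)
  for (i in seq_len(N)) w[i] <- 0.5 * (1 - cos(2 * pi * (i - 1) / (N - 1)))
  U <- sum(w * w)
  hop <- max(1, round(N * (1 - overlap)))
  starts <- seq(1, length(x) - N + 1, by = hop)
  K <- floor(N / 2) + 1
  psd <- matrix(0, length(starts), K)
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + N - 1)] * w
    ft <- stats::fft(seg)
    for (k in seq_len(K)) {
      v <- Mod(ft[k])^2 / (fs * U)
      if (k > 1 && !(N %% 2 == 0 && k == K)) v <- 2 * v
      psd[s, k] <- v
    }
  }
  list(freqs = (seq_len(K) - 1) * fs / N,
       psd = colSums(psd) / length(starts),
       segPsd = psd)
}

oracleFeatures <- function(rho, tr, c = 0.001, seglen = min(length(rho), 128),
                           overlap = 0.5, band = c(0.01, 0.08), bins = 8) {
  T <- length(rho)
  mv <- sum(rho) / T
  va <- 0; for (t in seq_len(T)) va <- va + (rho[t] - mv)^2
  va <- va / (T - 1)
  pav <- 0; for (t in seq_len(T)) if (rho[t] < 0) pav <- pav + 1
  pav <- pav / T
  zc <- 0
  for (t in seq_len(T - 1))
    if (rho[t] * rho[t + 1] < 0 && abs(rho[t + 1] - rho[t]) >= c) zc <- zc + 1
  zc <- zc / (T - 1)

  W <- oracleWelch(rho, tr, seglen, overlap, FALSE)
  f <- W$freqs; M <- sqrt(W$psd); K <- length(f)
  tot <- sum(M)
  sco <- sum(f * M) / tot
  spr <- 0; for (k in seq_len(K)) spr <- spr + (f[k] - sco)^2 * M[k]
  spr <- spr / tot
  m3 <- 0; m4 <- 0
  for (k in seq_len(K)) {
    m3 <- m3 + (f[k] - sco)^3 * M[k]
    m4 <- m4 + (f[k] - sco)^4 * M[k]
  }
  skw <- if (spr > 0) (m3 / tot) / spr^1.5 else NA_real_
  kur <- if (spr > 0) (m4 / tot) / spr^2 - 3 else NA_real_
  cum <- 0; smed <- NA_real_
  for (k in seq_len(K)) { cum <- cum + M[k]
    if (cum >= 0.5 * tot) { smed <- f[k]; break } }
  cum <- 0; sro <- NA_real_
  for (k in seq_len(K)) { cum <- cum + M[k]
    if (cum >= 0.85 * tot) { sro <- f[k]; break } }

  am <- mean(M)
  crest <- max(M) / am
  flat <- if (any(M == 0)) 0 else exp(mean(log(M))) / am
  p <- W$psd / sum(W$psd)
  pse <- 0; for (k in seq_len(K)) if (p[k] > 0) pse <- pse - p[k] * log2(p[k])
  fb <- mean(f)
  slope <- sum((f - fb) * (M - am)) / sum((f - fb)^2)
  S <- nrow(W$segPsd)
  flux <- NA_real_
  if (S >= 2) {
    segM <- sqrt(W$segPsd)
    flux <- 0
    for (s in seq_len(S - 1)) {
      a <- segM[s, ] / sum(segM[s, ]); b <- segM[s + 1, ] / sum(segM[s + 1, ])
      flux <- flux + sqrt(sum((b - a)^2))
    }
    flux <- flux / (S - 1)
  }

  W0 <- oracleWelch(rho, tr, seglen, overlap, TRUE)
  f0 <- W0$freqs[-1]; p0 <- W0$psd[-1]
  nyq <- 1 / (2 * tr)
  peak <- NA_real_
  if (any(p0 > 0)) {
    edges <- seq(0, nyq, length.out = bins + 1)
    bestBin <- 0; bestAvg <- -Inf
    for (b in seq_len(bins)) {
      sel <- f0 > edges[b] & f0 <= edges[b + 1]
      if (any(sel) && mean(p0[sel]) > bestAvg) {
        bestAvg <- mean(p0[sel]); bestBin <- b
      }
    }
    sel <- f0 > edges[bestBin] & f0 <= edges[bestBin + 1]
    peak <- f0[sel][which.max(p0[sel])]
  }
  inb <- f0 >= band[1] & f0 <= band[2]
  alff <- mean(sqrt(p0[inb]))

  c(MV = mv, VAR = va, PAV = pav, ZC = zc, SCO = sco, SPR = spr, SKW = skw,
    KURT = kur, SMED = smed, SRO = sro, PEAK = peak, CREST = crest,
    FLUX = flux, SLOPE = slope, FLAT = flat, PSE = pse, ALFF_dFC = alff)
}

# brute-force Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= i*q/m, reject everything at or below it; adjusted values by the
# defining minimum
oracleBH <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  rej <- logical(m)
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * ps[j] / j)
    adj[o[i]] <- min(1, min(vals))
  }
  list(adjusted = adj, rejected = rej)
}
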