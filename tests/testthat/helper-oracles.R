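# Independent naive-loop oracles for the feature battery and the
# Kruskal-Wallis statistic. Deliberately written with explicit loops /
# direct DFT so they share no code path with the package implementation.

oracle_dft_periodogram <- function(x, fs) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)     # direct DFT matrix
  X <- as.vector(W %*% x)
  nh <- n %/% 2 + 1
  p <- Mod(X[1:nh])^2 / n^2
  for (i in 2:(nh - if (n %% 2 == 0) 1 else 0)) p[i] <- 2 * p[i]
  list(freqs = (0:(nh - 1)) * fs / n, power = p)
}

oracle_band_powers <- function(psd, bands) {
  absb <- numeric(nrow(bands))
  total <- 0
  for (i in seq_along(psd$power)) total <- total + psd$power[i]
  for (b in seq_len(nrow(bands))) {
    s <- 0
    for (i in seq_along(psd$freqs)) {
      f <- psd$freqs[i]
      if (f >= bands$lo[b] && f < bands$hi[b]) s <- s + psd$power[i]
    }
    absb[b] <- s
  }
  relb <- if (total > 0) absb / total else rep(0, length(absb))
  c(absb, relb)
}

oracle_entropies <- function(power) {
  total <- sum(power)
  if (total == 0) return(c(0, 0))
  h_raw <- 0; h_norm <- 0
  for (v in power) {
    if (v > 0) h_raw <- h_raw - v * log(v)
    q <- v / total
    if (q > 0) h_norm <- h_norm - q * log(q)
  }
  c(h_raw, h_norm)
}

# Kaspar-Schuster scan, 1-indexed transcription
oracle_lz76 <- function(s) {
  n <- length(s)
  if (n == 0) return(0)
  if (n == 1) return(1)
  c0 <- 1; l <- 1; i <- 0; k <- 1; kmax <- 1
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1
      if (l + k > n) { c0 <- c0 + 1; break }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1
      if (i == l) {
        c0 <- c0 + 1; l <- l + kmax
        if (l + 1 > n) break
        i <- 0; k <- 1; kmax <- 1
      } else k <- 1
    }
  }
  c0
}

oracle_time_features <- function(x, fs) {
  n <- length(x)
  sx <- 0; for (v in x) sx <- sx + v
  mu <- sx / n
  v2 <- 0; m3 <- 0; m4 <- 0; en <- 0; sx6 <- 0
  for (xi in x) {
    c <- xi - mu
    v2 <- v2 + c^2; m3 <- m3 + c^3; m4 <- m4 + c^4
    en <- en + xi^2; sx6 <- sx6 + xi^6
  }
  v2 <- v2 / n; m3 <- m3 / n; m4 <- m4 / n
  s <- sqrt(v2)
  dx <- numeric(n - 1); for (i in 2:n) dx[i - 1] <- x[i] - x[i - 1]
  mdx <- sum(dx) / (n - 1)
  vd <- 0; for (d in dx) vd <- vd + (d - mdx)^2
  vd <- vd / (n - 1)
  ddx <- numeric(n - 2); for (i in 2:(n - 1)) ddx[i - 1] <- dx[i] - dx[i - 1]
  mddx <- sum(ddx) / (n - 2)
  vdd <- 0; for (d in ddx) vdd <- vdd + (d - mddx)^2
  vdd <- vdd / (n - 2)
  mob <- if (v2 > 0) sqrt(vd / v2) else 0
  mob_d <- if (vd > 0) sqrt(vdd / vd) else 0
  cplx <- if (mob > 0) mob_d / mob else 0
  cl <- 0; for (d in dx) cl <- cl + abs(d)
  tg <- 0; for (i in 2:(n - 1)) tg <- tg + x[i]^2 - x[i - 1] * x[i + 1]
  ent <- 0
  if (s > 0) {
    cnt <- integer(100)
    for (xi in x) {
      z <- (xi - mu) / s
      b <- ceiling((z + 5) / 0.1)
      if (b < 1) b <- 1
      if (b > 100) b <- 100
      cnt[b] <- cnt[b] + 1
    }
    for (cc in cnt) if (cc > 0) { p <- cc / n; ent <- ent - p * log(p) }
  }
  srt <- sort(x)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  c(signal_entropy = ent,
    lzc = oracle_lz76(as.integer(x >= mu)),
    curve_length = cl, energy = en, nonlinear_energy = tg,
    sixth_power = sx6, min = min(x), max = max(x), median = med,
    variance = v2, std = s,
    skew = if (v2 > 0) m3 / s^3 else 0,
    kurtosis = if (v2 > 0) m4 / v2^2 else 0,
    integral = sx / fs, mobility = mob, complexity = cplx)
}

# full per-channel oracle block in battery order
oracle_channel_features <- function(x, fs, bands) {
  psd <- oracle_dft_periodogram(x, fs)
  c(oracle_band_powers(psd, bands), oracle_entropies(psd$power),
    oracle_time_features(x, fs))
}

# rank-based Kruskal-Wallis recomputed with explicit counting
oracle_kruskal_H <- function(a, b) {
  x <- c(a, b)
  N <- length(x)
  r <- numeric(N)
  for (i in 1:N) {
    smaller <- 0; equal <- 0
    for (j in 1:N) {
      if (x[j] < x[i]) smaller <- smaller + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- smaller + (equal + 1) / 2      # mid-rank
  }
  R1 <- sum(r[seq_along(a)]); R2 <- sum(r[-seq_along(a)])
  H <- 12 / (N * (N + 1)) * (R1^2 / length(a) + R2^2 / length(b)) -
    3 * (N + 1)
  tie <- 0
  for (u in unique(x)) {
    t <- sum(x == u)
    tie <- tie + t^3 - t
  }
  corr <- 1 - tie / (N^3 - N)
  if (corr > 0) H / corr else 0
}

expect_rel_equal <- function(a, b, tol = 1e-9) {
  expect_true(all(abs(a - b) <= tol * pmax(1, abs(a), abs(b))),
              label = paste("max dev",
                            max(abs(a - b) / pmax(1, abs(a), abs(b)))))
}
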