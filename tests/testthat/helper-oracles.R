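# Independent brute-force oracles: explicit loops, no FFT, no shared code
# with the package implementation.

# population moments, sum of |x|, least-squares slope, via direct sums
oracle_oxy <- function(x, sfreq) {
  n <- length(x)
  m <- 0; for (v in x) m <- m + v; m <- m / n
  v2 <- 0; v3 <- 0; v4 <- 0
  for (v in x) {
    v2 <- v2 + (v - m)^2; v3 <- v3 + (v - m)^3; v4 <- v4 + (v - m)^4
  }
  v2 <- v2 / n; v3 <- v3 / n; v4 <- v4 / n
  auc <- 0; for (v in x) auc <- auc + abs(v)
  t <- (seq_len(n) - 1) / sfreq
  tm <- mean(t)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    num <- num + (t[i] - tm) * (x[i] - m)
    den <- den + (t[i] - tm)^2
  }
  c(peak = max(x), average = m, variance = v2,
    skewness = v3 / v2^1.5, kurtosis = v4 / v2^2,
    auc = auc, slope = num / den)
}

# loop-DFT Welch magnitude-squared coherence
oracle_welch <- function(x, y, seg_len, step, taper) {
  n <- length(x)
  starts <- seq(1, n - seg_len + 1, by = step)
  nbins <- seg_len %/% 2 + 1
  gxx <- gyy <- numeric(nbins)
  gxy <- complex(nbins)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1)]; xs <- (xs - mean(xs)) * taper
    ys <- y[s:(s + seg_len - 1)]; ys <- (ys - mean(ys)) * taper
    for (k in seq_len(nbins)) {
      Xk <- 0+0i; Yk <- 0+0i
      for (t in seq_len(seg_len)) {
        ph <- exp(-2i * pi * (k - 1) * (t - 1) / seg_len)
        Xk <- Xk + xs[t] * ph
        Yk <- Yk + ys[t] * ph
      }
      gxx[k] <- gxx[k] + Mod(Xk)^2
      gyy[k] <- gyy[k] + Mod(Yk)^2
      gxy[k] <- gxy[k] + Xk * Conj(Yk)
    }
  }
  (Mod(gxy)^2 / (gxx * gyy))[-1] # drop DC, like the implementation
}

# loop-DFT Morlet continuous wavelet transform (time x scale)
oracle_cwt <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  xhat <- complex(npad)
  for (k in 0:(npad - 1)) {
    acc <- 0+0i
    for (t in 0:(npad - 1)) acc <- acc + xp[t + 1] * exp(-2i * pi * k * t / npad)
    xhat[k + 1] <- acc
  }
  omega <- numeric(npad)
  for (k in 0:(npad - 1)) {
    omega[k + 1] <- (if (k <= npad / 2) k else k - npad) * 2 * pi / (npad * dt)
  }
  W <- matrix(0+0i, n, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- numeric(npad)
    for (k in seq_len(npad)) {
      psi[k] <- if (omega[k] > 0) {
        pi^(-1 / 4) * sqrt(2 * pi * s / dt) * exp(-0.5 * (s * omega[k] - omega0)^2)
      } else 0
    }
    for (t in 0:(n - 1)) {
      acc <- 0+0i
      for (k in 0:(npad - 1)) {
        acc <- acc + xhat[k + 1] * psi[k + 1] * exp(2i * pi * k * t / npad)
      }
      W[t + 1, si] <- acc / npad
    }
  }
  W
}

# loop-DFT time smoothing (frequency-domain Gaussian, sd = scale) followed
# by loop boxcar smoothing across scales with edge renormalization
oracle_smooth <- function(field, scales, dt, dj) {
  n <- nrow(field); ns <- ncol(field)
  npad <- 2^ceiling(log2(2 * n))
  omega <- numeric(npad)
  for (k in 0:(npad - 1)) {
    omega[k + 1] <- (if (k <= npad / 2) k else k - npad) * 2 * pi / (npad * dt)
  }
  sm <- matrix(0+0i, n, ns)
  for (si in seq_len(ns)) {
    xp <- c(field[, si], rep(0, npad - n))
    xhat <- complex(npad)
    for (k in 0:(npad - 1)) {
      acc <- 0+0i
      for (t in 0:(npad - 1)) acc <- acc + xp[t + 1] * exp(-2i * pi * k * t / npad)
      xhat[k + 1] <- acc
    }
    for (t in 0:(n - 1)) {
      acc <- 0+0i
      for (k in 0:(npad - 1)) {
        acc <- acc + xhat[k + 1] * exp(-0.5 * (scales[si] * omega[k + 1])^2) *
          exp(2i * pi * k * t / npad)
      }
      sm[t + 1, si] <- acc / npad
    }
  }
  w <- max(1L, as.integer(round(0.6 / dj)))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  out <- sm
  for (si in seq_len(ns)) {
    win <- max(1L, si - half_lo):min(ns, si + half_hi)
    for (t in seq_len(n)) out[t, si] <- mean(sm[t, win])
  }
  out
}

# full Eq.-style wavelet coherence assembled from the loop oracles
oracle_wavelet_coherence <- function(x, y, sfreq, dj, omega0 = 6,
                                     max_period = 12.8) {
  dt <- 1 / sfreq
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- 2 * dt
  J <- floor(log2((max_period / ff) / s0) / dj)
  scales <- s0 * 2^((0:J) * dj)
  Wx <- oracle_cwt(x, dt, scales, omega0)
  Wy <- oracle_cwt(y, dt, scales, omega0)
  inv_s <- matrix(rep(1 / scales, each = length(x)), length(x))
  sxx <- Re(oracle_smooth(Mod(Wx)^2 * inv_s, scales, dt, dj))
  syy <- Re(oracle_smooth(Mod(Wy)^2 * inv_s, scales, dt, dj))
  sxy <- oracle_smooth(Wx * Conj(Wy) * inv_s, scales, dt, dj)
  rsq <- Mod(sxy)^2 / (sxx * syy)
  list(rsq = t(pmin(pmax(rsq, 0), 1)), scales = scales, period = ff * scales)
}
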