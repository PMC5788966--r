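# Five pairwise connectivity measures: covariance, Pearson, Spearman,
# Welch magnitude-squared coherence, and Morlet wavelet coherence
# (Torrence-Compo construction with Grinsted-style smoothing). Time-domain
# measures use the 80-sample kept window; the two coherence measures are
# computed on the full 200-sample epoch (wavelet maps are cropped to the
# central 80 time points before band averaging).

#' Names of the connectivity measures, in canonical order
#' @return Character vector of length 5.
#' @export
connectivity_measure_names <- function() {
  c("covariance", "pearson", "spearman", "coherence", "wavelet_coherence")
}

#' Pairwise covariance (sample convention, divisor N - 1)
#' @param x,y Equal-length numeric vectors.
#' @return Scalar covariance.
#' @export
covariance_pair <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  stats::cov(x, y)
}

#' Pearson correlation of a signal pair
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @return Scalar in `[-1, 1]`, or NA (with warning) if either signal is
#'   constant.
#' @export
pearson_pair <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance signal: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Spearman rank correlation of a signal pair
#'
#' Pearson correlation applied to the average ranks of the two signals.
#' @param x,y Equal-length numeric vectors.
#' @return Scalar in `[-1, 1]`, or NA (with warning) for an all-tied signal.
#' @export
spearman_pair <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("all-tied signal: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

## ---- Welch magnitude-squared coherence -------------------------------------

welch_taper <- function(seg_len, window) {
  switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)),
    rectangular = rep(1, seg_len),
    stop("unknown taper: ", window)
  )
}

welch_starts <- function(n, seg_len, overlap) {
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  starts
}

# complex segment spectra for all columns of `mat`: array [nbins, K, nch]
welch_segment_fft <- function(mat, seg_len, overlap, window) {
  n <- nrow(mat)
  starts <- welch_starts(n, seg_len, overlap)
  taper <- welch_taper(seg_len, window)
  nbins <- seg_len %/% 2 + 1
  out <- array(0+0i, dim = c(nbins, length(starts), ncol(mat)))
  for (k in seq_along(starts)) {
    seg <- mat[starts[k]:(starts[k] + seg_len - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * taper
    sp <- stats::mvfft(seg)
    out[, k, ] <- sp[seq_len(nbins), , drop = FALSE]
  }
  out
}

#' Welch magnitude-squared coherence of a signal pair
#'
#' Segment-averaged auto- and cross-spectra, then
#' `C_xy(f) = |G_xy(f)|^2 / (G_xx(f) G_yy(f))` per frequency bin. With a
#' single segment the estimator is identically 1 regardless of the signals,
#' so `K >= 2` segments are required. Defaults (segment length 100, 50%
#' overlap, Hamming taper) give K = 3 segments on a 200-sample epoch while
#' still resolving the 0.078 Hz band edge.
#'
#' @param x,y Equal-length numeric vectors.
#' @param sfreq Sampling rate in Hz.
#' @param seg_len Segment length in samples (default 100).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window Taper: "hamming" (default), "hann" or "rectangular".
#' @return A tibble of class `coherence_spectrum` with columns `freq` (Hz,
#'   DC excluded) and `coherence` in `[0, 1]`; attributes `seg_len`,
#'   `overlap`, `window`, `n_segments`.
#' @export
spectral_coherence <- function(x, y, sfreq, seg_len = 100, overlap = 0.5,
                               window = "hamming") {
  if (length(x) != length(y)) stop("signals must have equal length")
  n <- length(x)
  if (n < seg_len) stop("signals shorter than one segment")
  K <- length(welch_starts(n, seg_len, overlap))
  if (K < 2) {
    stop("only one Welch segment fits (estimate would be identically 1); ",
         "shorten `seg_len` or provide longer signals")
  }
  sp <- welch_segment_fft(cbind(x, y), seg_len, overlap, window)
  X <- sp[, , 1]; Y <- sp[, , 2]
  gxx <- rowMeans(Mod(X)^2)
  gyy <- rowMeans(Mod(Y)^2)
  gxy <- rowMeans(X * Conj(Y))
  coh <- Mod(gxy)^2 / (gxx * gyy)
  freq <- (seq_len(nrow(X)) - 1) * sfreq / seg_len
  keep <- freq > 0
  out <- tibble::tibble(freq = freq[keep],
                        coherence = pmin(pmax(coh[keep], 0), 1))
  structure(out, seg_len = seg_len, overlap = overlap, window = window,
            n_segments = K,
            class = c("coherence_spectrum", class(out)))
}

## ---- Morlet continuous wavelet transform -----------------------------------

#' Fourier factor of the Morlet wavelet
#'
#' Converts wavelet scale to equivalent Fourier period:
#' `period = 4 * pi / (omega0 + sqrt(2 + omega0^2)) * scale` (about 1.033 for
#' `omega0 = 6`).
#' @param omega0 Morlet center frequency (default 6).
#' @return Scalar factor.
#' @export
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

morlet_scales <- function(n, dt, dj, s0, max_period) {
  ff <- morlet_fourier_factor()
  s_max <- max_period / ff
  J <- floor(log2(s_max / s0) / dj)
  if (J < 1) stop("signal/sampling configuration leaves no valid wavelet scale")
  s0 * 2^((0:J) * dj)
}

# Morlet CWT via zero-padded FFT; returns n x nscale (time x scale)
morlet_cwt_t <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  xf <- stats::fft(xp)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  # daughter-wavelet spectra for all scales at once (columns = scales)
  norm0 <- pi^(-1 / 4)
  arg <- outer(omega, scales) - omega0
  psi <- norm0 * exp(-0.5 * arg^2) * (omega > 0)
  psi <- sweep(psi, 2, sqrt(2 * pi * scales / dt), "*")
  W <- stats::mvfft(psi * xf, inverse = TRUE) / npad
  W[seq_len(n), , drop = FALSE]
}

# conventional scales x time orientation
morlet_cwt <- function(x, dt, scales, omega0 = 6) {
  t(morlet_cwt_t(x, dt, scales, omega0))
}

## ---- Torrence-Compo smoothing operator ------------------------------------

# Gaussian time smoothing (sd = scale, per row) via zero-padded FFT
smooth_time <- function(field, scales, dt) {
  n <- ncol(field)
  npad <- 2^ceiling(log2(2 * n))
  pad <- matrix(0+0i, nrow(field), npad)
  pad[, seq_len(n)] <- field
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  F <- t(stats::mvfft(t(pad)))
  K <- exp(-0.5 * outer(scales, omega)^2)
  sm <- t(stats::mvfft(t(F * K), inverse = TRUE)) / npad
  sm[, seq_len(n), drop = FALSE]
}

# boxcar smoothing across scales over the Morlet decorrelation length 0.6
smooth_scale <- function(field, dj) {
  w <- max(1L, as.integer(round(0.6 / dj)))
  ns <- nrow(field)
  if (w <= 1 || ns == 1) return(field)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- apply(field, 2, cumsum)
  cs <- rbind(0, cs)
  idx <- seq_len(ns)
  lo <- pmax(1L, idx - half_lo)
  hi <- pmin(ns, idx + half_hi)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

# the full smoothing operator S applied to a (possibly complex) field
smooth_operator <- function(field, scales, dt, dj) {
  sm <- smooth_time(field, scales, dt)
  sm <- smooth_scale(sm, dj)
  sm
}

# column-layout variants (time along rows): no transposes around mvfft
smooth_time_cols <- function(fieldT, scales_per_col, dt) {
  n <- nrow(fieldT)
  npad <- 2^ceiling(log2(2 * n))
  pad <- matrix(0+0i, npad, ncol(fieldT))
  pad[seq_len(n), ] <- fieldT
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  F <- stats::mvfft(pad)
  K <- exp(-0.5 * outer(omega, scales_per_col)^2)
  sm <- stats::mvfft(F * K, inverse = TRUE) / npad
  sm[seq_len(n), , drop = FALSE]
}

# boxcar-in-scale as an nscale x nscale weight matrix (edge-renormalized)
scale_boxcar_matrix <- function(ns, dj) {
  w <- max(1L, as.integer(round(0.6 / dj)))
  if (w <= 1 || ns == 1) return(diag(ns))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  B <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    win <- max(1L, i - half_lo):min(ns, i + half_hi)
    B[win, i] <- 1 / length(win)
  }
  B
}

#' Wavelet coherence of a signal pair
#'
#' Continuous Morlet wavelet transforms of `x` and `y` on a
#' dyadic-fractional scale grid; the squared coherence
#' `R_n^2(s) = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) S(|W_y|^2 / s))` where
#' `W_xy = W_x conj(W_y)` is the cross-wavelet transform and `S` smooths in
#' time (Gaussian of width matched to scale) and across scales (boxcar over
#' the Morlet decorrelation length). Without smoothing the expression is
#' identically 1 for any pair, which is why `S` is mandatory;
#' `smooth = FALSE` exists only to demonstrate that identity.
#'
#' @param x,y Equal-length numeric vectors, length >= 64.
#' @param sfreq Sampling rate in Hz.
#' @param omega0 Morlet center frequency (default 6).
#' @param dj Scale spacing in octaves (default 1/12).
#' @param s0 Smallest scale (default `2 / sfreq`, i.e. two sampling periods).
#' @param max_period Largest equivalent Fourier period in s (default 12.8,
#'   the lower edge of the standard fNIRS connectivity band).
#' @param smooth Apply the smoothing operator (default TRUE).
#' @return List of class `wavelet_coherence_map`: `rsq` (scales x time,
#'   values in `[0, 1]`), `scale`, `period` (s), `freq` (Hz), `time`
#'   (sample indices), `params`.
#' @export
wavelet_coherence <- function(x, y, sfreq, omega0 = 6, dj = 1 / 12,
                              s0 = 2 / sfreq, max_period = 12.8,
                              smooth = TRUE) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 64) stop("need at least 64 samples for wavelet coherence")
  dt <- 1 / sfreq
  scales <- morlet_scales(length(x), dt, dj, s0, max_period)
  Wx <- morlet_cwt(x, dt, scales, omega0)
  Wy <- morlet_cwt(y, dt, scales, omega0)
  cross_map(Wx, Wy, scales, dt, dj, omega0, smooth,
            time = seq_along(x), sfreq = sfreq)
}

# build the coherence map from two precomputed transforms
cross_map <- function(Wx, Wy, scales, dt, dj, omega0, smooth, time, sfreq,
                      sxx = NULL, syy = NULL) {
  inv_s <- 1 / scales
  if (smooth) {
    if (is.null(sxx)) sxx <- smooth_operator(Mod(Wx)^2 * inv_s, scales, dt, dj)
    if (is.null(syy)) syy <- smooth_operator(Mod(Wy)^2 * inv_s, scales, dt, dj)
    sxy <- smooth_operator(Wx * Conj(Wy) * inv_s, scales, dt, dj)
    rsq <- Mod(sxy)^2 / (Re(sxx) * Re(syy))
  } else {
    rsq <- Mod(Wx * Conj(Wy))^2 / (Mod(Wx)^2 * Mod(Wy)^2)
  }
  rsq <- pmin(pmax(Re(rsq), 0), 1)
  ff <- morlet_fourier_factor(omega0)
  structure(list(
    rsq = rsq, scale = scales, period = ff * scales, freq = 1 / (ff * scales),
    time = time, sfreq = sfreq,
    params = list(omega0 = omega0, dj = dj, s0 = scales[1],
                  fourier_factor = ff, smoothed = smooth)
  ), class = "wavelet_coherence_map")
}

#' Crop a wavelet coherence map to its central time points
#'
#' Removes edge-affected time points: transforms are computed on the full
#' epoch, then only the `keep` centered columns are retained for averaging.
#'
#' @param map A `wavelet_coherence_map`.
#' @param keep Number of central time points to keep (default 80).
#' @return The cropped map.
#' @export
crop_map <- function(map, keep = 80) {
  n <- ncol(map$rsq)
  if (keep > n) stop("cannot keep ", keep, " of ", n, " time points")
  start <- (n - keep) %/% 2 + 1
  idx <- start:(start + keep - 1)
  map$rsq <- map$rsq[, idx, drop = FALSE]
  map$time <- map$time[idx]
  map
}

#' Frequency band for coherence averaging
#'
#' Default band 0.078125-0.3125 Hz (periods 3.2-12.8 s), the standard band
#' for fNIRS functional connectivity.
#'
#' @param low,high Band edges in Hz.
#' @return List of class `band_spec`.
#' @export
band_spec <- function(low = 1 / 12.8, high = 1 / 3.2) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  structure(list(low = low, high = high), class = "band_spec")
}

#' Band-averaged coherence
#'
#' Unweighted mean of coherence values over all frequency bins (spectra) or
#' all (scale, time) points (wavelet maps) whose equivalent frequency lies in
#' the closed band.
#'
#' @param x A `coherence_spectrum` or `wavelet_coherence_map`.
#' @param band A [band_spec()].
#' @return Scalar in `[0, 1]`.
#' @export
band_average <- function(x, band = band_spec()) {
  UseMethod("band_average")
}

#' @export
band_average.coherence_spectrum <- function(x, band = band_spec()) {
  sel <- x$freq >= band$low & x$freq <= band$high
  if (!any(sel)) {
    stop(sprintf(
      "no frequency bin inside [%.5g, %.5g] Hz (grid: %.5g..%.5g Hz, %d bins)",
      band$low, band$high, min(x$freq), max(x$freq), length(x$freq)
    ))
  }
  mean(x$coherence[sel])
}

#' @export
band_average.wavelet_coherence_map <- function(x, band = band_spec()) {
  sel <- x$freq >= band$low & x$freq <= band$high
  if (!any(sel)) {
    stop(sprintf(
      "no wavelet scale inside [%.5g, %.5g] Hz (grid: %.5g..%.5g Hz, %d scales)",
      band$low, band$high, min(x$freq), max(x$freq), length(x$freq)
    ))
  }
  mean(x$rsq[sel, , drop = FALSE])
}

#' @export
print.wavelet_coherence_map <- function(x, ...) {
  cat(sprintf(
    "<wavelet_coherence_map> %d scales (periods %.2f-%.2f s) x %d time points%s\n",
    length(x$scale), min(x$period), max(x$period), ncol(x$rsq),
    if (x$params$smoothed) "" else " [unsmoothed]"
  ))
  invisible(x)
}

#' Plot a wavelet coherence map
#'
#' @param object A `wavelet_coherence_map`.
#' @param ... Unused.
#' @return A ggplot raster of squared coherence over time and period
#'   (log2 period axis, as is conventional for wavelet spectra).
#' @method autoplot wavelet_coherence_map
#' @export
autoplot.wavelet_coherence_map <- function(object, ...) {
  df <- tibble::tibble(
    period = rep(object$period, each = ncol(object$rsq)),
    time_s = rep((object$time - 1) / object$sfreq, times = nrow(object$rsq)),
    rsq = as.vector(t(object$rsq))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$period,
                                   fill = .data$rsq)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(R^2)) +
    ggplot2::labs(x = "Time (s)", y = "Period (s)",
                  title = "Wavelet coherence") +
    ggplot2::theme_minimal()
}

## ---- Batch extraction ------------------------------------------------------

#' Extract connectivity features from preprocessed epochs
#'
#' Computes the five connectivity measures for every unordered channel pair,
#' epoch and chromophore. Covariance, Pearson and Spearman are computed on
#' the 80-sample kept window; the two coherence measures are computed on the
#' full epoch and band-averaged (wavelet maps are first cropped to the
#' central `keep` time points). Per-channel wavelet transforms are computed
#' once per epoch and reused across pairs.
#'
#' @param epochs A `fnirs_epochs`.
#' @param measures Subset of [connectivity_measure_names()] (default all).
#' @param band [band_spec()] for the coherence averages.
#' @param keep Kept-window length (default 80).
#' @param seg_len,overlap,window Welch estimator parameters.
#' @param omega0,dj,max_period Morlet wavelet parameters.
#' @return Tidy tibble: `landing`, `condition`, `epoch`, `ch_a`, `ch_b`,
#'   `chromophore`, `measure`, `value`.
#' @export
extract_connectivity <- function(epochs,
                                 measures = connectivity_measure_names(),
                                 band = band_spec(), keep = 80,
                                 seg_len = 100, overlap = 0.5,
                                 window = "hamming",
                                 omega0 = 6, dj = 1 / 12, max_period = 12.8) {
  measures <- match.arg(measures, connectivity_measure_names(),
                        several.ok = TRUE)
  fs <- montage_sfreq(epochs$montage)
  dt <- 1 / fs
  channels <- epochs$montage$channel
  n_ch <- length(channels)
  pairs <- channel_pairs(epochs$montage)
  pair_i <- match(pairs$ch_a, channels)
  pair_j <- match(pairs$ch_b, channels)
  want_wc <- "wavelet_coherence" %in% measures
  want_sc <- "coherence" %in% measures

  res <- purrr::imap_dfr(epochs$epochs, function(ep, idx) {
    meta <- epochs$info[idx, ]
    purrr::map_dfr(c(HbO = "hbo", HbR = "hbr"), function(slot) {
      mat <- ep[[slot]]
      win <- central_window(mat, epoch_len = nrow(mat), keep = keep)
      out <- list()
      if ("covariance" %in% measures) {
        cv <- stats::cov(win)
        out$covariance <- cv[cbind(pair_i, pair_j)]
      }
      if ("pearson" %in% measures) {
        cr <- suppressWarnings(stats::cor(win))
        out$pearson <- cr[cbind(pair_i, pair_j)]
      }
      if ("spearman" %in% measures) {
        rs <- suppressWarnings(stats::cor(win, method = "spearman"))
        out$spearman <- rs[cbind(pair_i, pair_j)]
      }
      if (want_sc) {
        sp <- welch_segment_fft(mat, seg_len, overlap, window)
        freq <- (seq_len(dim(sp)[1]) - 1) * fs / seg_len
        bsel <- freq >= band$low & freq <= band$high & freq > 0
        if (!any(bsel)) stop("no Welch frequency bin inside the band")
        auto <- vapply(seq_len(n_ch), function(c) {
          rowMeans(Mod(sp[, , c, drop = FALSE])^2)[bsel]
        }, numeric(sum(bsel)))
        out$coherence <- vapply(seq_len(nrow(pairs)), function(p) {
          i <- pair_i[p]; j <- pair_j[p]
          gxy <- rowMeans(sp[, , i] * Conj(sp[, , j]))[bsel]
          mean(Mod(gxy)^2 / (auto[, i] * auto[, j]))
        }, numeric(1))
      }
      if (want_wc) {
        scales <- morlet_scales(nrow(mat), dt, dj, 2 * dt, max_period)
        ns <- length(scales)
        inv_s <- 1 / scales
        ff <- morlet_fourier_factor(omega0)
        fsel <- which(1 / (ff * scales) >= band$low &
                        1 / (ff * scales) <= band$high)
        if (length(fsel) == 0) stop("no wavelet scale inside the band")
        tstart <- (nrow(mat) - keep) %/% 2 + 1
        tidx <- tstart:(tstart + keep - 1)
        # only scales feeding the band average are needed: the boxcar in
        # scale couples each target scale to at most +/- half its width
        w_box <- max(1L, as.integer(round(0.6 / dj)))
        half_lo <- (w_box - 1L) %/% 2L
        half_hi <- w_box - 1L - half_lo
        ssel <- max(1L, min(fsel) - half_lo):min(ns, max(fsel) + half_hi)
        B <- scale_boxcar_matrix(ns, dj)[ssel, fsel, drop = FALSE]
        scales_s <- scales[ssel]
        inv_s <- 1 / scales_s
        ns <- length(ssel)
        Ws <- lapply(seq_len(n_ch), function(c) {
          morlet_cwt_t(mat[, c], dt, scales_s, omega0) # time x scale
        })
        # time smoothing is batched: pair fields stacked column-wise, one
        # FFT pass per chunk; scale smoothing is a small matrix product
        auto_stack <- do.call(cbind, lapply(Ws, function(W) {
          sweep(Mod(W)^2, 2, inv_s, "*")
        }))
        sm_auto <- Re(smooth_time_cols(auto_stack, rep(scales_s, n_ch), dt))
        autos <- lapply(seq_len(n_ch), function(c) {
          sm_auto[, (c - 1) * ns + seq_len(ns), drop = FALSE] %*% B
        })
        np <- nrow(pairs)
        vals <- numeric(np)
        chunk <- max(1L, 6000L %/% ns)
        for (start in seq(1L, np, by = chunk)) {
          idx <- start:min(np, start + chunk - 1L)
          cross_stack <- do.call(cbind, lapply(idx, function(p) {
            sweep(Ws[[pair_i[p]]] * Conj(Ws[[pair_j[p]]]), 2, inv_s, "*")
          }))
          sm <- smooth_time_cols(cross_stack, rep(scales_s, length(idx)), dt)
          for (q in seq_along(idx)) {
            p <- idx[q]
            cols <- (q - 1) * ns + seq_len(ns)
            sxy <- sm[, cols, drop = FALSE] %*% B
            rsq <- Mod(sxy)^2 / (autos[[pair_i[p]]] * autos[[pair_j[p]]])
            rsq <- pmin(pmax(Re(rsq), 0), 1)
            vals[p] <- mean(rsq[tidx, ])
          }
        }
        out$wavelet_coherence <- vals
      }
      purrr::imap_dfr(out, function(vals, m) {
        tibble::tibble(ch_a = pairs$ch_a, ch_b = pairs$ch_b,
                       measure = m, value = vals)
      })
    }, .id = "chromophore") |>
      dplyr::mutate(landing = meta$landing, condition = meta$condition,
                    epoch = meta$epoch) |>
      dplyr::select("landing", "condition", "epoch", "ch_a", "ch_b",
                    "chromophore", "measure", "value")
  })
  res
}
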