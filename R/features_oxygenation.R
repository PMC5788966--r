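# Seven per-channel oxygenation features computed on each 80-sample kept
# window, separately for HbO and HbR. Moments use the population (1/N)
# convention, matching the expectation form of the defining equations;
# kurtosis is non-excess (Gaussian -> 3).

#' Names of the oxygenation features, in canonical order
#' @return Character vector of length 7.
#' @export
oxygenation_feature_names <- function() {
  c("peak", "average", "variance", "skewness", "kurtosis", "auc", "slope")
}

#' Oxygenation features of a single window
#'
#' * `peak`: maximum of the signed signal.
#' * `average`, `variance`: first two population moments.
#' * `skewness`, `kurtosis`: third and fourth standardized population moments
#'   (kurtosis non-excess); undefined (NA, with a warning) for a
#'   zero-variance window.
#' * `auc`: sum of absolute sample values.
#' * `slope`: least-squares linear-regression coefficient against time in
#'   seconds, so its units are concentration per second and independent of
#'   the sampling rate.
#'
#' @param x Numeric vector (a kept window of one channel/chromophore),
#'   length >= 3.
#' @param sfreq Sampling rate in Hz (default 7.8125), used for the slope's
#'   time axis.
#' @return Named numeric vector of the 7 features.
#' @examples
#' oxygenation_features(c(1, -2, 3))[c("auc", "peak", "average")]
#' @export
oxygenation_features <- function(x, sfreq = 7.8125) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v > 0) {
    skew <- mean(d^3) / v^1.5
    kurt <- mean(d^4) / v^2
  } else {
    warning("zero-variance window: skewness and kurtosis undefined")
    skew <- NA_real_
    kurt <- NA_real_
  }
  t_s <- (seq_len(n) - 1) / sfreq
  slope <- sum((t_s - mean(t_s)) * d) / sum((t_s - mean(t_s))^2)
  c(
    peak = max(x), average = m, variance = v,
    skewness = skew, kurtosis = kurt,
    auc = sum(abs(x)), slope = slope
  )
}

#' Extract oxygenation features from preprocessed epochs
#'
#' Computes the 7 features on the 80-sample central window of every epoch,
#' channel and chromophore.
#'
#' @param epochs A `fnirs_epochs` object from [preprocess_session()].
#' @param keep Central-window length (default 80).
#' @return Tidy tibble: `landing`, `condition`, `epoch`, `channel`,
#'   `chromophore` ("HbO"/"HbR"), `feature`, `value`.
#' @export
extract_oxygenation <- function(epochs, keep = 80) {
  fs <- montage_sfreq(epochs$montage)
  channels <- epochs$montage$channel
  purrr::imap_dfr(epochs$epochs, function(ep, i) {
    meta <- epochs$info[i, ]
    purrr::map_dfr(c(HbO = "hbo", HbR = "hbr"), function(slot) {
      win <- central_window(ep[[slot]], epoch_len = nrow(ep[[slot]]), keep = keep)
      feats <- apply(win, 2, oxygenation_features, sfreq = fs)
      tibble::tibble(
        channel = rep(channels, each = nrow(feats)),
        feature = rep(rownames(feats), times = ncol(feats)),
        value = as.numeric(feats)
      )
    }, .id = "chromophore") |>
      dplyr::mutate(landing = meta$landing, condition = meta$condition,
                    epoch = meta$epoch) |>
      dplyr::select("landing", "condition", "epoch", "channel",
                    "chromophore", "feature", "value")
  })
}
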