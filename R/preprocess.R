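# Preprocessing: intensity -> optical density -> artifact correction ->
# Butterworth band-pass -> modified Beer-Lambert inversion -> 200-sample
# epochs with 80-sample central windows. Every epoch is processed
# independently so the pipeline extends to online use.

#' Modified Beer-Lambert law parameters
#'
#' Extinction coefficients, differential pathlength factors (DPF) and
#' source-detector distance used both by the forward model in the simulator
#' and by the inverse in preprocessing. Coefficients default to the packaged
#' constants table (units 1/(M cm)); DPF defaults are 6.4 at 760 nm and 5.75
#' at 850 nm, overridable.
#'
#' @param wavelengths Two wavelengths in nm.
#' @param dpf Differential pathlength factor per wavelength (recycled if
#'   length 1). If `NULL`, wavelength-specific defaults are used.
#' @param distance Source-detector distance in cm.
#' @param extinction Optional 2x2 matrix (rows = wavelengths, columns =
#'   HbO, HbR) overriding the packaged table.
#' @return List of class `mbll_params` with `wavelengths`, `eps` (2x2 matrix),
#'   `dpf`, `distance`.
#' @export
mbll_params <- function(wavelengths = c(760, 850), dpf = NULL, distance = 3,
                        extinction = NULL) {
  stopifnot(length(wavelengths) == 2, distance > 0)
  wavelengths <- sort(wavelengths)
  if (is.null(extinction)) {
    tbl <- extinction_table()
    idx <- match(wavelengths, tbl$wavelength_nm)
    if (anyNA(idx)) {
      stop("no packaged extinction coefficients for wavelength(s) ",
           paste(wavelengths[is.na(idx)], collapse = ", "),
           "; available: ", paste(tbl$wavelength_nm, collapse = ", "),
           " nm (pass `extinction` explicitly for other wavelengths)")
    }
    extinction <- as.matrix(tbl[idx, c("eps_hbo", "eps_hbr")])
  }
  extinction <- matrix(as.numeric(extinction), 2, 2,
                       dimnames = list(wavelengths, c("HbO", "HbR")))
  if (!is.finite(rcond_2x2(extinction)) || rcond_2x2(extinction) < 1e-12) {
    stop("extinction matrix is singular or ill-conditioned")
  }
  if (is.null(dpf)) {
    defaults <- c(`760` = 6.4, `850` = 5.75)
    dpf <- unname(defaults[as.character(wavelengths)])
    dpf[is.na(dpf)] <- 6
  }
  dpf <- rep_len(dpf, 2)
  if (any(dpf <= 0)) stop("DPF must be positive")
  structure(list(wavelengths = wavelengths, eps = extinction, dpf = dpf,
                 distance = distance),
            class = "mbll_params")
}

rcond_2x2 <- function(m) {
  d <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  d / max(abs(m))^2
}

extinction_table <- function() {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "fnirsbci", mustWork = TRUE)
  utils::read.csv(path)
}

extinction_matrix <- function(mbll) mbll$eps

#' Convert raw intensities to optical density
#'
#' `OD(t) = -log10(I(t) / I_ref)`. The default reference is the series mean,
#' so epochs are self-referenced and processed independently.
#'
#' @param intensity Numeric vector or matrix (columns = channels) of strictly
#'   positive intensities.
#' @param reference Reference intensity; default the per-column mean.
#' @return Optical-density series of the same shape.
#' @export
intensity_to_od <- function(intensity, reference = NULL) {
  x <- as.matrix(intensity)
  bad <- which(x <= 0 | !is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity at channel %d, sample %d",
                 bad[1, 2], bad[1, 1]))
  }
  if (is.null(reference)) reference <- colMeans(x)
  reference <- rep_len(reference, ncol(x))
  if (any(reference <= 0)) stop("reference intensity must be positive")
  od <- -log10(sweep(x, 2, reference, "/"))
  if (is.vector(intensity)) drop(od) else od
}

## ---- MODWT (Daubechies-2) motion-artifact correction -----------------------

# db2 (D4) scaling filter
.db2_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db2_g <- rev(.db2_h) * c(1, -1, 1, -1) # QMF wavelet filter

# circular filter for MODWT level j (filter upsampled by 2^(j-1))
modwt_convolve <- function(v, filt, j) {
  n <- length(v)
  out <- numeric(n)
  gap <- 2^(j - 1)
  for (l in seq_along(filt)) {
    idx <- ((seq_len(n) - 1) - (l - 1) * gap) %% n + 1
    out <- out + filt[l] * v[idx]
  }
  out
}

imodwt_convolve <- function(v, filt, j) {
  n <- length(v)
  out <- numeric(n)
  gap <- 2^(j - 1)
  for (l in seq_along(filt)) {
    idx <- ((seq_len(n) - 1) + (l - 1) * gap) %% n + 1
    out <- out + filt[l] * v[idx]
  }
  out
}

modwt <- function(x, n_levels) {
  ht <- .db2_h / sqrt(2)
  gt <- .db2_g / sqrt(2)
  v <- x
  details <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    details[[j]] <- modwt_convolve(v, gt, j)
    v <- modwt_convolve(v, ht, j)
  }
  list(details = details, smooth = v)
}

imodwt <- function(dec) {
  ht <- .db2_h / sqrt(2)
  gt <- .db2_g / sqrt(2)
  v <- dec$smooth
  for (j in rev(seq_along(dec$details))) {
    v <- imodwt_convolve(v, ht, j) + imodwt_convolve(dec$details[[j]], gt, j)
  }
  v
}

#' Wavelet-based motion-artifact correction
#'
#' Decomposes the optical-density epoch with a maximal-overlap discrete
#' wavelet transform (Daubechies-2), zeroes detail coefficients that are
#' outliers under the interquartile rule, and reconstructs. Transient spikes
#' concentrate in few large detail coefficients, so zeroing them suppresses
#' the artifact while the smooth hemodynamic component passes through
#' essentially unchanged.
#'
#' @param od Numeric vector or matrix (columns = channels), length >= 8.
#' @param iqr_factor Outlier rule: coefficients outside
#'   `[Q1 - f * IQR, Q3 + f * IQR]` per level are zeroed (default 1.5).
#' @param n_levels Decomposition depth; default the maximal dyadic depth
#'   `floor(log2(n))`.
#' @return Corrected series, same shape and length as the input.
#' @export
wavelet_artifact_correct <- function(od, iqr_factor = 1.5, n_levels = NULL) {
  if (is.matrix(od)) {
    return(apply(od, 2, wavelet_artifact_correct, iqr_factor = iqr_factor,
                 n_levels = n_levels))
  }
  n <- length(od)
  if (is.null(n_levels)) n_levels <- max(1L, floor(log2(n)))
  if (n < 8) stop("epoch too short for wavelet decomposition")
  if (2^n_levels > n) stop("epoch shorter than required for decomposition depth ", n_levels)
  # reflect to 2n so the circular transform sees a continuous signal;
  # coefficients whose support crosses a reflection junction are boundary
  # coefficients and exempt from zeroing (their large values come from the
  # junction's slope break, not from artifacts)
  xe <- c(od, rev(od))
  N <- 2L * n
  dec <- modwt(xe, n_levels)
  for (j in seq_len(n_levels)) {
    w <- dec$details[[j]]
    Lj <- (2^j - 1) * (length(.db2_h) - 1) + 1
    boundary <- logical(N)
    if (Lj > 1) {
      boundary[seq_len(min(N, Lj - 1))] <- TRUE # support wraps past index 1
      boundary[intersect((n + 1):(n + Lj - 1), seq_len(N))] <- TRUE
    }
    q <- stats::quantile(w, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- (w < q[1] - iqr_factor * iqr | w > q[2] + iqr_factor * iqr) &
      !boundary
    w[out] <- 0
    dec$details[[j]] <- w
  }
  imodwt(dec)[seq_len(n)]
}

## ---- Band-pass filtering ---------------------------------------------------

#' Band-pass filter specification
#'
#' Butterworth high-pass followed by low-pass, with the design orders the
#' analysis prescribes (high-pass cutoff 0.01 Hz order 3; low-pass cutoff
#' 0.5 Hz order 5). The default zero-phase mode applies each filter
#' forward-backward, so no group delay is introduced (offline analysis);
#' `"causal"` retains single-pass filtering for online use.
#'
#' @param high_cut High-pass cutoff (Hz), default 0.01.
#' @param high_order High-pass design order, default 3.
#' @param low_cut Low-pass cutoff (Hz), default 0.5.
#' @param low_order Low-pass design order, default 5.
#' @param mode `"zero-phase"` (default) or `"causal"`.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(high_cut = 0.01, high_order = 3,
                        low_cut = 0.5, low_order = 5,
                        mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  if (!(high_cut > 0 && high_cut < low_cut)) {
    stop("need 0 < high-pass cutoff < low-pass cutoff")
  }
  structure(list(high_cut = high_cut, high_order = high_order,
                 low_cut = low_cut, low_order = low_order, mode = mode),
            class = "filter_spec")
}

#' Apply the Butterworth band-pass
#'
#' @param x Numeric vector or matrix (columns = channels).
#' @param sfreq Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same shape.
#' @export
bandpass <- function(x, sfreq, spec = filter_spec()) {
  nyq <- sfreq / 2
  if (spec$low_cut >= nyq) stop("low-pass cutoff must be below Nyquist (", nyq, " Hz)")
  hp <- signal::butter(spec$high_order, spec$high_cut / nyq, type = "high")
  lp <- signal::butter(spec$low_order, spec$low_cut / nyq, type = "low")
  apply_filt <- function(v) {
    if (spec$mode == "zero-phase") {
      v <- filtfilt_padded(hp$b, hp$a, v)
      filtfilt_padded(lp$b, lp$a, v)
    } else {
      v <- lfilter(hp$b, hp$a, v)
      lfilter(lp$b, lp$a, v)
    }
  }
  if (is.matrix(x)) apply(x, 2, apply_filt) else apply_filt(as.numeric(x))
}

# causal IIR filter: vectorized FIR part + recursive part, zero initial state
lfilter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nf <- length(b)
  v <- stats::filter(c(rep(x[1], nf - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nf - 1 + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# zero-phase filtering with odd-reflection padding: a forward and a backward
# causal pass over the extended signal. The odd extension of a constant is
# the constant, and a high-pass numerator sums to zero, so DC is removed
# exactly; padding absorbs the start-up transients of both passes.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  k <- min(n - 1, max(12 * length(a), 100))
  left <- 2 * x[1] - x[(k + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - k)]
  xe <- c(left, x, right)
  y <- lfilter(b, a, xe)
  y <- rev(lfilter(b, a, rev(y)))
  y[k + seq_len(n)]
}

## ---- MBLL inversion --------------------------------------------------------

#' Convert optical densities to hemoglobin concentration changes
#'
#' Solves, per time point and channel, the 2x2 modified Beer-Lambert system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`.
#'
#' @param od Numeric array `[samples, channels, 2]` (third dimension ordered
#'   as the sorted wavelengths of `mbll`), or a `samples x 2` matrix for a
#'   single channel.
#' @param mbll [mbll_params()].
#' @return List with matrices `hbo` and `hbr` (`samples x channels`, molar).
#' @export
od_to_hemoglobin <- function(od, mbll = mbll_params()) {
  if (is.matrix(od)) od <- array(od, dim = c(nrow(od), 1, ncol(od)))
  stopifnot(length(dim(od)) == 3)
  if (dim(od)[3] != 2) stop("both wavelengths must be present (third dim = 2)")
  A <- extinction_matrix(mbll) * (mbll$distance * mbll$dpf) # row-scaled
  Ainv <- solve(A)
  n <- dim(od)[1]; n_ch <- dim(od)[2]
  hbo <- matrix(0, n, n_ch)
  hbr <- matrix(0, n, n_ch)
  for (ch in seq_len(n_ch)) {
    conc <- od[, ch, ] %*% t(Ainv) # n x 2
    hbo[, ch] <- conc[, 1]
    hbr[, ch] <- conc[, 2]
  }
  list(hbo = hbo, hbr = hbr)
}

## ---- Epoching --------------------------------------------------------------

#' Epoch onsets for one landing
#'
#' Epochs are `epoch_len` samples with successive onsets `step` samples apart
#' (the defaults 200 and 60 give 12 epochs in an 860-sample landing).
#'
#' @param n_samples Landing length in samples.
#' @param epoch_len Epoch length (default 200).
#' @param step Onset-to-onset step (default 60).
#' @param max_epochs Optional cap on the number of epochs.
#' @return Integer vector of 1-based onsets.
#' @export
epoch_onsets <- function(n_samples, epoch_len = 200, step = 60,
                         max_epochs = NULL) {
  if (n_samples < epoch_len) {
    stop("landing of ", n_samples, " samples is shorter than one epoch (",
         epoch_len, ")")
  }
  k <- (n_samples - epoch_len) %/% step + 1
  if (!is.null(max_epochs)) k <- min(k, max_epochs)
  as.integer(seq(1, by = step, length.out = k))
}

#' Central 80-sample window of a 200-sample epoch
#'
#' Returns samples 61..140 (1-based; the 80 centered samples), per channel.
#' Time-domain features are computed on this window; time-frequency
#' transforms use the full epoch and are cropped afterwards, so that
#' spectral leakage from the epoch edges never reaches the features.
#'
#' @param x Numeric vector or matrix with 200 rows.
#' @param epoch_len Expected epoch length (default 200).
#' @param keep Number of central samples kept (default 80).
#' @return The central slice (length/row count `keep`).
#' @export
central_window <- function(x, epoch_len = 200, keep = 80) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n != epoch_len) stop("expected an epoch of ", epoch_len, " samples, got ", n)
  start <- (epoch_len - keep) %/% 2 + 1
  idx <- start:(start + keep - 1)
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Preprocess a session into HbO/HbR epochs
#'
#' Runs the full per-epoch chain on every landing: segment into 200-sample
#' epochs (onsets 60 samples apart, count capped by the shortest landing and
#' by `max_epochs`), then per epoch: optical-density conversion referenced to
#' the epoch mean, wavelet artifact correction, Butterworth band-pass, and
#' Beer-Lambert inversion to HbO/HbR.
#'
#' @param session A `fnirs_session` (from [simulate_session()] or
#'   [read_snirf()]).
#' @param filter A [filter_spec()].
#' @param mbll [mbll_params()]; defaults to the session's forward-model
#'   parameters when present.
#' @param iqr_factor IQR factor for artifact correction; `NA` disables the
#'   correction step.
#' @param epoch_len,step Epoching geometry (defaults 200, 60).
#' @param max_epochs Cap on epochs per landing (default 12, giving 96 epochs
#'   for the default 8-landing session).
#' @return A list of class `fnirs_epochs`: `epochs` (list of lists with
#'   `hbo`, `hbr` matrices `epoch_len x channels`), `info` (tibble: `landing`,
#'   `condition`, `epoch`, `onset`), `montage`.
#' @export
preprocess_session <- function(session, filter = filter_spec(),
                               mbll = NULL, iqr_factor = 1.5,
                               epoch_len = 200, step = 60, max_epochs = 12) {
  montage <- session$montage
  fs <- montage_sfreq(montage)
  if (is.null(mbll)) {
    mbll <- session$mbll %||% mbll_params(
      wavelengths = montage_wavelengths(montage),
      distance = montage_distance(montage)
    )
  }
  n_per_landing <- vapply(session$landings,
                          function(l) dim(l$intensity)[1], integer(1))
  k_min <- min(vapply(n_per_landing, function(n) {
    length(epoch_onsets(n, epoch_len, step))
  }, integer(1)))
  if (!is.null(max_epochs)) k_min <- min(k_min, max_epochs)

  epochs <- list()
  info <- list()
  for (i in seq_along(session$landings)) {
    lnd <- session$landings[[i]]
    onsets <- epoch_onsets(dim(lnd$intensity)[1], epoch_len, step, k_min)
    for (e in seq_along(onsets)) {
      sl <- onsets[e]:(onsets[e] + epoch_len - 1)
      od <- array(0, dim = c(epoch_len, nrow(montage), 2))
      for (w in 1:2) {
        odw <- intensity_to_od(lnd$intensity[sl, , w])
        if (!is.na(iqr_factor)) odw <- wavelet_artifact_correct(odw, iqr_factor)
        odw <- bandpass(odw, fs, filter)
        od[, , w] <- odw
      }
      hemo <- od_to_hemoglobin(od, mbll)
      epochs[[length(epochs) + 1L]] <- list(hbo = hemo$hbo, hbr = hemo$hbr)
      info[[length(info) + 1L]] <- tibble::tibble(
        landing = i, condition = lnd$condition, epoch = e, onset = onsets[e]
      )
    }
  }
  structure(list(
    epochs = epochs,
    info = dplyr::bind_rows(info),
    montage = montage
  ), class = "fnirs_epochs")
}

#' @export
print.fnirs_epochs <- function(x, ...) {
  cat(sprintf("<fnirs_epochs> %d epochs x %d channels (%d landings)\n",
              length(x$epochs), nrow(x$montage), max(x$info$landing)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
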