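# Synthetic two-condition fNIRS session generator. Channels are noisy copies of
# a band-limited latent per ROI; inter-ROI coupling is imposed on the latents,
# so ground-truth connectivity is known and monotonically recoverable.

#' Uniform inter-ROI coupling matrix
#'
#' Convenience constructor for a symmetric 6x6 (or `n_roi` x `n_roi`) coupling
#' matrix with unit diagonal and a constant off-diagonal coupling.
#'
#' @param between Off-diagonal coupling in `[0, 1]`.
#' @param n_roi Number of ROIs (default 6).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
coupling_matrix <- function(between, n_roi = 6) {
  stopifnot(between >= 0, between <= 1)
  m <- matrix(between, n_roi, n_roi)
  diag(m) <- 1
  m
}

#' Generator configuration for synthetic fNIRS sessions
#'
#' Defines the statistical structure of one simulated subject: 8 landings
#' (4 "manual", 4 "auto") of two-wavelength intensities over a montage. The
#' condition contrast has two independent components: an inter-ROI coupling
#' contrast (drives connectivity features) and a mean HbO activation offset
#' (drives oxygenation features); either can be zeroed for null testing.
#'
#' Concentrations are in molar units (1e-6 = 1 micromolar); artifact
#' amplitudes are in optical-density units.
#'
#' @param landings_per_condition Landings per condition (default 4).
#' @param duration_mean,duration_sd,duration_floor Landing duration (s): drawn
#'   from a normal truncated below at `duration_floor` (defaults 152, 22, 120).
#' @param coupling Named list with matrices `manual` and `auto`: symmetric
#'   unit-diagonal inter-ROI coupling in `[0, 1]`.
#' @param hbo_offset Named numeric `c(manual = , auto = )`: mean HbO activation
#'   offset per condition (molar).
#' @param lfo_band Low-frequency-oscillation band (Hz), default 0.06-0.12.
#' @param lfo_amp Latent LFO amplitude (molar sd), default 1e-6.
#' @param pink_frac Fraction of latent variance from 1/f (pink) background.
#' @param cardiac_freq,cardiac_amp,resp_freq,resp_amp,mayer_freq,mayer_amp
#'   Global physiological nuisance sinusoids: cardiac ~1.1 Hz, respiration
#'   ~0.25 Hz, Mayer waves ~0.1 Hz; amplitudes in molar.
#' @param channel_noise_sd Per-channel HbO measurement noise sd (molar).
#' @param hbr_gain HbR anti-correlation gain applied to the deterministic HbO
#'   part (default -0.5).
#' @param hbr_noise_sd Independent HbR noise sd (molar).
#' @param artifact_rate Motion-artifact events per minute per session.
#' @param artifact_amp Length-2 range of artifact amplitudes (OD units).
#' @param baseline_intensity Baseline detector intensity (arbitrary units, > 0).
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(landings_per_condition = 4,
                       duration_mean = 152, duration_sd = 22,
                       duration_floor = 120,
                       coupling = list(manual = coupling_matrix(0.7),
                                       auto = coupling_matrix(0.2)),
                       hbo_offset = c(manual = 3e-7, auto = 0),
                       lfo_band = c(0.06, 0.12),
                       lfo_amp = 1e-6,
                       pink_frac = 0.2,
                       cardiac_freq = 1.1, cardiac_amp = 2e-7,
                       resp_freq = 0.25, resp_amp = 2e-7,
                       mayer_freq = 0.1, mayer_amp = 1e-7,
                       channel_noise_sd = 3e-7,
                       hbr_gain = -0.5,
                       hbr_noise_sd = 1.5e-7,
                       artifact_rate = 2,
                       artifact_amp = c(0.02, 0.2),
                       baseline_intensity = 1,
                       seed = 1L) {
  cfg <- list(
    landings_per_condition = as.integer(landings_per_condition),
    duration_mean = duration_mean, duration_sd = duration_sd,
    duration_floor = duration_floor,
    coupling = coupling, hbo_offset = hbo_offset,
    lfo_band = lfo_band, lfo_amp = lfo_amp, pink_frac = pink_frac,
    cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
    resp_freq = resp_freq, resp_amp = resp_amp,
    mayer_freq = mayer_freq, mayer_amp = mayer_amp,
    channel_noise_sd = channel_noise_sd,
    hbr_gain = hbr_gain, hbr_noise_sd = hbr_noise_sd,
    artifact_rate = artifact_rate, artifact_amp = artifact_amp,
    baseline_intensity = baseline_intensity,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$landings_per_condition >= 1)
  if (cfg$baseline_intensity <= 0) stop("baseline intensity must be positive")
  for (cond in c("manual", "auto")) {
    m <- cfg$coupling[[cond]]
    if (is.null(m)) stop("coupling must have components 'manual' and 'auto'")
    if (!isSymmetric(unname(m))) stop("coupling matrix for '", cond, "' is not symmetric")
    if (any(m < 0 | m > 1)) stop("coupling values must lie in [0, 1]")
    if (any(abs(diag(m) - 1) > 1e-12)) stop("coupling matrix must have unit diagonal")
  }
  amps <- c(cfg$lfo_amp, cfg$cardiac_amp, cfg$resp_amp, cfg$mayer_amp,
            cfg$channel_noise_sd, cfg$hbr_noise_sd, cfg$artifact_rate)
  if (any(amps < 0)) stop("rates and amplitudes must be non-negative")
  if (cfg$lfo_band[1] <= 0 || cfg$lfo_band[1] >= cfg$lfo_band[2]) {
    stop("lfo_band must satisfy 0 < low < high")
  }
  invisible(cfg)
}

# run expr with a private RNG stream; caller's RNG state is untouched
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# unit-variance band-limited noise via brick-wall FFT masking
band_limited_noise <- function(n, sfreq, band) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  freq <- seq(0, n - 1) * (sfreq / n)
  freq <- pmin(freq, sfreq - freq) # two-sided
  mask <- freq >= band[1] & freq <= band[2]
  mask[1] <- FALSE
  if (!any(mask)) stop("lfo_band contains no DFT bin at this length/sampling rate")
  y <- Re(stats::fft(xf * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited draw")
  y / s
}

# unit-variance 1/f amplitude-spectrum noise
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - k + 1)
  xf <- xf / sqrt(k)
  xf[1] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y / stats::sd(y)
}

# factor L with L %*% t(L) = C after clipping eigenvalues to keep C PSD
coupling_factor <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  L <- e$vectors %*% diag(sqrt(vals), length(vals))
  # rescale so the implied latent variances stay 1 after clipping
  d <- sqrt(rowSums(L^2))
  L / d
}

simulate_landing <- function(cfg, montage, condition, duration_s) {
  fs <- montage_sfreq(montage)
  n <- as.integer(round(duration_s * fs))
  rois <- intersect(roi_labels(), unique(montage$roi))
  n_roi <- length(rois)
  C <- cfg$coupling[[condition]][seq_len(n_roi), seq_len(n_roi), drop = FALSE]

  # independent unit-variance latents (band-limited LFO + pink background)
  raw <- vapply(seq_len(n_roi), function(i) {
    lfo <- band_limited_noise(n, fs, cfg$lfo_band)
    pk <- pink_noise(n)
    z <- sqrt(1 - cfg$pink_frac) * lfo + sqrt(cfg$pink_frac) * pk
    z / stats::sd(z)
  }, numeric(n))
  latents <- raw %*% t(coupling_factor(C)) # n x n_roi, cross-corr ~ C

  t_s <- (seq_len(n) - 1) / fs
  nuisance <- cfg$cardiac_amp * sin(2 * pi * cfg$cardiac_freq * t_s + stats::runif(1, 0, 2 * pi)) +
    cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t_s + stats::runif(1, 0, 2 * pi)) +
    cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * t_s + stats::runif(1, 0, 2 * pi))

  n_ch <- nrow(montage)
  roi_idx <- match(montage$roi, rois)
  det_part <- cfg$lfo_amp * latents[, roi_idx, drop = FALSE] +
    cfg$hbo_offset[[condition]] + nuisance
  hbo <- det_part + matrix(stats::rnorm(n * n_ch, sd = cfg$channel_noise_sd), n, n_ch)
  hbr <- cfg$hbr_gain * det_part +
    matrix(stats::rnorm(n * n_ch, sd = cfg$hbr_noise_sd), n, n_ch)

  list(n = n, hbo = hbo, hbr = hbr, duration_s = duration_s)
}

# transient spikes (exponential decay ~0.5 s) and step baseline shifts, in OD
inject_artifacts <- function(od, cfg, fs, landing_id) {
  n <- dim(od)[1]; n_ch <- dim(od)[2]
  minutes <- n / fs / 60
  n_events <- stats::rpois(1, cfg$artifact_rate * minutes)
  events <- tibble::tibble(
    landing = integer(0), time_s = numeric(0), channel = integer(0),
    amplitude = numeric(0), kind = character(0)
  )
  if (n_events == 0) return(list(od = od, events = events))
  tau <- 0.5 * fs # decay constant in samples
  for (i in seq_len(n_events)) {
    ch <- sample.int(n_ch, 1)
    t0 <- sample.int(n, 1)
    amp <- stats::runif(1, cfg$artifact_amp[1], cfg$artifact_amp[2]) *
      sample(c(-1, 1), 1)
    kind <- if (stats::runif(1) < 0.8) "spike" else "shift"
    idx <- t0:n
    shape <- if (kind == "spike") exp(-(idx - t0) / tau) else rep(1, length(idx))
    od[idx, ch, ] <- od[idx, ch, , drop = FALSE] + amp * shape
    events <- dplyr::bind_rows(events, tibble::tibble(
      landing = landing_id, time_s = (t0 - 1) / fs, channel = ch,
      amplitude = amp, kind = kind
    ))
  }
  list(od = od, events = events)
}

#' Simulate one synthetic fNIRS session
#'
#' Generates `2 * landings_per_condition` landings in pseudo-random order.
#' Per landing, HbO is built as a ROI-latent mixture (band-limited low-frequency
#' oscillations plus pink background) whose latent cross-correlation equals the
#' condition's coupling matrix, plus an activation offset, global physiological
#' nuisance and channel noise; HbR is the anti-correlated copy plus independent
#' noise. Both chromophores are pushed through the forward modified
#' Beer-Lambert model into two-wavelength intensities; motion artifacts are
#' injected in optical-density space before exponentiation.
#'
#' @param config A [sim_config()].
#' @param montage A [default_montage()] (possibly reduced).
#' @param mbll [mbll_params()] used for the forward model; the same constants
#'   are used by the preprocessing inverse so the round trip is exact up to
#'   filtering.
#' @return A list of class `fnirs_session`: `montage`, `landings` (each with
#'   `condition`, `duration_s`, `intensity` array `[n, channel, wavelength]`),
#'   and `ground_truth` (labels, coupling, artifact events, true hemoglobin and
#'   optical-density traces, seed).
#' @examples
#' sess <- simulate_session(sim_config(seed = 7), default_montage(channels_per_roi = 1))
#' length(sess$landings) # 8
#' @export
simulate_session <- function(config, montage = default_montage(),
                             mbll = mbll_params(
                               wavelengths = montage_wavelengths(montage),
                               distance = montage_distance(montage)
                             )) {
  validate_sim_config(config)
  validate_montage(montage)
  fs <- montage_sfreq(montage)

  with_sim_seed(config$seed, {
    k <- config$landings_per_condition
    conditions <- sample(rep(c("manual", "auto"), each = k))
    durations <- vapply(seq_along(conditions), function(i) {
      d <- stats::rnorm(1, config$duration_mean, config$duration_sd)
      while (d < config$duration_floor) {
        d <- stats::rnorm(1, config$duration_mean, config$duration_sd)
      }
      d
    }, numeric(1))

    E <- extinction_matrix(mbll) # 2x2: rows wavelengths, cols HbO/HbR
    path <- montage_distance(montage) * mbll$dpf # per wavelength

    landings <- list()
    truth_hemo <- list()
    truth_od <- list()
    all_events <- tibble::tibble()
    for (i in seq_along(conditions)) {
      lnd <- simulate_landing(config, montage, conditions[i], durations[i])
      n <- lnd$n; n_ch <- nrow(montage)
      od <- array(0, dim = c(n, n_ch, 2))
      for (w in 1:2) {
        od[, , w] <- (E[w, 1] * lnd$hbo + E[w, 2] * lnd$hbr) * path[w]
      }
      art <- inject_artifacts(od, config, fs, i)
      intensity <- config$baseline_intensity * 10^(-art$od)
      landings[[i]] <- list(
        condition = conditions[i], duration_s = durations[i],
        intensity = intensity
      )
      truth_hemo[[i]] <- list(hbo = lnd$hbo, hbr = lnd$hbr)
      truth_od[[i]] <- art$od
      all_events <- dplyr::bind_rows(all_events, art$events)
    }

    structure(list(
      montage = montage,
      landings = landings,
      ground_truth = list(
        condition = conditions,
        coupling = config$coupling,
        artifact_events = all_events,
        hemoglobin = truth_hemo,
        od = truth_od,
        seed = config$seed
      ),
      mbll = mbll,
      config = config
    ), class = "fnirs_session")
  })
}

#' @export
print.fnirs_session <- function(x, ...) {
  cat(sprintf(
    "<fnirs_session> %d landings (%s), %d channels @ %.4f Hz\n",
    length(x$landings),
    paste(sprintf("%s=%d", names(table(x$ground_truth$condition)),
                  table(x$ground_truth$condition)), collapse = ", "),
    nrow(x$montage), montage_sfreq(x$montage)
  ))
  invisible(x)
}

#' Tidy view of a session's intensities
#'
#' @param x A `fnirs_session`.
#' @param ... Unused.
#' @return Long tibble: `landing`, `condition`, `time_s`, `channel`,
#'   `wavelength`, `intensity`.
#' @method tidy fnirs_session
#' @export
tidy.fnirs_session <- function(x, ...) {
  fs <- montage_sfreq(x$montage)
  wl <- montage_wavelengths(x$montage)
  purrr::imap_dfr(x$landings, function(lnd, i) {
    n <- dim(lnd$intensity)[1]
    tidyr::expand_grid(
      channel = x$montage$channel, wavelength = wl
    ) |>
      dplyr::mutate(landing = i, condition = lnd$condition) |>
      dplyr::rowwise() |>
      dplyr::mutate(series = list(lnd$intensity[, match(.data$channel, x$montage$channel),
                                                match(.data$wavelength, wl)])) |>
      dplyr::ungroup() |>
      dplyr::mutate(time_s = list((seq_len(n) - 1) / fs)) |>
      tidyr::unnest(c("series", "time_s")) |>
      dplyr::rename(intensity = "series") |>
      dplyr::select("landing", "condition", "time_s", "channel", "wavelength", "intensity")
  })
}
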