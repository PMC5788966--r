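# Shared fixtures: small montages and sessions so each test file stays fast.
# Everything is generated in code; fixed seeds make the suite deterministic.

FS <- 7.8125

tiny_montage <- function(channels_per_roi = 1) {
  default_montage(channels_per_roi = channels_per_roi)
}

# short-landing config: quick to simulate but still fits 12 epochs
quick_sim_config <- function(seed = 1, ...) {
  sim_config(duration_mean = 125, duration_sd = 5, duration_floor = 120,
             seed = seed, ...)
}

quick_session <- function(seed = 1, channels_per_roi = 1, ...) {
  simulate_session(quick_sim_config(seed = seed, ...),
                   default_montage(channels_per_roi = channels_per_roi))
}

# session with no artifacts/nuisance, for clean round-trip checks
clean_session <- function(seed = 1, channels_per_roi = 1, ...) {
  simulate_session(
    quick_sim_config(seed = seed, artifact_rate = 0, cardiac_amp = 0,
                     resp_amp = 0, mayer_amp = 0, ...),
    default_montage(channels_per_roi = channels_per_roi)
  )
}
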