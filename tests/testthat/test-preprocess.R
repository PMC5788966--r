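test_that("optical density conversion follows the -log10 definition", {
  x <- rep(2, 10)
  expect_equal(intensity_to_od(x, reference = 2), rep(0, 10))
  expect_equal(intensity_to_od(rep(0.2, 5), reference = 2), rep(1, 5))
  expect_error(intensity_to_od(c(1, -1, 2)), "channel 1, sample 2")
  expect_error(intensity_to_od(c(1, 1), reference = 0), "positive")
})

test_that("optical density round-trips the generator's internal OD trace", {
  sess <- clean_session(seed = 4)
  i1 <- sess$landings[[1]]$intensity[, 1, 1]
  od_true <- sess$ground_truth$od[[1]][, 1, 1]
  od_rec <- intensity_to_od(i1, reference = sess$config$baseline_intensity)
  expect_lt(max(abs(od_rec - od_true)), 1e-10)
})

test_that("wavelet artifact correction barely touches a clean oscillation", {
  t <- seq_len(200) / FS
  x <- sin(2 * pi * 0.1 * t)
  y <- wavelet_artifact_correct(x)
  expect_length(y, 200)
  expect_lt(max(abs(y - x)), 0.05 * stats::sd(x))
})

test_that("wavelet artifact correction suppresses an injected spike", {
  withr::with_seed(10, {
    t <- seq_len(200) / FS
    base <- sin(2 * pi * 0.1 * t) + rnorm(200, sd = 0.05)
    spike <- numeric(200)
    spike[100:103] <- 10 * stats::sd(base) * exp(-(0:3) / 2)
    y <- wavelet_artifact_correct(base + spike)
    resid_peak <- max(abs((y - base)[95:110]))
    expect_lt(resid_peak, 0.2 * max(spike))
  })
})

test_that("artifact correction preserves length for non-dyadic epochs", {
  for (n in c(128, 200, 256)) {
    x <- rnorm(n)
    expect_length(wavelet_artifact_correct(x), n)
  }
  expect_error(wavelet_artifact_correct(rnorm(4)), "too short")
})

test_that("wavelet decomposition is perfectly invertible", {
  withr::with_seed(1, {
    x <- rnorm(200)
    dec <- fnirsbci:::modwt(x, 7)
    expect_lt(max(abs(fnirsbci:::imodwt(dec) - x)), 1e-10)
  })
})

test_that("band-pass kills DC, passes 0.1 Hz, rejects 1.5 Hz", {
  n <- 2000 # long enough that the slow high-pass transient has died out
  t <- seq_len(n) / FS
  dc <- rep(3, n)
  expect_lt(max(abs(bandpass(dc, FS))), 1e-6 * 3)
  mid <- 700:1300
  pass <- bandpass(sin(2 * pi * 0.1 * t), FS)
  amp_pass <- (max(pass[mid]) - min(pass[mid])) / 2
  expect_gte(amp_pass, 0.9)
  expect_lte(amp_pass, 1.1)
  stopb <- bandpass(sin(2 * pi * 1.5 * t), FS)
  expect_lt(max(abs(stopb[mid])), 0.05)
  expect_error(bandpass(dc, FS, filter_spec(low_cut = 5)), "Nyquist")
  expect_error(filter_spec(high_cut = 0.6, low_cut = 0.5), "cutoff")
})

test_that("Beer-Lambert inversion is exact, linear, and wavelength-order invariant", {
  mbll <- mbll_params()
  od0 <- array(0, dim = c(10, 3, 2))
  h0 <- od_to_hemoglobin(od0, mbll)
  expect_equal(h0$hbo, matrix(0, 10, 3))
  expect_equal(h0$hbr, matrix(0, 10, 3))

  withr::with_seed(2, {
    hbo <- matrix(rnorm(50, sd = 1e-6), 50, 1)
    hbr <- matrix(rnorm(50, sd = 1e-6), 50, 1)
    E <- mbll$eps
    path <- mbll$distance * mbll$dpf
    od <- array(0, dim = c(50, 1, 2))
    for (w in 1:2) od[, , w] <- (E[w, 1] * hbo + E[w, 2] * hbr) * path[w]
    rec <- od_to_hemoglobin(od, mbll)
    expect_lt(max(abs(rec$hbo - hbo)) / max(abs(hbo)), 1e-8)
    expect_lt(max(abs(rec$hbr - hbr)) / max(abs(hbr)), 1e-8)

    # linearity to 1e-10
    od2 <- od * 0.3
    mix <- od * 2 + od2 * 5
    rmix <- od_to_hemoglobin(mix, mbll)
    r1 <- od_to_hemoglobin(od, mbll)
    r2 <- od_to_hemoglobin(od2, mbll)
    expect_lt(max(abs(rmix$hbo - (2 * r1$hbo + 5 * r2$hbo))), 1e-10)

    # swapping the wavelength rows (and the matching constants) changes nothing
    mbll_sw <- mbll
    mbll_sw$eps <- mbll$eps[2:1, ]
    mbll_sw$dpf <- mbll$dpf[2:1]
    od_sw <- od[, , 2:1, drop = FALSE]
    expect_equal(od_to_hemoglobin(od, mbll)$hbo,
                 od_to_hemoglobin(od_sw, mbll_sw)$hbo)
  })
  expect_error(mbll_params(extinction = matrix(c(1, 1, 2, 2), 2)), "singular")
})

test_that("epoching yields 12 epochs from 860 samples and errors below 200", {
  expect_length(epoch_onsets(860), 12)
  expect_length(epoch_onsets(200), 1)
  expect_error(epoch_onsets(199), "shorter than one epoch")
  expect_equal(epoch_onsets(860)[1:3], c(1L, 61L, 121L))
  expect_length(epoch_onsets(2000, max_epochs = 12), 12)
})

test_that("central window selects samples 61..140 of a 200-sample epoch", {
  ramp <- 0:199
  w <- central_window(ramp)
  expect_length(w, 80)
  expect_equal(w[1], 60)
  expect_equal(w[80], 139)
  sym <- c(1:100, 100:1)
  expect_equal(central_window(sym), rev(central_window(sym)))
  expect_error(central_window(1:100), "expected an epoch of 200")
})

test_that("a preprocessed default session yields 96 epochs of both chromophores", {
  sess <- quick_session(seed = 6)
  ep <- preprocess_session(sess)
  expect_length(ep$epochs, 96)
  expect_equal(nrow(ep$info), 96)
  expect_true(all(table(ep$info$landing) == 12))
  e1 <- ep$epochs[[1]]
  expect_equal(dim(e1$hbo), c(200, 6))
  expect_equal(dim(e1$hbr), c(200, 6))
})

test_that("epochs are processed independently of their landing context", {
  sess <- quick_session(seed = 12)
  ep_full <- preprocess_session(sess)
  # rebuild a session holding only landing 3 and compare its epochs
  sub <- sess
  sub$landings <- sess$landings[3]
  ep_sub <- preprocess_session(sub)
  idx_full <- which(ep_full$info$landing == 3)
  for (k in seq_along(ep_sub$epochs)) {
    expect_equal(ep_sub$epochs[[k]]$hbo, ep_full$epochs[[idx_full[k]]]$hbo)
  }
})

test_that("recovered HbO tracks generated HbO on artifact-free data", {
  sess <- clean_session(seed = 9)
  ep <- preprocess_session(sess, iqr_factor = NA)
  fspec <- filter_spec()
  r <- c()
  for (i in which(ep$info$landing == 1)[1:4]) {
    onset <- ep$info$onset[i]
    truth <- sess$ground_truth$hemoglobin[[1]]$hbo[onset:(onset + 199), 1]
    truth_f <- bandpass(truth - mean(truth), FS, fspec)
    r <- c(r, stats::cor(ep$epochs[[i]]$hbo[, 1], truth_f))
  }
  expect_true(all(r > 0.95))
})
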