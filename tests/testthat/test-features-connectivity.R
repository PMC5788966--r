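test_that("covariance matches its defining sum and bilinearity", {
  withr::with_seed(21, {
    x <- rnorm(50)
    expect_equal(covariance_pair(x, x), stats::var(x))
    expect_equal(covariance_pair(x, -x), -stats::var(x))
  })
  expect_equal(covariance_pair(c(1, 2, 3), c(2, 4, 6)), 2.0)
  expect_error(covariance_pair(1:3, 1:4), "equal length")
})

test_that("Pearson correlation handles affine and independent signals", {
  withr::with_seed(22, {
    x <- rnorm(100)
    expect_equal(pearson_pair(x, 2 * x + 1), 1.0)
    expect_equal(pearson_pair(x, -x), -1.0)
    a <- rnorm(1e4); b <- rnorm(1e4)
    expect_lt(abs(pearson_pair(a, b)), 0.05)
    expect_warning(r <- pearson_pair(rep(1, 10), rnorm(10)), "zero-variance")
    expect_true(is.na(r))
  })
})

test_that("Spearman equals rank-then-correlate and is monotone invariant", {
  withr::with_seed(23, {
    x <- rnorm(60)
    expect_equal(spearman_pair(x, exp(x)), 1.0)
    xd <- sample(seq(-3, 3, length.out = 60)) # distinct values
    expect_equal(spearman_pair(xd, -xd^3), -1.0)
    # tied data against the brute-force average-rank oracle
    xt <- c(1, 2, 2, 3); yt <- c(1, 2, 3, 4)
    expect_equal(spearman_pair(xt, yt), stats::cor(rank(xt), rank(yt)))
    # invariance under any strictly increasing transform
    y <- rnorm(60)
    r0 <- spearman_pair(x, y)
    expect_equal(spearman_pair(atan(x), y), r0)
    expect_equal(spearman_pair(x, exp(y / 2)), r0)
  })
})

test_that("Welch coherence is 1 for proportional signals and rejects K = 1", {
  withr::with_seed(24, {
    x <- rnorm(200)
    cs <- spectral_coherence(x, 3 * x, FS)
    expect_true(all(abs(cs$coherence - 1) < 1e-9))
    expect_equal(attr(cs, "n_segments"), 3)
    expect_error(spectral_coherence(x, 3 * x, FS, seg_len = 200),
                 "identically 1")
  })
})

test_that("Welch coherence matches the loop-DFT oracle on 64-sample signals", {
  withr::with_seed(25, {
    for (rep in 1:5) {
      x <- rnorm(64); y <- rnorm(64)
      got <- spectral_coherence(x, y, FS, seg_len = 32, overlap = 0.5,
                                window = "hamming")
      taper <- 0.54 - 0.46 * cos(2 * pi * (0:31) / 31)
      want <- oracle_welch(x, y, 32, 16, taper)
      expect_equal(got$coherence, want, tolerance = 1e-9)
    }
  })
})

test_that("independence bias of Welch coherence is about 1/K", {
  withr::with_seed(26, {
    K <- 3
    acc <- 0
    reps <- 200
    for (r in seq_len(reps)) {
      x <- rnorm(300); y <- rnorm(300)
      cs <- spectral_coherence(x, y, FS, seg_len = 100, overlap = 0,
                               window = "rectangular")
      acc <- acc + mean(cs$coherence)
    }
    expect_lt(abs(acc / reps - 1 / K), 0.03)
  })
})

test_that("wavelet coherence is 1 for proportional signals", {
  withr::with_seed(27, {
    x <- rnorm(200)
    m1 <- wavelet_coherence(x, x, FS)
    expect_true(all(abs(m1$rsq - 1) < 1e-6))
    m2 <- wavelet_coherence(x, -4 * x, FS)
    expect_true(all(abs(m2$rsq - 1) < 1e-6))
  })
})

test_that("without smoothing wavelet coherence is identically 1 for any pair", {
  withr::with_seed(28, {
    x <- rnorm(200); y <- rnorm(200)
    m <- wavelet_coherence(x, y, FS, smooth = FALSE)
    expect_true(all(abs(m$rsq - 1) < 1e-9))
    ms <- wavelet_coherence(x, y, FS)
    expect_lt(mean(ms$rsq), 0.9) # smoothing restores discrimination
  })
})

test_that("wavelet scale grid and band selection follow the Morlet Fourier factor", {
  m <- wavelet_coherence(rnorm(200), rnorm(200), FS)
  ff <- 4 * pi / (6 + sqrt(2 + 36))
  expect_equal(m$period, ff * m$scale, tolerance = 1e-12)
  expect_true(all(diff(m$period) > 0))
  expect_lte(max(m$period), 12.8)
  # closed-form enumeration of scales with period inside [3.2, 12.8] s
  dt <- 1 / FS
  s0 <- 2 * dt
  j <- 0:floor(log2((12.8 / ff) / s0) * 12)
  periods <- ff * s0 * 2^(j / 12)
  want_n <- sum(periods >= 3.2 & periods <= 12.8)
  got_n <- sum(m$freq >= 1 / 12.8 & m$freq <= 1 / 3.2)
  expect_equal(got_n, want_n)
  expect_error(band_average(m, band_spec(low = 5, high = 6)), "no wavelet scale")
})

test_that("band averaging a constant map returns the constant", {
  m <- wavelet_coherence(rnorm(200), rnorm(200), FS)
  m$rsq[] <- 1
  expect_equal(band_average(m), 1.0)
  expect_equal(band_average(crop_map(m, 80)), 1.0)
  expect_equal(ncol(crop_map(m, 80)$rsq), 80)
})

test_that("all measures are symmetric, bounded and affine invariant", {
  withr::with_seed(29, {
    x <- rnorm(200); y <- as.numeric(stats::filter(rnorm(200), 0.6,
                                                   method = "recursive"))
    xw <- x[61:140]; yw <- y[61:140]
    # symmetry
    expect_equal(covariance_pair(xw, yw), covariance_pair(yw, xw))
    expect_equal(pearson_pair(xw, yw), pearson_pair(yw, xw))
    expect_equal(spearman_pair(xw, yw), spearman_pair(yw, xw))
    expect_equal(spectral_coherence(x, y, FS)$coherence,
                 spectral_coherence(y, x, FS)$coherence)
    expect_equal(wavelet_coherence(x, y, FS)$rsq,
                 wavelet_coherence(y, x, FS)$rsq)
    # ranges
    expect_true(abs(pearson_pair(xw, yw)) <= 1 + 1e-9)
    expect_true(abs(spearman_pair(xw, yw)) <= 1 + 1e-9)
    cs <- spectral_coherence(x, y, FS)$coherence
    expect_true(all(cs >= -1e-9 & cs <= 1 + 1e-9))
    wc <- wavelet_coherence(x, y, FS)$rsq
    expect_true(all(wc >= -1e-9 & wc <= 1 + 1e-9))
    # affine invariance x -> a x + b
    a <- 2.7; b <- -3
    expect_equal(pearson_pair(a * xw + b, yw), pearson_pair(xw, yw),
                 tolerance = 1e-9)
    expect_equal(spearman_pair(a * xw + b, yw), spearman_pair(xw, yw),
                 tolerance = 1e-9)
    expect_equal(spectral_coherence(a * x + b, y, FS)$coherence,
                 spectral_coherence(x, y, FS)$coherence, tolerance = 1e-9)
    expect_equal(wavelet_coherence(a * x + b, y, FS)$rsq,
                 wavelet_coherence(x, y, FS)$rsq, tolerance = 1e-9)
    expect_equal(covariance_pair(a * xw + b, yw), a * covariance_pair(xw, yw))
  })
})

test_that("wavelet null distribution is stable across independent batches", {
  # AR(1) pairs, phi = 0.7: two batches of the same Monte-Carlo estimator
  ar1_pair_value <- function() {
    x <- as.numeric(stats::filter(rnorm(200), 0.7, method = "recursive"))
    y <- as.numeric(stats::filter(rnorm(200), 0.7, method = "recursive"))
    band_average(crop_map(wavelet_coherence(x, y, FS), 80))
  }
  withr::with_seed(30, b1 <- mean(replicate(100, ar1_pair_value())))
  withr::with_seed(31, b2 <- mean(replicate(100, ar1_pair_value())))
  expect_lt(abs(b1 - b2), 0.05)
})

test_that("batch extraction agrees with the single-pair estimators", {
  sess <- quick_session(seed = 33, channels_per_roi = 1)
  ep <- preprocess_session(sess)
  ep$epochs <- ep$epochs[1]
  ep$info <- ep$info[1, ]
  tbl <- extract_connectivity(ep)
  expect_equal(nrow(tbl), 15 * 5 * 2) # 15 pairs x 5 measures x 2 chromophores
  mat <- ep$epochs[[1]]$hbo
  win <- central_window(mat)
  pick <- function(meas, a, b) {
    tbl$value[tbl$measure == meas & tbl$ch_a == a & tbl$ch_b == b &
                tbl$chromophore == "HbO"]
  }
  for (pr in list(c(1, 2), c(3, 6))) {
    a <- pr[1]; b <- pr[2]
    expect_equal(pick("covariance", a, b), covariance_pair(win[, a], win[, b]))
    expect_equal(pick("pearson", a, b), pearson_pair(win[, a], win[, b]))
    expect_equal(pick("spearman", a, b), spearman_pair(win[, a], win[, b]))
    expect_equal(pick("coherence", a, b),
                 band_average(spectral_coherence(mat[, a], mat[, b], FS)))
    expect_equal(pick("wavelet_coherence", a, b),
                 band_average(crop_map(wavelet_coherence(mat[, a], mat[, b], FS), 80)),
                 tolerance = 1e-10)
  }
})

test_that("band-averaged wavelet coherence recovers the coupling ordering", {
  # Monte-Carlo, >= 20 landings per level, 3-point grid, strictly increasing
  level_mean <- function(between, seeds) {
    vals <- c()
    for (sd_ in seeds) {
      sess <- simulate_session(
        sim_config(seed = sd_, duration_mean = 125, duration_sd = 2,
                   duration_floor = 120,
                   coupling = list(manual = coupling_matrix(between),
                                   auto = coupling_matrix(between)),
                   artifact_rate = 0),
        default_montage(channels_per_roi = 1)
      )
      ep <- preprocess_session(sess)
      first <- ep$info$epoch == 1
      for (i in which(first)) {
        mat <- ep$epochs[[i]]$hbo
        vals <- c(vals, band_average(crop_map(
          wavelet_coherence(mat[, 1], mat[, 4], FS), 80
        )))
      }
    }
    mean(vals)
  }
  m_lo <- level_mean(0.1, 34:36) # 24 landings per level
  m_mid <- level_mean(0.5, 34:36)
  m_hi <- level_mean(0.9, 34:36)
  expect_lt(m_lo, m_mid)
  expect_lt(m_mid, m_hi)
})
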