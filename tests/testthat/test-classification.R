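fake_features <- function(seed = 1, n_landings_per_class = 4, epochs = 12,
                          n_feats = 12, dims = 3, signal = 0) {
  withr::with_seed(seed, {
    landings <- rep(seq_len(2 * n_landings_per_class), each = epochs)
    cond <- rep(rep(c("manual", "auto"), each = n_landings_per_class),
                each = epochs)
    info <- tibble::tibble(landing = landings, condition = cond,
                           epoch = rep(seq_len(epochs), 2 * n_landings_per_class))
    mats <- list()
    for (chrom in c("HbO", "HbR")) {
      mats[[chrom]] <- list()
      for (f in seq_len(n_feats)) {
        m <- matrix(rnorm(nrow(info) * dims), nrow(info), dims)
        m[cond == "manual", 1] <- m[cond == "manual", 1] + signal
        colnames(m) <- paste0("d", seq_len(dims))
        mats[[chrom]][[paste0("feat", f)]] <- m
      }
    }
    structure(list(info = info, matrices = mats), class = "fnirs_features")
  })
}

test_that("z-score normalizer standardizes its own training set and transfers", {
  withr::with_seed(51, {
    x <- matrix(rnorm(60, mean = 3, sd = 2), 20, 3)
    nz <- fit_normalizer(x)
    z <- apply_normalizer(nz, x)
    expect_true(all(abs(colMeans(z)) < 1e-9))
    expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
    # test rows use the training parameters, not their own
    xt <- matrix(rnorm(15, mean = 10), 5, 3)
    zt <- apply_normalizer(nz, xt)
    want <- sweep(sweep(xt, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
    expect_equal(zt, want)
  })
})

test_that("constant dimensions are dropped with a warning", {
  x <- cbind(rnorm(10), rep(5, 10))
  expect_warning(nz <- fit_normalizer(x), "constant dimension")
  expect_equal(ncol(apply_normalizer(nz, x)), 1)
})

test_that("leave-two-landings-out folds enumerate all 16 class-paired combinations", {
  landing <- rep(1:8, each = 12)
  label <- rep(rep(c("manual", "auto"), 4), each = 12)
  folds <- make_folds(landing, label)
  expect_length(folds, 16)
  for (f in folds) {
    expect_length(f$train, 72)
    expect_length(f$test, 24)
    expect_length(intersect(f$train, f$test), 0)
    # test set is class-balanced: 12 + 12
    expect_equal(as.integer(table(label[f$test])), c(12L, 12L))
  }
  # exhaustiveness: each landing is left out once per opposite-class landing
  test_landings <- unlist(lapply(folds, function(f) f$test_landings))
  expect_true(all(table(test_landings) == 4))
  # the union of test epochs covers every epoch
  expect_equal(sort(unique(unlist(lapply(folds, function(f) f$test)))),
               seq_along(landing))

  small <- make_folds(rep(1:4, each = 3), rep(c("a", "b", "a", "b"), each = 3))
  expect_length(small, 4)
  expect_error(make_folds(rep(1:2, each = 3), rep(c("a", "b"), each = 3)),
               "at least 2 landings")
  expect_error(make_folds(rep(1:7, each = 2),
                          rep(c("a", "b", "a", "b", "a", "b", "a"), each = 2)),
               "unbalanced")
})

test_that("shrinkage LDA separates well-separated Gaussian clouds", {
  withr::with_seed(52, {
    n <- 200
    x <- rbind(matrix(rnorm(n, mean = 0), n / 2, 2),
               matrix(rnorm(n, mean = 6), n / 2, 2))
    y <- rep(c("a", "b"), each = n / 2)
    test_x <- rbind(matrix(rnorm(n, mean = 0), n / 2, 2),
                    matrix(rnorm(n, mean = 6), n / 2, 2))
    model <- fit_shrinkage_lda(x, y)
    expect_gte(mean(predict(model, test_x) == y), 0.99)
  })
})

test_that("shrinkage LDA is at chance under label permutation", {
  withr::with_seed(53, {
    acc <- replicate(200, {
      x <- matrix(rnorm(40 * 3), 40, 3)
      y <- sample(rep(c("a", "b"), 20))
      xt <- matrix(rnorm(20 * 3), 20, 3)
      yt <- sample(rep(c("a", "b"), 10))
      mean(predict(fit_shrinkage_lda(x, y), xt) == yt)
    })
    expect_gt(mean(acc), 0.45)
    expect_lt(mean(acc), 0.55)
  })
})

test_that("shrinkage makes p > n fits well-posed", {
  withr::with_seed(54, {
    x <- matrix(rnorm(20 * 50), 20, 50)
    y <- rep(c("a", "b"), each = 10)
    model <- fit_shrinkage_lda(x, y)
    expect_gt(model$shrinkage, 0)
    pred <- predict(model, matrix(rnorm(5 * 50), 5, 50))
    expect_true(all(pred %in% c("a", "b")))
    expect_true(all(is.finite(model$weights)))
    # fixed-intensity override is respected
    m2 <- fit_shrinkage_lda(x, y, shrinkage = 0.42)
    expect_equal(m2$shrinkage, 0.42)
  })
})

test_that("tidy and glance expose the discriminant and its metadata", {
  withr::with_seed(55, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- rep(c("a", "b"), each = 10)
    model <- fit_shrinkage_lda(x, y)
    td <- tidy(model)
    expect_equal(td$term, c("f1", "f2"))
    gl <- glance(model)
    expect_equal(gl$n, 20)
    expect_equal(gl$class_1, "a")
  })
})

test_that("normalizer and model parameters never depend on test rows", {
  withr::with_seed(56, {
    info_landing <- rep(1:4, each = 6)
    info_label <- rep(c("manual", "auto", "manual", "auto"), each = 6)
    x <- matrix(rnorm(24 * 3), 24, 3)
    folds <- make_folds(info_landing, info_label)
    f <- folds[[1]]
    fit_on <- function(mat) {
      nz <- fit_normalizer(mat[f$train, ])
      fit_shrinkage_lda(apply_normalizer(nz, mat[f$train, ]),
                        info_label[f$train])
    }
    x_corrupt <- x
    x_corrupt[f$test, ] <- 1e6
    expect_identical(fit_on(x)$weights, fit_on(x_corrupt)$weights)
  })
})

test_that("binomial chance threshold reproduces the exact tail", {
  expect_equal(chance_threshold(96, 2, 0.05), 100 * 56 / 96)
  expect_equal(round(chance_threshold(96, 2, 0.05), 1), 58.3)
  expect_lt(chance_threshold(1e6, 2, 0.05), 50.2)
  # brute-force pmf-summation oracle at n = 24
  n <- 24; p <- 0.5
  pmf <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
                numeric(1))
  cdf <- cumsum(pmf)
  k_star <- min(which(cdf >= 0.95)) - 1
  expect_equal(chance_threshold(24, 2, 0.05), 100 * k_star / 24)
  expect_gt(chance_threshold(24, 2, 0.05), 50)
  expect_error(chance_threshold(96, 2, 1.5), "alpha")
})

test_that("evaluation enumerates 12 singles plus 66 pairs per chromophore", {
  feats <- fake_features(seed = 57)
  cv <- evaluate_features(feats)
  smry <- glance(cv)
  expect_equal(nrow(smry), 2 * (12 + 66))
  expect_equal(length(unique(smry$feature_set)), 78)
  expect_equal(attr(cv, "chance_threshold"), chance_threshold(96))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  per_set <- dplyr::count(tibble::as_tibble(cv), feature_set, chromophore)
  expect_true(all(per_set$n == 16))
})

test_that("evaluation separates informative features and is deterministic", {
  feats <- fake_features(seed = 58, signal = 4)
  cv1 <- evaluate_features(feats, sets = list("feat1", c("feat1", "feat2")))
  cv2 <- evaluate_features(feats, sets = list("feat1", c("feat1", "feat2")))
  expect_identical(tibble::as_tibble(cv1), tibble::as_tibble(cv2))
  smry <- glance(cv1)
  expect_true(all(smry$mean_accuracy > 0.9))
  expect_equal(sort(unique(smry$feature_set)), c("feat1", "feat1+feat2"))
})

test_that("undefined dimensions are excluded, never whole epochs", {
  feats <- fake_features(seed = 59, n_feats = 2, signal = 2)
  feats$matrices$HbO$feat1[, 2] <- NA
  expect_warning(cv <- evaluate_features(feats, sets = list("feat1")),
                 "undefined")
  smry <- glance(cv)
  expect_equal(nrow(smry), 2)
  expect_true(all(is.finite(smry$mean_accuracy)))
})
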