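# Shrinkage-LDA classification of engagement condition under a
# landing-stratified leave-two-landings-out cross-validation, with an exact
# binomial chance-level threshold. z-scoring is fit on training folds only
# by default (a global option reproduces whole-set scaling at the cost of
# train/test leakage).

## ---- Normalization ---------------------------------------------------------

#' Fit a z-score normalizer on training rows
#'
#' @param x Numeric matrix (rows = epochs, columns = feature dimensions).
#' @return List of class `normalizer`: `mean`, `sd`, `keep` (logical mask of
#'   retained dimensions; zero-sd dimensions are dropped with a warning).
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training rows")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant dimension(s) dropped: ",
            paste(which(!keep), collapse = ", "))
  }
  structure(list(mean = mu, sd = sds, keep = keep), class = "normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer A [fit_normalizer()] result.
#' @param x Matrix with the same columns as the training data.
#' @return `(x - train mean) / train sd`, restricted to retained dimensions.
#' @export
apply_normalizer <- function(normalizer, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer$mean)) stop("dimension mismatch")
  z <- sweep(x, 2, normalizer$mean)
  z <- sweep(z, 2, ifelse(normalizer$keep, normalizer$sd, 1), "/")
  z[, normalizer$keep, drop = FALSE]
}

## ---- Cross-validation folds ------------------------------------------------

#' Leave-two-landings-out stratified folds
#'
#' One fold per (landing of class A) x (landing of class B) combination;
#' each fold tests on every epoch of exactly those two landings (one per
#' condition) and trains on the rest. With 4 landings per condition and 12
#' epochs per landing this yields 16 folds of 72 training / 24 test epochs.
#'
#' @param landing Integer vector, one entry per epoch.
#' @param label Condition label per epoch (constant within a landing).
#' @return List of folds, each a list with `test_landings`, `train` and
#'   `test` (integer row indices).
#' @export
make_folds <- function(landing, label) {
  stopifnot(length(landing) == length(label))
  per_landing <- tapply(as.character(label), landing, unique)
  if (any(lengths(per_landing) != 1)) {
    stop("condition label is not constant within a landing")
  }
  lnd_label <- vapply(per_landing, identity, character(1))
  classes <- sort(unique(lnd_label))
  if (length(classes) != 2) stop("need exactly 2 classes, got ", length(classes))
  l1 <- names(lnd_label)[lnd_label == classes[1]]
  l2 <- names(lnd_label)[lnd_label == classes[2]]
  if (length(l1) < 2 || length(l2) < 2) stop("need at least 2 landings per class")
  if (length(l1) != length(l2)) {
    stop("unbalanced design: ", length(l1), " vs ", length(l2),
         " landings per class")
  }
  folds <- list()
  for (a in l1) {
    for (b in l2) {
      test <- which(as.character(landing) %in% c(a, b))
      folds[[length(folds) + 1L]] <- list(
        test_landings = c(a, b),
        train = setdiff(seq_along(landing), test),
        test = test
      )
    }
  }
  folds
}

## ---- Shrinkage LDA ---------------------------------------------------------

# Ledoit-Wolf analytic shrinkage intensity toward (trace/p) * identity,
# estimated from class-centered observations
lw_shrinkage <- function(z) {
  n <- nrow(z); p <- ncol(z)
  S <- crossprod(z) / n
  nu <- sum(diag(S)) / p
  d2 <- sum((S - diag(nu, p))^2)
  if (d2 < .Machine$double.eps) return(0)
  b2 <- 0
  for (k in seq_len(n)) {
    W <- tcrossprod(z[k, ])
    b2 <- b2 + sum((W - S)^2)
  }
  b2 <- b2 / n^2
  max(0, min(1, b2 / d2))
}

#' Fit a shrinkage-regularized linear discriminant
#'
#' Two-class LDA whose pooled within-class covariance is shrunk toward a
#' scaled identity, `(1 - gamma) S + gamma (tr(S)/p) I`, with the shrinkage
#' intensity `gamma` estimated analytically (Ledoit-Wolf) unless fixed. The
#' regularized covariance is positive-definite for any `gamma > 0`, so the
#' model fits even with more dimensions than observations. Priors are taken
#' equal (the design is balanced). Ties in the discriminant score are broken
#' toward the first class in canonical label order.
#'
#' @param x Numeric matrix (rows = observations).
#' @param y Two-class label vector, length `nrow(x)`.
#' @param shrinkage Fixed shrinkage intensity in `[0, 1]`, or `NULL`
#'   (default) for the analytic estimate.
#' @return List of class `shrinkage_lda`: `classes`, `means`, `weights`,
#'   `bias`, `shrinkage`, `n`, `p`.
#' @export
fit_shrinkage_lda <- function(x, y, shrinkage = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop("need exactly 2 classes in the training set, got ", length(classes))
  }
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  p <- ncol(x)
  mu1 <- colMeans(x[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(x[y == classes[2], , drop = FALSE])
  z <- x
  z[y == classes[1], ] <- sweep(x[y == classes[1], , drop = FALSE], 2, mu1)
  z[y == classes[2], ] <- sweep(x[y == classes[2], , drop = FALSE], 2, mu2)
  if (is.null(shrinkage)) shrinkage <- lw_shrinkage(z)
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  S <- crossprod(z) / max(1, nrow(z) - 2)
  nu <- sum(diag(S)) / p
  S_reg <- (1 - shrinkage) * S + diag(shrinkage * nu, p)
  w <- solve(S_reg, mu2 - mu1)
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(classes = classes, means = rbind(mu1, mu2), weights = w,
                 bias = b, shrinkage = shrinkage, n = nrow(x), p = p),
            class = "shrinkage_lda")
}

#' Predict with a shrinkage LDA
#'
#' @param object A `shrinkage_lda` model.
#' @param newdata Matrix with the model's feature dimensions.
#' @param type `"class"` (default) or `"score"` (signed discriminant value;
#'   positive scores favor the second class).
#' @param ... Unused.
#' @return Character labels or numeric scores.
#' @export
predict.shrinkage_lda <- function(object, newdata, type = c("class", "score"),
                                  ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("dimension mismatch")
  score <- drop(newdata %*% object$weights) + object$bias
  if (type == "score") return(score)
  # score == 0 resolves to the first class in canonical order
  ifelse(score > 0, object$classes[2], object$classes[1])
}

#' @export
print.shrinkage_lda <- function(x, ...) {
  cat(sprintf("<shrinkage_lda> %s vs %s, p = %d, n = %d, shrinkage = %.3f\n",
              x$classes[1], x$classes[2], x$p, x$n, x$shrinkage))
  invisible(x)
}

#' Tidy a shrinkage LDA: one row per discriminant weight
#' @param x A `shrinkage_lda`.
#' @param ... Unused.
#' @return Tibble with `term` and `weight`.
#' @method tidy shrinkage_lda
#' @export
tidy.shrinkage_lda <- function(x, ...) {
  tibble::tibble(
    term = if (!is.null(names(x$weights))) names(x$weights)
           else paste0("dim", seq_along(x$weights)),
    weight = unname(x$weights)
  )
}

#' One-row model summary of a shrinkage LDA
#' @param x A `shrinkage_lda`.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `shrinkage`, `class_1`, `class_2`.
#' @method glance shrinkage_lda
#' @export
glance.shrinkage_lda <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, shrinkage = x$shrinkage,
                 class_1 = x$classes[1], class_2 = x$classes[2])
}

## ---- Chance level ----------------------------------------------------------

#' Exact binomial chance-level threshold
#'
#' The smallest number of correct predictions `k` out of `n` such that the
#' binomial CDF at `k` (success probability `1/classes`) reaches `1 - alpha`,
#' reported as an accuracy percentage `100 k / n`. Computed from the exact
#' binomial tail; no normal approximation. For `n = 96`, two classes and
#' `alpha = 0.05` the threshold is 58.33%.
#'
#' @param n Total number of test predictions (>= 1).
#' @param classes Number of classes (default 2).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Threshold in percent.
#' @examples
#' chance_threshold(96) # 58.33
#' @export
chance_threshold <- function(n, classes = 2, alpha = 0.05) {
  if (n < 1 || classes < 2) stop("need n >= 1 and classes >= 2")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  k <- stats::qbinom(1 - alpha, n, 1 / classes)
  100 * k / n
}

## ---- Feature matrices and CV evaluation ------------------------------------

#' Assemble per-feature ROI matrices for classification
#'
#' Pivots the tidy ROI-level feature tables into one numeric matrix per
#' (chromophore, feature): rows are epochs in a fixed (landing, epoch) order
#' shared across features, columns are the ROI (oxygenation, 6 dims) or
#' ROI-pair (connectivity, 21 dims) dimensions.
#'
#' @param oxy_roi Tibble from [reduce_oxygenation()] (or NULL).
#' @param conn_roi Tibble from [reduce_connectivity()] (or NULL).
#' @return List of class `fnirs_features`: `info` (tibble `landing`,
#'   `condition`, `epoch`), `matrices[[chromophore]][[feature]]`.
#' @export
build_feature_matrices <- function(oxy_roi = NULL, conn_roi = NULL) {
  if (is.null(oxy_roi) && is.null(conn_roi)) stop("no features supplied")
  long <- list()
  if (!is.null(oxy_roi)) {
    long$oxy <- oxy_roi |>
      dplyr::mutate(dim = .data$roi) |>
      dplyr::select("landing", "condition", "epoch", "chromophore",
                    "feature", "dim", "value")
  }
  if (!is.null(conn_roi)) {
    long$conn <- conn_roi |>
      dplyr::mutate(dim = paste(.data$roi_a, .data$roi_b, sep = "|"),
                    feature = .data$measure) |>
      dplyr::select("landing", "condition", "epoch", "chromophore",
                    "feature", "dim", "value")
  }
  long <- dplyr::bind_rows(long)
  info <- long |>
    dplyr::distinct(.data$landing, .data$condition, .data$epoch) |>
    dplyr::arrange(.data$landing, .data$epoch)
  key <- paste(info$landing, info$epoch)
  matrices <- list()
  for (chrom in unique(long$chromophore)) {
    sub_c <- long[long$chromophore == chrom, ]
    matrices[[chrom]] <- list()
    for (feat in unique(sub_c$feature)) {
      sub <- sub_c[sub_c$feature == feat, ]
      dims <- unique(sub$dim)
      m <- matrix(NA_real_, nrow(info), length(dims),
                  dimnames = list(NULL, dims))
      ridx <- match(paste(sub$landing, sub$epoch), key)
      cidx <- match(sub$dim, dims)
      m[cbind(ridx, cidx)] <- sub$value
      matrices[[chrom]][[feat]] <- m
    }
  }
  structure(list(info = info, matrices = matrices), class = "fnirs_features")
}

# per-fold z-score + LDA + accuracy for one design matrix
cv_accuracy <- function(x, label, folds, shrinkage = NULL,
                        global_zscore = FALSE) {
  x <- as.matrix(x)
  na_cols <- which(apply(x, 2, anyNA))
  if (length(na_cols) > 0) {
    warning("excluding ", length(na_cols),
            " dimension(s) with undefined values: ",
            paste(colnames(x)[na_cols], collapse = ", "))
    x <- x[, -na_cols, drop = FALSE]
    if (ncol(x) == 0) stop("no usable feature dimensions left")
  }
  if (global_zscore) {
    nz <- suppressWarnings(fit_normalizer(x))
    x <- apply_normalizer(nz, x)
  }
  vapply(folds, function(fold) {
    xtr <- x[fold$train, , drop = FALSE]
    xte <- x[fold$test, , drop = FALSE]
    if (!global_zscore) {
      nz <- suppressWarnings(fit_normalizer(xtr))
      xtr <- apply_normalizer(nz, xtr)
      xte <- apply_normalizer(nz, xte)
    }
    model <- fit_shrinkage_lda(xtr, label[fold$train], shrinkage = shrinkage)
    mean(predict(model, xte) == label[fold$test])
  }, numeric(1))
}

#' Evaluate features and feature pairs under the stratified CV
#'
#' For every requested feature set and chromophore: per fold, fit the
#' z-score normalizer and the shrinkage LDA on the training epochs, predict
#' the held-out two landings, and record accuracy. Feature pairs are
#' column-wise concatenations of the two feature matrices before
#' normalization. With the default 12 features this evaluates 12 single
#' sets plus C(12,2) = 66 pairs per chromophore.
#'
#' @param features A [build_feature_matrices()] result.
#' @param sets `"single"`, `"pairs"` or `"both"` (default "both"); or a list
#'   of character vectors naming explicit feature sets.
#' @param folds CV folds; default [make_folds()] on the feature info.
#' @param shrinkage Fixed LDA shrinkage intensity or NULL (analytic).
#' @param global_zscore If TRUE, z-score once on the full set instead of per
#'   training fold (reproduces whole-session scaling at the cost of
#'   normalization leakage; default FALSE).
#' @param alpha Significance level for the chance threshold (default 0.05).
#' @return Tibble of class `cv_results`: `feature_set`, `chromophore`,
#'   `fold`, `accuracy`; attributes `chance_threshold` (percent) and
#'   `n_test_total`.
#' @export
evaluate_features <- function(features, sets = c("both", "single", "pairs"),
                              folds = NULL, shrinkage = NULL,
                              global_zscore = FALSE, alpha = 0.05) {
  stopifnot(inherits(features, "fnirs_features"))
  info <- features$info
  if (is.null(folds)) folds <- make_folds(info$landing, info$condition)
  if (is.character(sets)) {
    sets <- match.arg(sets)
    feat_names <- names(features$matrices[[1]])
    singles <- as.list(feat_names)
    pairs <- if (length(feat_names) >= 2) {
      cmb <- utils::combn(feat_names, 2, simplify = FALSE)
      cmb
    } else list()
    sets <- switch(sets,
      single = singles, pairs = pairs, both = c(singles, pairs)
    )
  }
  res <- purrr::map_dfr(names(features$matrices), function(chrom) {
    mats <- features$matrices[[chrom]]
    purrr::map_dfr(sets, function(fs) {
      missing <- setdiff(fs, names(mats))
      if (length(missing) > 0) {
        stop("unknown feature(s): ", paste(missing, collapse = ", "))
      }
      x <- do.call(cbind, mats[fs])
      acc <- cv_accuracy(x, info$condition, folds, shrinkage = shrinkage,
                         global_zscore = global_zscore)
      tibble::tibble(
        feature_set = paste(fs, collapse = "+"),
        chromophore = chrom,
        fold = seq_along(acc),
        accuracy = acc
      )
    })
  })
  n_test_total <- length(unique(unlist(lapply(folds, function(f) f$test))))
  structure(res,
            chance_threshold = chance_threshold(n_test_total, 2, alpha),
            n_test_total = n_test_total,
            class = c("cv_results", class(res)))
}

#' Per-fold view of CV results
#' @param x A `cv_results` tibble.
#' @param ... Unused.
#' @return The underlying tibble (`feature_set`, `chromophore`, `fold`,
#'   `accuracy`).
#' @method tidy cv_results
#' @export
tidy.cv_results <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize CV results: mean accuracy per feature set and chromophore
#'
#' @param x A `cv_results` tibble.
#' @param ... Unused.
#' @return Tibble with `feature_set`, `chromophore`, `mean_accuracy`,
#'   `sd_accuracy`, `n_folds`, `chance_threshold` (percent), `significant`.
#' @method glance cv_results
#' @export
glance.cv_results <- function(x, ...) {
  thr <- attr(x, "chance_threshold")
  tibble::as_tibble(x) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      n_folds = dplyr::n(),
      .by = c("feature_set", "chromophore")
    ) |>
    dplyr::mutate(chance_threshold = thr,
                  significant = 100 * .data$mean_accuracy > thr)
}

#' Plot CV accuracies against the chance level
#'
#' @param object A `cv_results` tibble.
#' @param ... Unused.
#' @return A ggplot: mean accuracy per feature set and chromophore with the
#'   binomial chance threshold as a dashed line.
#' @method autoplot cv_results
#' @export
autoplot.cv_results <- function(object, ...) {
  smry <- glance.cv_results(object)
  thr <- attr(object, "chance_threshold") / 100
  ggplot2::ggplot(smry, ggplot2::aes(
    x = stats::reorder(.data$feature_set, .data$mean_accuracy),
    y = .data$mean_accuracy, fill = .data$chromophore
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean CV accuracy",
                  caption = sprintf("Dashed line: binomial chance level (%.1f%%)",
                                    100 * thr)) +
    ggplot2::theme_minimal()
}
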