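# Channel-to-ROI reduction: 42 channel values -> 6 ROI values per
# oxygenation feature; 861 channel-pair values -> 21 ROI-pair values per
# connectivity measure (the 15 between-ROI connections plus the 6 within-ROI
# terms, which are kept as features).

#' Reduce channel oxygenation features to ROI features
#'
#' Per ROI, the unweighted mean of the feature value over member channels.
#' Undefined channel values (NA) are dropped from the mean with a warning.
#'
#' @param features Tidy tibble from [extract_oxygenation()] (needs columns
#'   `channel`, `value` plus any grouping columns).
#' @param partition A [roi_partition()] or montage.
#' @return Tibble with `roi` replacing `channel`; one row per ROI per
#'   combination of the remaining id columns.
#' @export
reduce_oxygenation <- function(features, partition) {
  part <- roi_partition(partition)
  unmapped <- setdiff(unique(features$channel), part$channel)
  if (length(unmapped) > 0) {
    stop("channels without ROI mapping: ", paste(unmapped, collapse = ", "))
  }
  if (anyNA(features$value)) {
    warning("undefined feature values excluded from ROI means")
  }
  id_cols <- setdiff(names(features), c("channel", "value"))
  features |>
    dplyr::inner_join(part, by = "channel") |>
    dplyr::summarise(
      value = mean(.data$value, na.rm = TRUE),
      .by = dplyr::all_of(c(id_cols, "roi"))
    ) |>
    dplyr::mutate(roi = factor(.data$roi, levels = attr(part, "rois"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(id_cols, "roi")))) |>
    dplyr::mutate(roi = as.character(.data$roi))
}

#' Reduce channel-pair connectivity values to ROI-pair values
#'
#' For each unordered ROI pair, including the within-ROI terms, the mean over
#' all channel pairs whose endpoints lie in those ROIs. For the default
#' 6-ROI montage this yields 15 between-ROI + 6 within-ROI = 21 values per
#' measure; within-ROI terms average the C(7,2) = 21 internal channel pairs.
#' Between-ROI terms are ordered before within-ROI terms, each block in
#' canonical ROI order, so feature indices are stable across runs.
#'
#' @param pair_values Tidy tibble from [extract_connectivity()] (needs
#'   columns `ch_a`, `ch_b`, `value` plus grouping columns).
#' @param partition A [roi_partition()] or montage.
#' @return Tibble with `roi_a`, `roi_b` (canonical order, `roi_a == roi_b`
#'   for within-ROI terms) replacing the channel columns.
#' @export
reduce_connectivity <- function(pair_values, partition) {
  part <- roi_partition(partition)
  rois <- attr(part, "rois")
  missing_ch <- setdiff(unique(c(pair_values$ch_a, pair_values$ch_b)),
                        part$channel)
  if (length(missing_ch) > 0) {
    stop("pair endpoints without ROI mapping: ",
         paste(missing_ch, collapse = ", "))
  }
  lut <- stats::setNames(part$roi, part$channel)
  id_cols <- setdiff(names(pair_values), c("ch_a", "ch_b", "value"))
  ra <- lut[as.character(pair_values$ch_a)]
  rb <- lut[as.character(pair_values$ch_b)]
  ia <- match(ra, rois); ib <- match(rb, rois)
  swap <- ia > ib
  tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
  pair_values |>
    dplyr::mutate(roi_a = unname(ra), roi_b = unname(rb)) |>
    dplyr::summarise(
      value = mean(.data$value, na.rm = TRUE),
      .by = dplyr::all_of(c(id_cols, "roi_a", "roi_b"))
    ) |>
    dplyr::mutate(
      .within = .data$roi_a == .data$roi_b,
      .ia = match(.data$roi_a, rois), .ib = match(.data$roi_b, rois)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(id_cols)),
                   .data$.within, .data$.ia, .data$.ib) |>
    dplyr::select(-".within", -".ia", -".ib")
}

#' Expected number of ROI-pair features
#'
#' `C(R, 2) + R` for `R` ROIs: between-ROI connections plus the within-ROI
#' terms (21 for the default 6 ROIs).
#' @param n_roi Number of ROIs.
#' @return Integer count.
#' @export
n_roi_pairs <- function(n_roi) {
  as.integer(choose(n_roi, 2) + n_roi)
}
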