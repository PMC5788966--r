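#' Canonical region-of-interest labels
#'
#' The six cortical regions covered by the default frontal + occipital probe
#' layout, in the canonical order used everywhere in the package (feature
#' indices are stable because ROI order is stable).
#'
#' @return Character vector of length 6.
#' @export
roi_labels <- function() {
  c(
    "Frontal-Left", "Frontal-Right", "Fronto-Central",
    "Occipital-Left", "Occipital-Right", "Occipito-Central"
  )
}

#' Build the default 42-channel montage
#'
#' Two 8-source/8-detector optode sets cover frontal and occipital cortex,
#' giving 42 measurement channels grouped into 6 regions of interest (ROIs),
#' 7 channels per ROI. Each channel carries two wavelengths.
#'
#' @param channels_per_roi Number of channels per ROI (default 7, giving the
#'   standard 42-channel layout). Smaller montages are useful for simulation
#'   studies where the channel dimension is not under test.
#' @param sfreq Sampling rate in Hz (default 7.8125).
#' @param wavelengths Numeric vector of exactly two wavelengths in nm
#'   (default 760 and 850).
#' @param distance Source-detector separation in cm (default 3).
#'
#' @return A tibble of class `fnirs_montage` with one row per channel
#'   (`channel`, `source`, `detector`, `roi`) and attributes `sfreq`,
#'   `wavelengths`, `distance`.
#' @examples
#' m <- default_montage()
#' nrow(m) # 42
#' table(m$roi) # 7 per ROI
#' @export
default_montage <- function(channels_per_roi = 7, sfreq = 7.8125,
                            wavelengths = c(760, 850), distance = 3) {
  stopifnot(channels_per_roi >= 1, sfreq > 0, distance > 0)
  if (length(wavelengths) != 2L || any(wavelengths <= 0)) {
    stop("`wavelengths` must hold exactly two positive values (nm).")
  }
  rois <- roi_labels()
  n <- channels_per_roi * length(rois)
  m <- tibble::tibble(
    channel = seq_len(n),
    source = ((seq_len(n) - 1L) %/% 3L) + 1L,
    detector = ((seq_len(n) - 1L) %% 8L) + 1L,
    roi = rep(rois, each = channels_per_roi)
  )
  new_fnirs_montage(m, sfreq = sfreq, wavelengths = sort(wavelengths),
                    distance = distance)
}

new_fnirs_montage <- function(tbl, sfreq, wavelengths, distance) {
  structure(
    tbl,
    sfreq = sfreq,
    wavelengths = wavelengths,
    distance = distance,
    class = c("fnirs_montage", class(tbl))
  )
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf(
    "<fnirs_montage> %d channels, %d ROIs, %.4f Hz, wavelengths %s nm, d = %g cm\n",
    nrow(x), length(unique(x$roi)), attr(x, "sfreq"),
    paste(attr(x, "wavelengths"), collapse = "/"), attr(x, "distance")
  ))
  NextMethod()
}

#' Montage accessors
#'
#' Sampling rate (Hz), wavelengths (nm) and source-detector distance (cm)
#' of a montage.
#' @param montage A `fnirs_montage`.
#' @return Numeric scalar or vector.
#' @export
montage_sfreq <- function(montage) attr(montage, "sfreq")
#' @rdname montage_sfreq
#' @export
montage_wavelengths <- function(montage) attr(montage, "wavelengths")

#' @rdname montage_sfreq
#' @export
montage_distance <- function(montage) attr(montage, "distance")

validate_montage <- function(montage) {
  stopifnot(inherits(montage, "fnirs_montage"))
  if (anyDuplicated(montage$channel) > 0) stop("duplicate channel ids in montage")
  if (any(is.na(montage$roi))) stop("every channel must belong to exactly one ROI")
  invisible(montage)
}

#' Channel-to-ROI partition
#'
#' Extracts the total partition of channels into ROIs from a montage (or an
#' explicit mapping table with columns `channel` and `roi`).
#'
#' @param x A `fnirs_montage` or a data frame with `channel` and `roi` columns.
#' @return A tibble with columns `channel`, `roi` plus an attribute `rois`
#'   giving the ROI list in canonical order.
#' @export
roi_partition <- function(x) {
  stopifnot(all(c("channel", "roi") %in% names(x)))
  tbl <- tibble::as_tibble(x[, c("channel", "roi")])
  if (anyDuplicated(tbl$channel) > 0) {
    stop("partition is not total: a channel is mapped to more than one ROI")
  }
  rois <- intersect(roi_labels(), unique(tbl$roi))
  if (length(rois) == 0) rois <- sort(unique(tbl$roi))
  attr(tbl, "rois") <- rois
  tbl
}

#' All unordered channel pairs
#'
#' Enumerates the C(n, 2) unordered channel pairs of a montage in canonical
#' order (lower channel id first). For the default 42-channel montage this
#' yields 861 pairs.
#'
#' @param montage A `fnirs_montage` (or any data frame with a `channel` column).
#' @return A tibble with columns `ch_a`, `ch_b` (`ch_a < ch_b`).
#' @export
channel_pairs <- function(montage) {
  ch <- sort(montage$channel)
  if (length(ch) < 2) stop("need at least 2 channels to form pairs")
  idx <- utils::combn(ch, 2)
  tibble::tibble(ch_a = idx[1, ], ch_b = idx[2, ])
}
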