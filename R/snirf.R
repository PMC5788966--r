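# SNIRF (Shared Near Infrared Spectroscopy Format) I/O. SNIRF is HDF5, and
# the HDF5 layer here is delegated to a small bundled Python helper (h5py);
# numeric payloads travel through flat CSV scratch files so values
# round-trip exactly at full double precision.

find_python <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") {
    stop("SNIRF I/O requires a `python` with h5py on the PATH")
  }
  py
}

snirf_helper <- function() {
  system.file("python", "snirf_io.py", package = "fnirsbci", mustWork = TRUE)
}

run_snirf_job <- function(job) {
  py <- find_python()
  status <- system2(py, c(snirf_helper(), shQuote(jsonlite::toJSON(
    job, auto_unbox = TRUE
  ))), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0) {
    stop("SNIRF helper failed: ", paste(status, collapse = "\n"))
  }
  status
}

# measurement list: one row per data column (all wavelength-1 channels,
# then all wavelength-2 channels)
snirf_measlist <- function(montage) {
  rbind(
    cbind(montage$source, montage$detector, 1L),
    cbind(montage$source, montage$detector, 2L)
  )
}

#' Write a session to a SNIRF file
#'
#' Produces an HDF5 SNIRF file with one data block per landing (intensity
#' time series + measurement list), probe description, and the condition
#' labels as per-landing stimulus entries. Ground truth (condition labels,
#' coupling matrices, artifact events, seed) is written to a JSON sidecar
#' `<path>.groundtruth.json`.
#'
#' @param session A `fnirs_session`.
#' @param path Output file path (conventionally `.snirf`).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(session, path) {
  stopifnot(inherits(session, "fnirs_session"))
  if (length(session$landings) == 0) stop("session has no landings")
  montage <- session$montage
  payload <- tempfile("snirf_payload_")
  dir.create(payload)
  on.exit(unlink(payload, recursive = TRUE))

  ml <- snirf_measlist(montage)
  utils::write.table(ml, file.path(payload, "measlist.csv"), sep = ",",
                     row.names = FALSE, col.names = c("source", "detector", "wavelength"))
  for (i in seq_along(session$landings)) {
    d <- session$landings[[i]]$intensity
    flat <- cbind(d[, , 1], d[, , 2])
    utils::write.table(format(flat, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(payload, paste0("landing", i, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  n_src <- max(montage$source); n_det <- max(montage$detector)
  meta <- list(
    subject_id = "sim",
    wavelengths = montage_wavelengths(montage),
    sfreq = montage_sfreq(montage),
    n_landings = length(session$landings),
    conditions = vapply(session$landings, function(l) l$condition, character(1)),
    source_pos = as.vector(t(cbind(seq_len(n_src), 0, 0))),
    detector_pos = as.vector(t(cbind(seq_len(n_det), 1, 0)))
  )
  jsonlite::write_json(meta, file.path(payload, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  run_snirf_job(list(mode = "write", path = path, payload = payload))

  gt <- session$ground_truth
  jsonlite::write_json(
    list(
      condition = gt$condition,
      coupling = lapply(gt$coupling, unclass),
      artifact_events = gt$artifact_events,
      seed = gt$seed
    ),
    paste0(path, ".groundtruth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a SNIRF file into a session
#'
#' Reconstructs a `fnirs_session` from a SNIRF file: one landing per data
#' block, two wavelengths per channel, conditions from the stimulus names.
#' A channel-to-ROI map is required unless the file has the default
#' 42-channel layout, in which case the default montage mapping is assumed.
#'
#' @param path SNIRF file path.
#' @param roi_map Optional data frame with columns `channel`, `roi`.
#' @param sfreq Override for the sampling rate (default: inferred from the
#'   time vector).
#' @return A `fnirs_session` (without ground truth unless the sidecar file
#'   `<path>.groundtruth.json` exists).
#' @export
read_snirf <- function(path, roi_map = NULL, sfreq = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tempfile("snirf_read_")
  dir.create(payload)
  on.exit(unlink(payload, recursive = TRUE))
  run_snirf_job(list(mode = "read", path = path, payload = payload))
  meta <- jsonlite::fromJSON(file.path(payload, "meta.json"))
  ml <- utils::read.csv(file.path(payload, "measlist.csv"), header = FALSE,
                        skip = 1, col.names = c("source", "detector", "wavelength"))
  n_cols <- nrow(ml)
  n_ch <- n_cols / 2
  if (n_ch != round(n_ch)) stop("measurement list is not two-wavelength")
  if (is.null(sfreq)) sfreq <- meta$sfreq

  if (is.null(roi_map)) {
    if (n_ch == 42) {
      roi_map <- default_montage(sfreq = sfreq,
                                 wavelengths = meta$wavelengths)[, c("channel", "roi")]
    } else {
      stop("a channel-to-ROI map is required for a ", n_ch, "-channel file")
    }
  }
  part <- roi_partition(roi_map)
  if (nrow(part) != n_ch) stop("ROI map covers ", nrow(part), " channels, file has ", n_ch)
  m <- tibble::tibble(
    channel = seq_len(n_ch),
    source = ml$source[seq_len(n_ch)],
    detector = ml$detector[seq_len(n_ch)],
    roi = part$roi[match(seq_len(n_ch), part$channel)]
  )
  montage <- new_fnirs_montage(m, sfreq = sfreq,
                               wavelengths = sort(meta$wavelengths),
                               distance = 3)
  conditions <- meta$conditions
  landings <- lapply(seq_len(meta$n_landings), function(i) {
    d <- as.matrix(utils::read.csv(
      file.path(payload, paste0("landing", i, ".csv")), header = FALSE
    ))
    arr <- array(0, dim = c(nrow(d), n_ch, 2))
    arr[, , 1] <- d[, seq_len(n_ch)]
    arr[, , 2] <- d[, n_ch + seq_len(n_ch)]
    list(condition = if (length(conditions) >= i) conditions[i] else NA_character_,
         duration_s = nrow(d) / sfreq, intensity = arr)
  })
  sidecar <- paste0(path, ".groundtruth.json")
  gt <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar)
  } else {
    list(condition = vapply(landings, function(l) l$condition, character(1)))
  }
  structure(list(
    montage = montage, landings = landings, ground_truth = gt,
    mbll = NULL, config = NULL
  ), class = "fnirs_session")
}

#' Structural conformance check of a SNIRF file
#'
#' Verifies that the required SNIRF groups and datasets (format version,
#' metadata tags, probe wavelengths, data block with time vector and
#' measurement list) are present.
#'
#' @param path SNIRF file path.
#' @return Character vector of issues; empty if the structure conforms.
#' @export
snirf_structure_check <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- run_snirf_job(list(mode = "check", path = path))
  issues <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  as.character(issues)
}
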