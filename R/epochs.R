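#' Epoched EEG container
#'
#' An `epoch_array` holds one subject's epoched EEG as a
#' channels x time x trials numeric array together with its sampling rate,
#' time axis (ms relative to CS onset), per-trial CS labels and a subject id.
#' The canonical epoch spans -600 ms to 2000 ms: at 500 Hz that is 1300
#' samples starting at -600 ms in 2 ms steps (the end point is exclusive, so
#' the last sample sits at 1998 ms).
#'
#' @param data channels x time x trials numeric array (nominal microvolts).
#' @param srate Sampling rate in Hz.
#' @param channels Character vector of channel labels (length `dim(data)[1]`).
#' @param trial_labels CS type per trial (length `dim(data)[3]`).
#' @param subject_id Subject identifier string.
#' @param t_start First sample time in ms relative to CS onset.
#' @return An object of class `"epoch_array"`.
#' @export
epoch_array <- function(data, srate, channels, trial_labels, subject_id,
                        t_start = -600) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (length(channels) != d[1]) stop("channels length != dim(data)[1]", call. = FALSE)
  if (length(trial_labels) != d[3]) {
    stop("trial_labels length (", length(trial_labels),
         ") must equal trial count (", d[3], ")", call. = FALSE)
  }
  times <- t_start + 1000 / srate * (seq_len(d[2]) - 1)
  structure(
    list(data = data, srate = srate, times = times,
         channels = as.character(channels),
         trial_labels = as.character(trial_labels),
         subject_id = as.character(subject_id)),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> subject", x$subject_id, "\n")
  cat("  ", d[1], "channels x", d[2], "samples x", d[3], "trials @",
      x$srate, "Hz\n")
  cat("  time ", min(x$times), "..", max(x$times), "ms\n")
  tab <- table(x$trial_labels)
  cat("  trials:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' Number of samples in the canonical epoch
#'
#' @param srate Sampling rate in Hz.
#' @param t_start,t_end Epoch limits in ms (start inclusive, end exclusive).
#' @return Integer sample count; 1300 at the 500 Hz default.
#' @export
epoch_n_samples <- function(srate = 500, t_start = -600, t_end = 2000) {
  as.integer(round((t_end - t_start) * srate / 1000))
}

#' Subset an epoch array by trials and/or channels
#'
#' @param epochs An `epoch_array`.
#' @param trials Integer or logical index over trials.
#' @param channels Channel labels to keep.
#' @return An `epoch_array`.
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  ch_idx <- seq_along(epochs$channels)
  if (!is.null(channels)) {
    ch_idx <- match(channels, epochs$channels)
    if (anyNA(ch_idx)) {
      stop("Unknown channels: ",
           paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
    }
  }
  tr_idx <- seq_along(epochs$trial_labels)
  if (!is.null(trials)) tr_idx <- tr_idx[trials]
  epoch_array(epochs$data[ch_idx, , tr_idx, drop = FALSE], epochs$srate,
              epochs$channels[ch_idx], epochs$trial_labels[tr_idx],
              epochs$subject_id, t_start = epochs$times[1])
}

#' Save / load an epoch array (lossless round trip)
#'
#' The signal is stored as a flat little-endian float64 binary file and the
#' metadata (dimensions, sampling rate, time axis, labels, subject id) in a
#' JSON sidecar `<path>.json`.
#'
#' @param epochs An `epoch_array`.
#' @param path Path for the binary array file (e.g. `"sub01.f64"`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` the
#'   restored `epoch_array`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  meta <- list(dims = dim(epochs$data), srate = epochs$srate,
               t_start = epochs$times[1], channels = epochs$channels,
               trial_labels = epochs$trial_labels,
               subject_id = epochs$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) != n) stop("Truncated epoch file: ", path, call. = FALSE)
  epoch_array(array(vals, dim = meta$dims), meta$srate, meta$channels,
              meta$trial_labels, meta$subject_id, t_start = meta$t_start)
}
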