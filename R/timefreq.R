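#' Morlet wavelet bank
#'
#' Complex Morlet wavelets with variable bandwidth: at centre frequency `f`
#' the spectral SD is `sigma_f = f / m` (Morlet parameter `m = f/sigma_f`,
#' default 12) and the temporal SD `sigma_t = 1/(2 pi sigma_f)`. The default
#' frequency grid runs from 3.8 to 30.4 Hz in linear steps of 0.38 Hz.
#'
#' @param freqs Centre frequencies in Hz (uniformly spaced, all > 0).
#' @param m Morlet parameter `f / sigma_f`; must exceed 5 (admissibility).
#' @param srate Sampling rate in Hz.
#' @param trunc_sd Wavelet support truncation, in temporal SDs (default 3.5).
#' @return A list of class `"wavelet_bank"`.
#' @export
wavelet_bank <- function(freqs = seq(3.8, 30.4, by = 0.38), m = 12,
                         srate = 500, trunc_sd = 3.5) {
  stopifnot(all(freqs > 0), length(freqs) >= 1)
  if (length(freqs) > 1) {
    steps <- diff(freqs)
    if (max(abs(steps - steps[1])) > 1e-9) {
      stop("Frequency grid must be uniformly spaced", call. = FALSE)
    }
  }
  if (m <= 5) stop("Morlet parameter must exceed 5 (admissibility)", call. = FALSE)
  structure(list(freqs = freqs, m = m, srate = srate, trunc_sd = trunc_sd,
                 step = if (length(freqs) > 1) diff(freqs)[1] else NA_real_),
            class = "wavelet_bank")
}

#' A single complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential, truncated at `trunc_sd` temporal
#' SDs and normalized to unit discrete energy (`sum(|w|^2) == 1`).
#'
#' @param f Centre frequency, Hz.
#' @param m Morlet parameter `f / sigma_f`.
#' @param srate Sampling rate, Hz.
#' @param trunc_sd Support truncation in temporal SDs.
#' @return Complex vector of odd length.
#' @export
morlet_wavelet <- function(f, m = 12, srate = 500, trunc_sd = 3.5) {
  sigma_f <- f / m
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(trunc_sd * sigma_t * srate)
  t <- (-half:half) / srate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Spectral characterization of an implemented wavelet
#'
#' Measures the centre frequency and spectral SD of a [morlet_wavelet()]
#' from its discrete Fourier amplitude spectrum: the centre is the midpoint
#' of the half-maximum crossings and the SD is derived from the full width
#' at half maximum (`FWHM / (2 sqrt(2 ln 2))`), which is robust to the small
#' sidelobes introduced by support truncation. For a Morlet wavelet the
#' `centre / sd` ratio equals the Morlet parameter `m = f / sigma_f`.
#'
#' @inheritParams morlet_wavelet
#' @param nfft Zero-padded FFT length for the spectral measurement.
#' @return Named numeric: `centre` (Hz), `sd` (Hz), `ratio`.
#' @export
wavelet_spectral_ratio <- function(f, m = 12, srate = 500, trunc_sd = 3.5,
                                   nfft = 2^18) {
  w <- morlet_wavelet(f, m, srate, trunc_sd)
  amp <- Mod(stats::fft(c(w, rep(0, nfft - length(w)))))
  fax <- (0:(nfft - 1)) * srate / nfft
  keep <- fax <= srate / 2
  amp <- amp[keep]
  fax <- fax[keep]
  pk <- which.max(amp)
  half <- amp[pk] / 2
  lo <- max(which(amp[1:pk] <= half))
  hi <- pk - 1L + min(which(amp[pk:length(amp)] <= half))
  f_lo <- fax[lo] + (half - amp[lo]) / (amp[lo + 1] - amp[lo]) *
    (fax[lo + 1] - fax[lo])
  f_hi <- fax[hi - 1] + (half - amp[hi - 1]) / (amp[hi] - amp[hi - 1]) *
    (fax[hi] - fax[hi - 1])
  sigma <- (f_hi - f_lo) / (2 * sqrt(2 * log(2)))
  centre <- (f_hi + f_lo) / 2
  c(centre = centre, sd = sigma, ratio = centre / sigma)
}

#' Baseline-correct and taper epochs in the time domain
#'
#' Per trial and channel, subtracts the mean of the pre-stimulus baseline
#' window and applies a cosine-square (Hann-flank) taper: the first and last
#' `rise_fall_samples` samples are scaled by a squared-sine ramp whose first
#' sample is exactly 0; the interior is unchanged.
#'
#' @param epochs An [epoch_array()].
#' @param baseline_ms Length-2 baseline window in ms, inclusive (default
#'   `c(-600, -500)`).
#' @param rise_fall_samples Ramp length in samples (default 20; 40 ms at
#'   500 Hz).
#' @return A tapered, baseline-corrected [epoch_array()].
#' @export
taper_and_baseline <- function(epochs, baseline_ms = c(-600, -500),
                               rise_fall_samples = 20L) {
  stopifnot(inherits(epochs, "epoch_array"))
  sel <- epochs$times >= baseline_ms[1] & epochs$times <= baseline_ms[2]
  if (!any(sel)) {
    stop("Baseline window [", baseline_ms[1], ", ", baseline_ms[2],
         "] ms lies outside the epoch (", min(epochs$times), "..",
         max(epochs$times), " ms)", call. = FALSE)
  }
  d <- dim(epochs$data)
  r <- as.integer(rise_fall_samples)
  stopifnot(r >= 2, 2 * r <= d[2])
  ramp <- sin(pi / 2 * (0:(r - 1)) / (r - 1))^2
  win <- rep(1, d[2])
  win[1:r] <- ramp
  win[d[2]:(d[2] - r + 1)] <- ramp

  x <- epochs$data
  base <- apply(x[, sel, , drop = FALSE], c(1, 3), mean)
  for (tr in seq_len(d[3])) {
    x[, , tr] <- (x[, , tr] - base[, tr]) * rep(win, each = d[1])
  }
  epoch_array(x, epochs$srate, epochs$channels, epochs$trial_labels,
              epochs$subject_id, t_start = epochs$times[1])
}

#' Time-frequency power container
#'
#' Holds trial-averaged (or single-condition) wavelet power as a
#' frequencies x time x channels array, along with the frequency grid, time
#' axis, per-frequency convolution edge flags, and (after
#' [baseline_normalize()]) the stored baseline means that make the percent
#' -change rescaling invertible.
#'
#' @name tf_power
NULL

new_tf_power <- function(power, freqs, times, channels, srate, n_trials,
                         edge, subject_id, label,
                         normalized = FALSE, baseline_window = NULL,
                         baseline_mean = NULL, baseline_mode = NULL) {
  structure(list(power = power, freqs = freqs, times = times,
                 channels = channels, srate = srate, n_trials = n_trials,
                 edge = edge, subject_id = subject_id, label = label,
                 normalized = normalized, baseline_window = baseline_window,
                 baseline_mean = baseline_mean, baseline_mode = baseline_mode),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  cat("<tf_power>", if (x$normalized) "percent change" else "raw power", "\n")
  cat("  ", length(x$freqs), "freqs x", length(x$times), "samples x",
      length(x$channels), "channels; averaged over", x$n_trials, "trials\n")
  if (!is.null(x$label)) cat("  condition:", x$label, "\n")
  invisible(x)
}

#' Trial-averaged Morlet wavelet power
#'
#' Convolves every channel/trial series with each complex Morlet wavelet
#' (FFT convolution, zero-padded), squares the magnitude, and averages over
#' the trials present in `epochs`. Subset the epochs by condition first (see
#' [condition_power()]) to obtain per-condition averages. Samples whose
#' convolution window extends past the epoch edge are flagged per frequency
#' in the `edge` matrix.
#'
#' @param epochs A tapered [epoch_array()].
#' @param bank A [wavelet_bank()] with `srate` matching the epochs.
#' @param chunk_cols Number of channel/trial series transformed per FFT
#'   block (memory control).
#' @return A [tf_power] object (raw power, not yet normalized).
#' @export
morlet_power <- function(epochs, bank, chunk_cols = 4096L) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(bank, "wavelet_bank"))
  if (abs(bank$srate - epochs$srate) > 1e-9) {
    stop("wavelet_bank srate (", bank$srate, ") != epoch srate (",
         epochs$srate, ")", call. = FALSE)
  }
  d <- dim(epochs$data)
  n <- d[2]
  wavelets <- lapply(bank$freqs, morlet_wavelet, m = bank$m,
                     srate = bank$srate, trunc_sd = bank$trunc_sd)
  nw <- vapply(wavelets, length, integer(1))
  if (max(nw) > n) {
    stop("Wavelet support (", max(nw), " samples at ",
         bank$freqs[which.max(nw)], " Hz) exceeds the epoch length (", n,
         " samples); need at least ", max(nw), " samples", call. = FALSE)
  }
  nfft <- 2^ceiling(log2(n + max(nw) - 1))
  wf <- lapply(wavelets, function(w) stats::fft(c(w, rep(0, nfft - length(w)))))

  n_freq <- length(bank$freqs)
  power <- array(0, dim = c(n_freq, n, d[1]))
  # series as columns: time x (channel-major within trial)
  x <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = n)
  n_cols <- ncol(x)

  for (start in seq(1L, n_cols, by = chunk_cols)) {
    cols <- start:min(n_cols, start + chunk_cols - 1L)
    fx <- stats::mvfft(rbind(x[, cols, drop = FALSE],
                             matrix(0, nfft - n, length(cols))))
    # channel index of each column in this chunk
    ch_of <- ((cols - 1L) %% d[1]) + 1L
    for (k in seq_len(n_freq)) {
      conv <- stats::mvfft(fx * wf[[k]], inverse = TRUE) / nfft
      off <- (nw[k] - 1L) %/% 2L
      p <- Mod(conv[(off + 1L):(off + n), , drop = FALSE])^2
      for (ch in unique(ch_of)) {
        power[k, , ch] <- power[k, , ch] +
          rowSums(p[, ch_of == ch, drop = FALSE])
      }
    }
  }
  power <- power / d[3]

  half <- (nw - 1L) %/% 2L
  edge <- matrix(FALSE, n_freq, n)
  for (k in seq_len(n_freq)) {
    if (half[k] > 0) edge[k, c(seq_len(half[k]), (n - half[k] + 1L):n)] <- TRUE
  }
  new_tf_power(power, bank$freqs, epochs$times, epochs$channels, epochs$srate,
               d[3], edge, epochs$subject_id,
               label = if (length(unique(epochs$trial_labels)) == 1L)
                 unique(epochs$trial_labels) else NULL)
}

#' Per-condition trial-averaged power
#'
#' @param epochs A tapered [epoch_array()].
#' @param bank A [wavelet_bank()].
#' @param conditions Conditions to compute (default: all labels present).
#' @param ... Passed to [morlet_power()].
#' @return Named list of [tf_power] objects, one per condition.
#' @export
condition_power <- function(epochs, bank, conditions = NULL, ...) {
  conditions <- conditions %||% sort(unique(epochs$trial_labels))
  out <- lapply(conditions, function(cs) {
    morlet_power(subset_epochs(epochs, trials = epochs$trial_labels == cs),
                 bank, ...)
  })
  stats::setNames(out, conditions)
}

#' Pool trial-averaged power across groups
#'
#' Weighted (by trial count) mean of raw-power maps, e.g. to rebuild a
#' condition average from per-block averages.
#'
#' @param tf_list List of raw (unnormalized) [tf_power] objects on identical
#'   grids.
#' @return A [tf_power] object.
#' @export
pool_power <- function(tf_list) {
  stopifnot(length(tf_list) >= 1, !any(vapply(tf_list, `[[`, TRUE, "normalized")))
  w <- vapply(tf_list, `[[`, numeric(1), "n_trials")
  power <- Reduce(`+`, Map(function(tf, wi) tf$power * wi, tf_list, w)) / sum(w)
  tmpl <- tf_list[[1]]
  new_tf_power(power, tmpl$freqs, tmpl$times, tmpl$channels, tmpl$srate,
               sum(w), tmpl$edge, tmpl$subject_id, label = NULL)
}

#' Rescale power to percent change from a pre-stimulus baseline
#'
#' Per frequency and channel, the condition-averaged power is divided by its
#' mean over the baseline window and rescaled to
#' `100 * (power / baseline - 1)`. With `mode = "amplitude"` the division is
#' performed in the amplitude domain (square root of power) instead; the
#' power-domain default matches percent-change power maps.
#'
#' @param tf A raw [tf_power] object.
#' @param baseline_ms Baseline window in ms, inclusive (default
#'   `c(-400, -200)`).
#' @param mode `"power"` (default) or `"amplitude"`.
#' @return A normalized [tf_power] (values >= -100); the per-frequency/
#'   channel baseline means are stored for invertibility.
#' @export
baseline_normalize <- function(tf, baseline_ms = c(-400, -200),
                               mode = c("power", "amplitude")) {
  stopifnot(inherits(tf, "tf_power"))
  mode <- match.arg(mode)
  if (tf$normalized) stop("tf_power is already normalized", call. = FALSE)
  sel <- tf$times >= baseline_ms[1] & tf$times <= baseline_ms[2]
  if (!any(sel)) {
    stop("Baseline window outside the epoch time axis", call. = FALSE)
  }
  vals <- if (mode == "power") tf$power else sqrt(tf$power)
  base <- apply(vals[, sel, , drop = FALSE], c(1, 3), mean)
  if (any(base == 0)) {
    stop("Zero baseline mean (degenerate input); cannot rescale", call. = FALSE)
  }
  out <- 100 * (sweep(vals, c(1, 3), base, `/`) - 1)
  new_tf_power(out, tf$freqs, tf$times, tf$channels, tf$srate, tf$n_trials,
               tf$edge, tf$subject_id, tf$label, normalized = TRUE,
               baseline_window = baseline_ms, baseline_mean = base,
               baseline_mode = mode)
}

# indices of the frequency bins spanned by [lo, hi]; each endpoint snaps to
# the nearest bin within half a grid step, otherwise to the nearest bin
# inside the interval
band_bins <- function(freqs, band_hz) {
  step <- if (length(freqs) > 1) diff(freqs)[1] else Inf
  snap <- function(target, side) {
    i <- which.min(abs(freqs - target))
    if (abs(freqs[i] - target) <= step / 2 + 1e-12) return(i)
    if (side == "lo") {
      cand <- which(freqs >= target)
      if (!length(cand)) return(NA_integer_)
      min(cand)
    } else {
      cand <- which(freqs <= target)
      if (!length(cand)) return(NA_integer_)
      max(cand)
    }
  }
  lo <- snap(band_hz[1], "lo")
  hi <- snap(band_hz[2], "hi")
  if (is.na(lo) || is.na(hi) || lo > hi) {
    stop("Frequency band [", band_hz[1], ", ", band_hz[2],
         "] Hz selects no bins on the grid", call. = FALSE)
  }
  lo:hi
}

# mean of normalized power over band x window x ROI (inclusive endpoints);
# warns if the selection touches convolution edge samples
tf_mean <- function(tf, band_hz, roi, window_ms, warn_edge = TRUE) {
  stopifnot(inherits(tf, "tf_power"))
  if (!tf$normalized) stop("tf_power must be normalized first", call. = FALSE)
  fb <- band_bins(tf$freqs, band_hz)
  tsel <- which(tf$times >= window_ms[1] & tf$times <= window_ms[2])
  chsel <- match(roi, tf$channels)
  if (anyNA(chsel)) {
    stop("ROI channels not present: ",
         paste(roi[is.na(chsel)], collapse = ", "), call. = FALSE)
  }
  if (!length(tsel)) stop("Empty time window selection", call. = FALSE)
  if (warn_edge && any(tf$edge[fb, tsel])) {
    warning("Selection window touches convolution edge samples",
            call. = FALSE)
  }
  mean(tf$power[fb, tsel, chsel])
}

#' Save / load a time-frequency power container (lossless round trip)
#'
#' The power array is stored as flat little-endian float64 with a JSON
#' sidecar `<path>.json` carrying the grid, axes, edge flags and
#' normalization state.
#'
#' @param tf A [tf_power] object.
#' @param path Path for the binary array file.
#' @return `write_tf_power()` returns `path` invisibly; `read_tf_power()`
#'   the restored object.
#' @export
write_tf_power <- function(tf, path) {
  stopifnot(inherits(tf, "tf_power"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(tf$power), con, size = 8L, endian = "little")
  meta <- list(dims = dim(tf$power), freqs = tf$freqs, t_start = tf$times[1],
               srate = tf$srate, channels = tf$channels,
               n_trials = tf$n_trials, edge = tf$edge,
               subject_id = tf$subject_id, label = tf$label,
               normalized = tf$normalized,
               baseline_window = tf$baseline_window,
               baseline_mean = tf$baseline_mean,
               baseline_mode = tf$baseline_mode)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tf_power
#' @export
read_tf_power <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dims), size = 8L,
                  endian = "little")
  if (length(vals) != prod(meta$dims)) {
    stop("Truncated tf_power file: ", path, call. = FALSE)
  }
  times <- meta$t_start + 1000 / meta$srate * (seq_len(meta$dims[2]) - 1)
  new_tf_power(array(vals, meta$dims), meta$freqs, times, meta$channels,
               meta$srate, meta$n_trials,
               matrix(meta$edge, meta$dims[1], meta$dims[2]),
               meta$subject_id, meta$label, normalized = meta$normalized,
               baseline_window = meta$baseline_window,
               baseline_mean = if (!is.null(meta$baseline_mean))
                 matrix(meta$baseline_mean, meta$dims[1], meta$dims[3]),
               baseline_mode = meta$baseline_mode)
}

#' Long-format condition-difference map
#'
#' Elementwise difference of two time-frequency maps on the same grid
#' (e.g. CS+ minus CS-), returned as a tidy frame ready for CSV export or
#' plotting.
#'
#' @param tf_a,tf_b [tf_power] objects on identical grids.
#' @return A tibble with columns `freq_hz`, `time_ms`, `channel`, `value`.
#' @export
tf_difference_long <- function(tf_a, tf_b) {
  stopifnot(inherits(tf_a, "tf_power"), inherits(tf_b, "tf_power"))
  if (!isTRUE(all.equal(tf_a$freqs, tf_b$freqs)) ||
      !identical(tf_a$channels, tf_b$channels) ||
      !isTRUE(all.equal(tf_a$times, tf_b$times))) {
    stop("tf_power grids differ", call. = FALSE)
  }
  d <- tf_a$power - tf_b$power
  nf <- length(tf_a$freqs)
  nt <- length(tf_a$times)
  tibble::tibble(
    freq_hz = rep(tf_a$freqs, times = nt * length(tf_a$channels)),
    time_ms = rep(rep(tf_a$times, each = nf), times = length(tf_a$channels)),
    channel = rep(tf_a$channels, each = nf * nt),
    value = as.vector(d))
}

#' Subject-level alpha summary for the 2x2 design
#'
#' Means the normalized power over the alpha band, occipital ROI and analysis
#' window for each CS type, yielding one row per design cell: the values
#' that feed all 2x2 inference.
#'
#' @param tf_by_cond Named list of normalized [tf_power] objects, one per CS
#'   type (`CS+E`, `CS+N`, `CS-E`, `CS-N`).
#' @param band_hz Alpha band in Hz, inclusive after nearest-bin snapping
#'   (default `c(8.1, 11.9)`).
#' @param roi Channels averaged (default [roi_channels()]).
#' @param window_ms Analysis window in ms, inclusive (default `c(500, 1200)`).
#' @param subject_id Optional override for the subject id.
#' @return A tibble with columns `subject_id`, `contingency` (`"CS+"` /
#'   `"CS-"`), `extinction` (`"E"` / `"N"`), `alpha_pct`.
#' @export
alpha_summary <- function(tf_by_cond, band_hz = c(8.1, 11.9),
                          roi = roi_channels(), window_ms = c(500, 1200),
                          subject_id = NULL) {
  stopifnot(all(cs_types() %in% names(tf_by_cond)))
  sid <- subject_id %||% tf_by_cond[[1]]$subject_id %||% "sub"
  purrr::map_dfr(cs_types(), function(cs) {
    tibble::tibble(
      subject_id = sid,
      contingency = substr(cs, 1, 3),
      extinction = substr(cs, 4, 4),
      alpha_pct = tf_mean(tf_by_cond[[cs]], band_hz, roi, window_ms,
                          warn_edge = FALSE)
    )
  })
}

#' Per-subject alpha timecourses by contingency
#'
#' Band/ROI-averaged normalized power at every time sample, with the two
#' extinction members of each contingency level averaged (both CS+ vs. both
#' CS-): the input to the per-sample permutation test.
#'
#' @inheritParams alpha_summary
#' @return A tibble with columns `subject_id`, `contingency`, `time_ms`,
#'   `alpha_pct`; the full epoch time axis per series.
#' @export
timecourse_summary <- function(tf_by_cond, band_hz = c(8.1, 11.9),
                               roi = roi_channels(), subject_id = NULL) {
  stopifnot(all(cs_types() %in% names(tf_by_cond)))
  sid <- subject_id %||% tf_by_cond[[1]]$subject_id %||% "sub"
  tmpl <- tf_by_cond[[1]]
  fb <- band_bins(tmpl$freqs, band_hz)
  chsel <- match(roi, tmpl$channels)
  if (anyNA(chsel)) {
    stop("ROI channels not present: ",
         paste(roi[is.na(chsel)], collapse = ", "), call. = FALSE)
  }
  # freqs x time x roi -> per-sample mean over freq and roi
  series <- function(cs) {
    tf <- tf_by_cond[[cs]]
    if (!tf$normalized) stop("tf_power must be normalized first", call. = FALSE)
    apply(tf$power[fb, , chsel, drop = FALSE], 2, mean)
  }
  purrr::map_dfr(c("CS+", "CS-"), function(cg) {
    members <- paste0(cg, c("E", "N"))
    avg <- (series(members[1]) + series(members[2])) / 2
    tibble::tibble(subject_id = sid, contingency = cg,
                   time_ms = tmpl$times, alpha_pct = avg)
  })
}
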