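#' Simulation parameters
#'
#' Bundles the generative settings for synthetic recall-test EEG. The
#' defaults reproduce the paradigm's recording conditions: 500 Hz sampling,
#' epochs from -600 to 2000 ms, a 10 Hz occipital alpha oscillator whose
#' amplitude is suppressed after CS onset (event-related desynchronization,
#' ERD), 1/f background noise mixed across neighbouring channels, and
#' per-subject variation in amplitude and effect size. Retained-trial counts
#' per CS type are drawn from the 16-57 range observed after artifact
#' rejection in this paradigm.
#'
#' @param n_subjects Number of subjects for cohort simulation.
#' @param srate Sampling rate, Hz.
#' @param alpha_freq_hz Centre frequency of the simulated alpha oscillator.
#' @param baseline_alpha_amp Length-2 numeric: mean and between-subject SD of
#'   the pre-stimulus alpha amplitude (nominal microvolts).
#' @param erd_onset_ms Onset of the amplitude suppression, ms after CS onset.
#' @param ramp_ms Duration of the linear amplitude ramp from 1 to 1 - depth.
#' @param suppression_depth Named numeric over the four CS types: fraction of
#'   the baseline alpha amplitude removed after `erd_onset_ms` (in \[0, 1\]).
#' @param depth_jitter_sd SD of the per-subject additive jitter applied to
#'   all four depths jointly (shared draw, so equal depths stay equal within
#'   a subject; results are clamped to \[0, 1\]).
#' @param noise_1f_amp RMS amplitude of the 1/f background noise.
#' @param topo_sd_rad Angular SD (radians) of the Gaussian alpha topography
#'   centred at Oz.
#' @param mix_width_rad Angular width of the Gaussian channel-mixing kernel
#'   that spatially correlates the noise (volume-conduction stand-in).
#' @param dc_offset_sd SD of the per-channel DC offset (exercises the
#'   reference-invariance of the surface Laplacian downstream).
#' @param trials_retained Either a length-2 integer range applied to every CS
#'   type or a named list of ranges per CS type; the retained count per CS is
#'   drawn uniformly from the range.
#' @param t_start,t_end Epoch limits in ms (start inclusive, end exclusive).
#' @param seed Master seed for cohort simulation.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_subjects = 24,
                       srate = 500,
                       alpha_freq_hz = 10,
                       baseline_alpha_amp = c(20, 5),
                       erd_onset_ms = 500,
                       ramp_ms = 200,
                       suppression_depth = c("CS+E" = 0.5, "CS+N" = 0.5,
                                             "CS-E" = 0.2, "CS-N" = 0.2),
                       depth_jitter_sd = 0.08,
                       noise_1f_amp = 10,
                       topo_sd_rad = 0.6,
                       mix_width_rad = 0.35,
                       dc_offset_sd = 20,
                       trials_retained = c(16L, 57L),
                       t_start = -600, t_end = 2000,
                       seed = 1L) {
  if (!all(cs_types() %in% names(suppression_depth))) {
    stop("suppression_depth must be named over ",
         paste(cs_types(), collapse = ", "), call. = FALSE)
  }
  suppression_depth <- suppression_depth[cs_types()]
  if (any(suppression_depth < 0 | suppression_depth > 1)) {
    stop("suppression_depth must lie in [0, 1]", call. = FALSE)
  }
  if (is.numeric(trials_retained)) {
    trials_retained <- stats::setNames(
      rep(list(as.integer(trials_retained)), 4L), cs_types())
  }
  stopifnot(all(cs_types() %in% names(trials_retained)))
  for (r in trials_retained) stopifnot(length(r) == 2L, r[1] >= 1L, r[2] >= r[1])
  structure(
    list(n_subjects = as.integer(n_subjects), srate = srate,
         alpha_freq_hz = alpha_freq_hz,
         baseline_alpha_amp = baseline_alpha_amp,
         erd_onset_ms = erd_onset_ms, ramp_ms = ramp_ms,
         suppression_depth = suppression_depth,
         depth_jitter_sd = depth_jitter_sd,
         noise_1f_amp = noise_1f_amp, topo_sd_rad = topo_sd_rad,
         mix_width_rad = mix_width_rad, dc_offset_sd = dc_offset_sd,
         trials_retained = trials_retained,
         t_start = t_start, t_end = t_end,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# 1/f-amplitude-shaped Gaussian noise, one column per channel/trial series.
# Spectral shaping via FFT; the filter is normalized to unit RMS gain so the
# output SD matches the input's.
noise_1f_matrix <- function(n_samples, n_cols, srate) {
  x <- matrix(stats::rnorm(n_samples * n_cols), n_samples, n_cols)
  k <- seq_len(n_samples) - 1L
  f <- pmin(k, n_samples - k) * srate / n_samples  # two-sided frequency axis
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)             # power ~ 1/f
  amp <- amp / sqrt(mean(amp^2))
  ft <- stats::mvfft(x) * amp
  Re(stats::mvfft(ft, inverse = TRUE)) / n_samples
}

# Gaussian angular mixing kernel, row-normalized
mixing_matrix <- function(montage, width_rad) {
  ang <- montage_angles(montage)
  k <- exp(-(ang / width_rad)^2)
  k / rowSums(k)
}

# multiplicative ERD envelope: 1 before onset, linear ramp to 1 - depth
erd_envelope <- function(times_ms, depth, onset_ms, ramp_ms) {
  frac <- pmin(1, pmax(0, (times_ms - onset_ms) / ramp_ms))
  1 - depth * frac
}

#' Simulate one subject's recall-test epochs
#'
#' Each trial is spatially mixed 1/f noise plus a 10 Hz alpha oscillation
#' with random phase per trial, a Gaussian topography peaking at Oz, and a
#' multiplicative ERD envelope dropping from 1 to `1 - depth[cs_type]` via a
#' linear ramp starting at `erd_onset_ms`. A per-channel DC offset is added.
#' The number of retained trials per CS type is drawn from the configured
#' range and trials are subsampled from the schedule in presentation order.
#'
#' @param schedule A recall-phase schedule from [generate_schedule()].
#' @param params A [sim_params()] object.
#' @param montage A montage from [build_montage()].
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param subject_id Subject identifier.
#' @return An [epoch_array()].
#' @export
simulate_subject <- function(schedule, params, montage, seed,
                             subject_id = "sub01") {
  validate_schedule(schedule)
  if (unique(schedule$phase) != "recall") {
    stop("simulate_subject targets the recall phase", call. = FALSE)
  }
  stopifnot(inherits(params, "sim_params"))
  validate_montage(montage)
  if (any(params$suppression_depth < 0 | params$suppression_depth > 1)) {
    stop("suppression_depth must lie in [0, 1]", call. = FALSE)
  }
  local_rng(seed)

  n_samp <- epoch_n_samples(params$srate, params$t_start, params$t_end)
  times <- params$t_start + 1000 / params$srate * (0:(n_samp - 1))
  n_ch <- nrow(montage)

  # per-subject draws
  amp <- max(0.1, stats::rnorm(1, params$baseline_alpha_amp[1],
                               params$baseline_alpha_amp[2]))
  jitter <- stats::rnorm(1, 0, params$depth_jitter_sd)
  depths <- pmin(pmax(params$suppression_depth + jitter, 0), 1)
  dc <- stats::rnorm(n_ch, 0, params$dc_offset_sd)

  # retained trials per CS type, subsampled from the schedule
  kept <- purrr::map(cs_types(), function(cs) {
    idx <- which(schedule$cs_type == cs)
    rg <- params$trials_retained[[cs]]
    n_keep <- min(length(idx), sample(seq(rg[1], rg[2]), 1L))
    sort(sample(idx, n_keep))
  })
  kept <- sort(unlist(kept))
  labels <- schedule$cs_type[kept]
  n_tr <- length(kept)

  # spatially mixed 1/f background
  noise <- noise_1f_matrix(n_samp, n_ch * n_tr, params$srate)
  noise <- aperm(array(noise, dim = c(n_samp, n_ch, n_tr)), c(2L, 1L, 3L))
  mix <- mixing_matrix(montage, params$mix_width_rad)
  dim(noise) <- c(n_ch, n_samp * n_tr)
  noise <- mix %*% noise
  noise <- noise * (params$noise_1f_amp / stats::sd(noise))
  dim(noise) <- c(n_ch, n_samp, n_tr)

  # occipital alpha topography (Gaussian falloff in angle from Oz)
  pos <- montage_positions(montage)
  oz <- pos[match("Oz", montage$label), ]
  ang <- acos(pmin(1, pmax(-1, drop(pos %*% oz))))
  topo <- exp(-ang^2 / (2 * params$topo_sd_rad^2))

  phases <- stats::runif(n_tr, 0, 2 * pi)
  carrier_arg <- 2 * pi * params$alpha_freq_hz * times / 1000
  data <- noise
  for (tr in seq_len(n_tr)) {
    env <- erd_envelope(times, depths[[labels[tr]]],
                        params$erd_onset_ms, params$ramp_ms)
    osc <- amp * env * sin(carrier_arg + phases[tr])
    data[, , tr] <- data[, , tr] + tcrossprod(topo, osc) + dc
  }

  epoch_array(data, params$srate, montage$label, labels, subject_id,
              t_start = params$t_start)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are `params$seed + subject index` (unless `seed`
#' overrides the master seed), so any individual subject can be regenerated
#' without the rest of the cohort. Each subject receives its own schedule
#' interleaving, baseline amplitude, effect jitter and retained-trial counts.
#'
#' @param params A [sim_params()] object (`n_subjects >= 2`).
#' @param montage A montage.
#' @param seed Optional master seed overriding `params$seed`.
#' @return A named list of [epoch_array()] objects (`sub01`, `sub02`, ...).
#' @export
simulate_cohort <- function(params, montage, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  master <- as.integer(seed %||% params$seed)
  ids <- sprintf("sub%02d", seq_len(params$n_subjects))
  out <- purrr::map(seq_len(params$n_subjects), function(i) {
    s <- derive_seed(master, i)
    sched <- generate_schedule("recall", seed = s)
    simulate_subject(sched, params, montage, seed = s, subject_id = ids[i])
  })
  stats::setNames(out, ids)
}

#' Simulate subject-level alpha-power timecourse cohorts
#'
#' Generates per-subject occipital alpha percent-change timecourses for the
#' CS+ and CS- contingency levels directly at the summary level that the
#' permutation stage consumes: temporally correlated noise (white noise
#' smoothed with a Gaussian kernel whose SD matches the 10 Hz wavelet's
#' temporal resolution) around a shared ERD mean, plus an optional injected
#' CS+/CS- difference confined to an effect window. With `effect = 0` the
#' two conditions are exchangeable within subject, giving exact null data
#' for family-wise-error studies at realistic sample autocorrelation.
#'
#' @param n_subjects Number of subjects.
#' @param n_samples Samples per series (1300 at the 500 Hz default epoch).
#' @param srate Sampling rate, Hz.
#' @param t_start Time of the first sample, ms.
#' @param noise_sd SD of the smoothed per-subject noise (percent-change
#'   units).
#' @param smooth_sd_ms Gaussian smoothing SD in ms (temporal autocorrelation
#'   scale; default matches sigma_t = 12 / (2 pi 10 Hz) ~ 191 ms).
#' @param effect Mean CS+ minus CS- difference (percent change) inside the
#'   effect window; 0 gives a null cohort.
#' @param effect_window_ms Window carrying the injected difference.
#' @param effect_ramp_ms Linear ramp length at the window edges.
#' @param subject_sd Between-subject SD of the injected effect.
#' @param seed Seed.
#' @return List with `times` (ms), `cs_plus` and `cs_minus`
#'   (subjects x samples matrices).
#' @export
simulate_timecourse_cohort <- function(n_subjects = 24, n_samples = 1300,
                                       srate = 500, t_start = -600,
                                       noise_sd = 15, smooth_sd_ms = 191,
                                       effect = 0,
                                       effect_window_ms = c(500, 1200),
                                       effect_ramp_ms = 100,
                                       subject_sd = abs(effect) / 3,
                                       seed = 1L) {
  local_rng(seed)
  times <- t_start + 1000 / srate * (0:(n_samples - 1))
  smooth_sd <- smooth_sd_ms * srate / 1000

  smooth <- function(m) {
    # FFT smoothing with a circular Gaussian kernel; variance renormalized
    k <- seq_len(n_samples) - 1L
    d <- pmin(k, n_samples - k)
    g <- exp(-d^2 / (2 * smooth_sd^2))
    g <- g / sum(g)
    gf <- Re(stats::fft(g))
    sm <- Re(stats::mvfft(stats::mvfft(m) * gf, inverse = TRUE)) / n_samples
    sm / sqrt(sum(g^2))
  }

  shape <- pmin(1, pmax(0, (times - effect_window_ms[1]) / effect_ramp_ms)) *
    pmin(1, pmax(0, (effect_window_ms[2] - times) / effect_ramp_ms))

  draw <- function() {
    t(smooth(matrix(stats::rnorm(n_samples * n_subjects), n_samples,
                    n_subjects))) * noise_sd
  }
  cs_plus <- draw()
  cs_minus <- draw()
  if (effect != 0 || subject_sd > 0) {
    eff_s <- stats::rnorm(n_subjects, effect, subject_sd)
    cs_plus <- cs_plus + outer(eff_s, shape)
  }
  list(times = times, cs_plus = cs_plus, cs_minus = cs_minus)
}
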