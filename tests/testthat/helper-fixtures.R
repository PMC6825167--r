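# shared fixtures, all generated in code

full_montage <- build_montage(64)
roi_montage <- subset_montage(full_montage, roi_channels())

# effect table with known structure: per-subject offsets plus cell effects
make_effect_table <- function(n, c_eff = 0, e_eff = 0, x_eff = 0,
                              sd_subject = 5, sd_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    g <- tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n)),
                            contingency = c("CS+", "CS-"),
                            extinction = c("E", "N"))
    subj <- stats::setNames(rnorm(n, 0, sd_subject),
                            sprintf("s%02d", seq_len(n)))
    g$alpha_pct <- subj[g$subject_id] +
      c_eff * (g$contingency == "CS+") +
      e_eff * (g$extinction == "E") +
      x_eff * (g$contingency == "CS+") * (g$extinction == "E") +
      rnorm(nrow(g), 0, sd_noise)
    g
  })
}

# small epoch array: pure sinusoid per channel with optional ERD envelope
make_tone_epochs <- function(montage, freq = 10, amp = 10, depth = 0,
                             n_trials = 2, srate = 500, t_start = -600,
                             n_samples = 1300, onset_ms = 500, ramp_ms = 200,
                             labels = NULL, seed = 1) {
  withr::with_seed(seed, {
    times <- t_start + 1000 / srate * (0:(n_samples - 1))
    env <- 1 - depth * pmin(1, pmax(0, (times - onset_ms) / ramp_ms))
    nch <- nrow(montage)
    x <- array(0, c(nch, n_samples, n_trials))
    for (tr in seq_len(n_trials)) {
      ph <- runif(1, 0, 2 * pi)
      osc <- amp * env * sin(2 * pi * freq * times / 1000 + ph)
      x[, , tr] <- matrix(osc, nch, n_samples, byrow = TRUE)
    }
    labels <- labels %||% rep("CS+E", n_trials)
    epoch_array(x, srate, montage$label, labels, "sub01", t_start = t_start)
  })
}

# raw tf_power object built directly (bypasses the wavelet) for testing the
# normalization arithmetic in isolation
make_flat_tf <- function(power_profile, freqs = c(9.5, 10.26), srate = 500,
                         n_samples = 1300, t_start = -600,
                         channels = roi_channels()) {
  times <- t_start + 1000 / srate * (0:(n_samples - 1))
  stopifnot(length(power_profile) == n_samples)
  p <- array(rep(power_profile, each = length(freqs)),
             c(length(freqs), n_samples, length(channels)))
  alphasupp:::new_tf_power(p, freqs, times, channels, srate, n_trials = 1,
                           edge = matrix(FALSE, length(freqs), n_samples),
                           subject_id = "sub01", label = "CS+E")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Jaccard overlap between detected windows and an injected interval
window_jaccard <- function(windows, lo, hi, step_ms = 2) {
  if (nrow(windows) == 0) return(0)
  len <- function(a, b) pmax(0, b - a + step_ms)
  inter <- sum(len(pmax(windows$start_ms, lo), pmin(windows$end_ms, hi)))
  union <- sum(len(windows$start_ms, windows$end_ms)) + len(lo, hi) - inter
  inter / union
}
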