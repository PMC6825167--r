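test_that("taper zeroes the epoch ends, leaves the interior unchanged, subtracts the baseline", {
  ep <- make_tone_epochs(roi_montage, n_trials = 2)
  ep$data <- ep$data + 4.2  # constant offset removed by baseline subtraction
  out <- taper_and_baseline(ep)
  expect_equal(out$data[, 1, ], matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(out$data[, 1300, ], matrix(0, 4, 2), ignore_attr = TRUE)
  # interior (beyond the 20-sample flanks) only shifted, not rescaled
  interior <- 21:1280
  base <- apply(ep$data[, ep$times >= -600 & ep$times <= -500, , drop = FALSE],
                c(1, 3), mean)
  expect_equal(out$data[, interior, ],
               sweep(ep$data[, interior, ], c(1, 3), base), tolerance = 1e-12)

  # constant signal: all-zero interior after subtraction
  cep <- epoch_array(array(7, c(4, 1300, 1)), 500, roi_montage$label,
                     "CS+E", "s1")
  expect_equal(max(abs(taper_and_baseline(cep)$data)), 0)
})

test_that("a 20-sample ramp at 500 Hz spans 40 ms", {
  srate <- 500
  expect_equal(20 / srate * 1000, 40)
  # and the taper flank indeed covers exactly the first 40 ms
  lin <- matrix(seq_len(1300), 4, 1300, byrow = TRUE)
  ep <- epoch_array(array(lin, c(4, 1300, 1)), srate, roi_montage$label,
                    "CS+E", "s1")
  out <- taper_and_baseline(ep, baseline_ms = c(1500, 1998))
  base <- mean(lin[1, ep$times >= 1500 & ep$times <= 1998])
  ratio <- out$data[1, 1:25, 1] / (lin[1, 1:25] - base)
  expect_equal(ratio[1], 0)
  expect_true(all(diff(ratio[1:20]) > 0))  # monotone rise over the flank
  expect_equal(ratio[21:25], rep(1, 5), tolerance = 1e-12)
  expect_equal(ep$times[21] - ep$times[1], 40)
})

test_that("baseline window outside the epoch fails", {
  ep <- make_tone_epochs(roi_montage)
  expect_error(taper_and_baseline(ep, baseline_ms = c(-900, -700)),
               "outside the epoch")
})

test_that("wavelet bank validates admissibility and uniform spacing", {
  expect_error(wavelet_bank(m = 4), "admissibility")
  expect_error(wavelet_bank(freqs = c(4, 5, 7)), "uniformly spaced")
  bank <- wavelet_bank()
  expect_equal(bank$freqs[1], 3.8)
  expect_equal(bank$step, 0.38)
  expect_equal(max(bank$freqs), 30.4)
})

test_that("spectral centre-to-SD ratio of the implemented wavelet is the Morlet parameter", {
  r10 <- wavelet_spectral_ratio(10, m = 12, srate = 500)
  expect_equal(unname(r10["ratio"]), 12, tolerance = 0.002)
  r6 <- wavelet_spectral_ratio(6.5, m = 8, srate = 500)
  expect_equal(unname(r6["ratio"]), 8, tolerance = 0.002)
})

test_that("stationary sinusoid gives a flat interior power profile at its own bin", {
  ep <- make_tone_epochs(roi_montage, freq = 10, n_trials = 1)
  tep <- taper_and_baseline(ep)
  tf <- morlet_power(tep, wavelet_bank(10, srate = 500))
  interior <- !tf$edge[1, ]
  p <- tf$power[1, interior, 1]
  expect_lt(stats::sd(p) / mean(p), 0.01)
})

test_that("wavelet longer than the epoch fails with the required length", {
  ep <- make_tone_epochs(roi_montage, n_samples = 200)
  expect_error(morlet_power(ep, wavelet_bank(3.8, srate = 500)),
               "at least")
})

test_that("white-noise power ratio between bins matches the wavelets' energy ratio", {
  # unit-energy wavelets: expected convolution power is equal across bins
  withr::with_seed(2, {
    x <- array(rnorm(2 * 4000 * 48), c(2, 4000, 48))
  })
  ep <- epoch_array(x, 500, c("Oz", "POz"), rep("CS+E", 48), "s1")
  bank <- wavelet_bank(c(6, 13, 20), srate = 500)
  tf <- morlet_power(ep, bank)
  interior <- !apply(tf$edge, 2, any)
  means <- apply(tf$power[, interior, , drop = FALSE], 1, mean)
  # wavelet-width autocorrelation limits the effective dof, so the MC
  # tolerance is a few percent even at 96 series
  expect_equal(means[2] / means[1], 1, tolerance = 0.08)
  expect_equal(means[3] / means[1], 1, tolerance = 0.08)
})

test_that("percent-change normalization identities hold", {
  # stationary power profile -> 0% everywhere
  tf <- make_flat_tf(rep(8, 1300))
  ntf <- baseline_normalize(tf)
  expect_equal(max(abs(ntf$power)), 0)
  # post-stimulus power at half the baseline level -> -50%
  times <- -600 + 2 * (0:1299)
  prof <- ifelse(times < 0, 8, 4)
  half <- baseline_normalize(make_flat_tf(prof))
  expect_equal(unique(as.vector(half$power[, times > 0, ])), -50)
  # invertibility via the stored baseline mean
  expect_equal(half$baseline_mean[1, 1], 8)
  restored <- (half$power / 100 + 1) * 8
  expect_equal(as.vector(restored[1, , 1]), prof)
  # double normalization and zero baselines rejected
  expect_error(baseline_normalize(half), "already normalized")
  expect_error(baseline_normalize(make_flat_tf(rep(0, 1300))),
               "Zero baseline")
})

test_that("amplitude-domain baseline option divides in the amplitude domain", {
  times <- -600 + 2 * (0:1299)
  prof <- ifelse(times < 0, 16, 4)  # amplitude halves: 4 -> 2
  ntf <- baseline_normalize(make_flat_tf(prof), mode = "amplitude")
  expect_equal(unique(as.vector(ntf$power[, times > 0, ])), -50)
})

test_that("half-amplitude ERD settles near -75% power on an edge-clean epoch", {
  ep <- make_tone_epochs(roi_montage, depth = 0.5, n_trials = 2,
                         t_start = -1500, n_samples = 2000)
  tep <- taper_and_baseline(ep, baseline_ms = c(-1500, -1400))
  ntf <- baseline_normalize(morlet_power(tep, wavelet_bank(10, srate = 500)))
  v <- alphasupp:::tf_mean(ntf, c(9, 11), roi_channels(), c(900, 1800),
                           warn_edge = FALSE)
  expect_equal(v, -75, tolerance = 0.01)
})

test_that("input amplitude scaling multiplies power by a^2 and leaves percent change fixed", {
  ep <- make_tone_epochs(roi_montage, depth = 0.4, n_trials = 2)
  tep <- taper_and_baseline(ep)
  ep2 <- ep
  ep2$data <- ep2$data * 3
  tep2 <- taper_and_baseline(ep2)
  bank <- wavelet_bank(10, srate = 500)
  tf1 <- morlet_power(tep, bank)
  tf2 <- morlet_power(tep2, bank)
  expect_equal(tf2$power, 9 * tf1$power, tolerance = 1e-10)
  n1 <- baseline_normalize(tf1)
  n2 <- baseline_normalize(tf2)
  expect_equal(n1$power, n2$power, tolerance = 1e-8)
})

test_that("alpha band selection snaps the stated band to the grid bins", {
  grid <- seq(3.8, 30.4, by = 0.38)
  bins <- alphasupp:::band_bins(grid, c(8.1, 11.9))
  expect_equal(length(bins), 11)
  expect_equal(grid[bins][1], 7.98)
  expect_equal(grid[bins][11], 11.78)
  expect_error(alphasupp:::band_bins(grid, c(31.5, 33)), "no bins")
})

test_that("the a priori window selects 351 samples on the canonical axis", {
  times <- -600 + 2 * (0:1299)
  expect_equal(sum(times >= 500 & times <= 1200), 351)
})

test_that("alpha_summary returns the plain mean and one row per design cell", {
  tf <- baseline_normalize(make_flat_tf(rep(8, 1300)))
  tf$power[] <- -30
  tf_by_cond <- stats::setNames(rep(list(tf), 4), cs_types_vec <- c(
    "CS+E", "CS+N", "CS-E", "CS-N"))
  tab <- alpha_summary(tf_by_cond, band_hz = c(9, 11),
                       window_ms = c(500, 1200))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$alpha_pct, rep(-30, 4))
  expect_setequal(paste0(tab$contingency, tab$extinction), cs_types_vec)
})

test_that("timecourse summary spans the full axis and is zero for identical conditions", {
  tf <- baseline_normalize(make_flat_tf(rep(8, 1300)))
  tf_by_cond <- stats::setNames(rep(list(tf), 4),
                                c("CS+E", "CS+N", "CS-E", "CS-N"))
  tc <- timecourse_summary(tf_by_cond, band_hz = c(9, 11))
  expect_equal(nrow(tc), 2 * 1300)
  d <- contingency_diffs(tc)
  expect_equal(dim(d), c(1, 1300))
  expect_equal(max(abs(d)), 0)
})

test_that("condition averaging precedes normalization (pinned order)", {
  # two trials with different stationary power: normalizing the pooled
  # average is not the average of separately normalized trials
  mon <- roi_montage
  e1 <- make_tone_epochs(mon, amp = 10, n_trials = 1, seed = 1)
  e2 <- make_tone_epochs(mon, amp = 2, n_trials = 1, seed = 2)
  both <- epoch_array(array(c(e1$data, e2$data), c(4, 1300, 2)), 500,
                      mon$label, c("CS+E", "CS+E"), "s1")
  bank <- wavelet_bank(10, srate = 500)
  tb <- function(e) taper_and_baseline(e)
  pooled <- baseline_normalize(morlet_power(tb(both), bank))
  sep <- (baseline_normalize(morlet_power(tb(e1), bank))$power +
            baseline_normalize(morlet_power(tb(e2), bank))$power) / 2
  pooled_direct <- (morlet_power(tb(e1), bank)$power +
                      morlet_power(tb(e2), bank)$power) / 2
  # implemented order equals normalize(mean power)
  manual <- 100 * (sweep(pooled_direct, c(1, 3),
                         apply(pooled_direct[, both$times >= -400 &
                                               both$times <= -200, ,
                                             drop = FALSE], c(1, 3), mean),
                         `/`) - 1)
  expect_equal(pooled$power, manual, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pooled$power, sep, tolerance = 1e-4)))
})

test_that("raw power is non-negative and pooled power is the trial-weighted mean", {
  ep <- make_tone_epochs(roi_montage, n_trials = 3)
  tep <- taper_and_baseline(ep)
  bank <- wavelet_bank(10, srate = 500)
  tf_all <- morlet_power(tep, bank)
  expect_true(all(tf_all$power >= 0))
  tf_a <- morlet_power(subset_epochs(tep, trials = 1:2), bank)
  tf_b <- morlet_power(subset_epochs(tep, trials = 3), bank)
  pooled <- pool_power(list(tf_a, tf_b))
  expect_equal(pooled$power, tf_all$power, tolerance = 1e-12)
  expect_equal(pooled$n_trials, 3)
})

test_that("tf_power serialization round-trips and difference maps are tidy", {
  ep <- make_tone_epochs(roi_montage, n_trials = 2, n_samples = 1300)
  tep <- taper_and_baseline(ep)
  tf <- baseline_normalize(morlet_power(tep, wavelet_bank(c(9, 10, 11),
                                                          srate = 500)))
  path <- withr::local_tempfile(fileext = ".f64")
  write_tf_power(tf, path)
  back <- read_tf_power(path)
  expect_identical(back$power, tf$power)
  expect_equal(back$freqs, tf$freqs)
  expect_equal(back$edge, tf$edge, ignore_attr = TRUE)
  expect_equal(back$baseline_mean, tf$baseline_mean, ignore_attr = TRUE)
  expect_true(back$normalized)

  d <- tf_difference_long(tf, back)
  expect_equal(nrow(d), 3 * 1300 * 4)
  expect_equal(max(abs(d$value)), 0)
  # orientation: value[i] corresponds to power[freq, time, channel]
  tf2 <- tf
  tf2$power[2, 5, 3] <- tf2$power[2, 5, 3] + 1
  d2 <- tf_difference_long(tf2, tf)
  hit <- d2[d2$value != 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$freq_hz, tf$freqs[2])
  expect_equal(hit$time_ms, tf$times[5])
  expect_equal(hit$channel, tf$channels[3])
})
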