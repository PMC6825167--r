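#' Per-sample paired t statistics
#'
#' One-sample t of the subject difference series (both CS+ averaged minus
#' both CS- averaged) at every time sample: `t = mean / (sd / sqrt(n))`
#' columnwise. Zero-variance samples yield non-finite values (0 when the
#' mean is also zero) rather than an error; they are flagged downstream.
#'
#' @param diffs Subjects x time numeric matrix of difference series.
#' @return Numeric vector of t values, one per time sample.
#' @export
samplewise_t <- function(diffs) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2L) stop("Need at least 2 subjects", call. = FALSE)
  if (anyNA(diffs)) stop("Missing samples in difference series", call. = FALSE)
  m <- colMeans(diffs)
  v <- (colSums(diffs^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative rounding
  t <- m / sqrt(v / n)
  t[m == 0 & v == 0] <- 0
  t
}

# t statistics for many sign-flip patterns at once: rows of `signs` are
# +-1 patterns over subjects. Sign flips leave each subject's squared
# values unchanged, so the per-sample sum of squares is shared.
signflip_t_matrix <- function(diffs, signs) {
  n <- nrow(diffs)
  m <- (signs %*% diffs) / n                       # n_perm x time means
  ss <- colSums(diffs^2)
  v <- sweep(-n * m^2, 2, ss, `+`) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[m == 0 & v == 0] <- 0
  t
}

row_extrema <- function(tm) {
  fin <- is.finite(tm)
  if (!all(fin)) {
    warning("Non-finite t values (zero-variance samples) excluded from ",
            "permutation extrema", call. = FALSE)
    tm[!fin] <- NA_real_
  }
  safe_ext <- function(f) function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else f(x)
  }
  list(tmin = apply(tm, 1, safe_ext(min)),
       tmax = apply(tm, 1, safe_ext(max)))
}

#' Sign-flip permutation null distributions of the t extrema
#'
#' Randomly re-labels the CS+/CS- conditions within each subject — for a
#' paired design this is an independent sign flip of each subject's whole
#' difference series — recomputes the per-sample t statistics, and stores
#' each permutation's minimum and maximum t across samples. The resulting
#' tmin/tmax distributions control the family-wise error over all samples.
#'
#' @param diffs Subjects x time difference matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed; distributions are reproducible given the seed.
#' @param include_identity If `TRUE`, the observed (unflipped) labeling is
#'   forced into the null as the first permutation (default `FALSE`).
#' @return A list with numeric vectors `tmin` and `tmax` of length `n_perm`.
#' @export
tmax_null <- function(diffs, n_perm = 1000L, seed = 1L,
                      include_identity = FALSE) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 1L) stop("Need at least 1 subject", call. = FALSE)
  stopifnot(n_perm >= 1L)
  local_rng(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  if (include_identity) signs[1L, ] <- 1
  row_extrema(signflip_t_matrix(diffs, signs))
}

#' Critical t values from the permutation null
#'
#' The lower critical value is the `alpha/2` percentile of the tmin
#' distribution and the upper the `1 - alpha/2` percentile of the tmax
#' distribution (linear-interpolation percentiles, `stats::quantile`
#' type 7).
#'
#' @param null A list with `tmin` and `tmax` (from [tmax_null()] or
#'   [exhaustive_signflip_oracle()]).
#' @param alpha Two-sided family-wise level (default 0.05).
#' @return Named numeric `c(t_crit_low, t_crit_high)`.
#' @export
critical_values <- function(null, alpha = 0.05) {
  stopifnot(length(null$tmin) >= 1, length(null$tmax) >= 1)
  c(t_crit_low = unname(stats::quantile(null$tmin, alpha / 2, names = FALSE,
                                        type = 7)),
    t_crit_high = unname(stats::quantile(null$tmax, 1 - alpha / 2,
                                         names = FALSE, type = 7)))
}

#' Maximal contiguous significant windows
#'
#' Samples with `t < t_crit_low` or `t > t_crit_high` are flagged; maximal
#' contiguous runs of flagged samples are reported in ms with inclusive
#' endpoints.
#'
#' @param t_series Observed per-sample t values.
#' @param crits Named numeric with `t_crit_low` and `t_crit_high`.
#' @param times Time axis in ms (same length as `t_series`).
#' @return A list with `sig_mask` (logical per sample) and `windows`
#'   (tibble: `start_ms`, `end_ms`, `n_samples`).
#' @export
significant_windows <- function(t_series, crits, times) {
  stopifnot(length(t_series) == length(times))
  mask <- is.finite(t_series) &
    (t_series < crits[["t_crit_low"]] | t_series > crits[["t_crit_high"]])
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  windows <- tibble::tibble(start_ms = times[starts[keep]],
                            end_ms = times[ends[keep]],
                            n_samples = runs$lengths[keep])
  list(sig_mask = mask, windows = windows)
}

#' Exhaustive sign-flip null (test oracle)
#'
#' Enumerates all `2^n` sign patterns over subjects and returns the exact
#' tmin/tmax null distributions. Intended as an independent oracle for
#' [tmax_null()] at small n.
#'
#' @param diffs Subjects x time difference matrix, at most 20 subjects.
#' @return A list with `tmin` and `tmax` of length `2^n`.
#' @export
exhaustive_signflip_oracle <- function(diffs) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n > 20L) stop("Exhaustive enumeration limited to n <= 20 subjects",
                    call. = FALSE)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  row_extrema(signflip_t_matrix(diffs, patterns))
}

#' Full per-sample permutation test
#'
#' Runs [samplewise_t()], [tmax_null()], [critical_values()] and
#' [significant_windows()] on a subjects x time difference matrix. The
#' observed t series is deterministic; only the null distributions depend on
#' the seed.
#'
#' @inheritParams tmax_null
#' @param times Time axis in ms.
#' @param alpha Family-wise two-sided level.
#' @return An object of class `"perm_result"`: list with `t_series`,
#'   `t_crit_low`, `t_crit_high`, `sig_mask`, `windows`, `null`, `n_perm`,
#'   `alpha`, `seed`, `times`, `n_subjects`.
#' @export
permutation_test <- function(diffs, times, n_perm = 1000L, alpha = 0.05,
                             seed = 1L, include_identity = FALSE) {
  diffs <- as.matrix(diffs)
  stopifnot(ncol(diffs) == length(times))
  t_obs <- samplewise_t(diffs)
  null <- tmax_null(diffs, n_perm = n_perm, seed = seed,
                    include_identity = include_identity)
  crits <- critical_values(null, alpha = alpha)
  sw <- significant_windows(t_obs, crits, times)
  structure(list(t_series = t_obs,
                 t_crit_low = crits[["t_crit_low"]],
                 t_crit_high = crits[["t_crit_high"]],
                 sig_mask = sw$sig_mask, windows = sw$windows,
                 null = null, n_perm = n_perm, alpha = alpha, seed = seed,
                 times = times, n_subjects = nrow(diffs)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Per-sample tmax/tmin permutation test: n =", x$n_subjects,
      "subjects,", length(x$times), "samples,", x$n_perm, "permutations\n")
  cat(sprintf("  t_crit: low %.3f, high %.3f (alpha = %g, two-sided)\n",
              x$t_crit_low, x$t_crit_high, x$alpha))
  if (nrow(x$windows) == 0) {
    cat("  no significant windows\n")
  } else {
    apply(x$windows, 1, function(w)
      cat(sprintf("  significant window: %g to %g ms (%d samples)\n",
                  w[["start_ms"]], w[["end_ms"]], w[["n_samples"]])))
  }
  invisible(x)
}

#' Subject-by-time difference matrix from tidy timecourses
#'
#' @param timecourses Tibble from [timecourse_summary()] rows bound over
#'   subjects (columns `subject_id`, `contingency`, `time_ms`, `alpha_pct`).
#' @return Subjects x time matrix of CS+ minus CS- series, with the time
#'   axis in `attr(, "times")`.
#' @export
contingency_diffs <- function(timecourses) {
  wide <- tidyr::pivot_wider(timecourses, names_from = "contingency",
                             values_from = "alpha_pct")
  d <- dplyr::mutate(wide, diff = .data[["CS+"]] - .data[["CS-"]])
  times <- sort(unique(d$time_ms))
  subjects <- unique(d$subject_id)
  out <- matrix(NA_real_, length(subjects), length(times),
                dimnames = list(subjects, NULL))
  out[cbind(match(d$subject_id, subjects), match(d$time_ms, times))] <- d$diff
  if (anyNA(out)) stop("Missing time samples for some subjects", call. = FALSE)
  attr(out, "times") <- times
  out
}
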