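#' Electrode montages
#'
#' A montage is a tibble with one row per electrode: a unique `label` and
#' unit-sphere coordinates `x`, `y`, `z` (idealized spherical head, radius 1).
#' All spherical-spline computations (see [csd_basis()]) and the simulated
#' alpha topography use the angular distances implied by these positions.
#'
#' @name montage
NULL

#' Build a standard montage
#'
#' Returns standard 10-10 electrode positions on the unit sphere from the
#' packaged layout file. The 64-channel layout corresponds to a standard
#' actiCAP arrangement and always contains the occipital region-of-interest
#' channels `Oz`, `POz`, `O1` and `O2`.
#'
#' @param n_channels Number of channels; currently the packaged layouts are
#'   64 (full cap) and any subset size >= 4 obtained with [subset_montage()].
#' @return A tibble with columns `label`, `x`, `y`, `z`; class `"montage"`.
#' @examples
#' mon <- build_montage(64)
#' nrow(mon)
#' @export
build_montage <- function(n_channels = 64) {
  supported <- c(64L)
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      !(as.integer(n_channels) %in% supported)) {
    stop("Unknown channel count ", n_channels,
         "; supported layouts: ", paste(supported, collapse = ", "),
         ". Use subset_montage() to derive smaller montages.", call. = FALSE)
  }
  path <- system.file("extdata", "montage64.csv", package = "alphasupp",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mon <- tibble::as_tibble(raw)
  class(mon) <- c("montage", class(mon))
  validate_montage(mon)
  mon
}

#' Subset a montage to named channels
#'
#' @param montage A montage tibble.
#' @param labels Channel labels to keep (order preserved as given).
#' @param require_roi If `TRUE` (default) the result must still contain the
#'   occipital ROI channels Oz, POz, O1, O2.
#' @return A montage tibble.
#' @export
subset_montage <- function(montage, labels, require_roi = TRUE) {
  validate_montage(montage, require_roi = FALSE)
  missing <- setdiff(labels, montage$label)
  if (length(missing) > 0L) {
    stop("Channels not in montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- montage[match(labels, montage$label), , drop = FALSE]
  class(out) <- c("montage", setdiff(class(out), "montage"))
  validate_montage(out, require_roi = require_roi)
  out
}

#' Occipital region-of-interest channels
#'
#' The four occipital/parieto-occipital electrodes over which alpha power is
#' averaged.
#' @return Character vector `c("Oz", "POz", "O1", "O2")`.
#' @export
roi_channels <- function() c("Oz", "POz", "O1", "O2")

validate_montage <- function(montage, require_roi = TRUE) {
  stopifnot(is.data.frame(montage),
            all(c("label", "x", "y", "z") %in% names(montage)))
  if (nrow(montage) < 4L) {
    stop("A montage needs at least 4 channels (the occipital ROI alone has 4); ",
         "got ", nrow(montage), call. = FALSE)
  }
  if (anyDuplicated(montage$label)) {
    stop("Montage labels must be unique", call. = FALSE)
  }
  norms <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(norms - 1) > 1e-9)) {
    stop("Montage positions must lie on the unit sphere (|norm - 1| <= 1e-9)",
         call. = FALSE)
  }
  if (require_roi && !all(roi_channels() %in% montage$label)) {
    stop("Montage must contain the ROI channels ",
         paste(roi_channels(), collapse = ", "), call. = FALSE)
  }
  invisible(montage)
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

# pairwise angular distance (radians) between electrodes
montage_angles <- function(montage) {
  pos <- montage_positions(montage)
  cosang <- tcrossprod(pos)
  cosang <- pmin(pmax(cosang, -1), 1)
  acos(cosang)
}
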