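#' Spherical-spline surface Laplacian (current source density)
#'
#' The scalp potential is interpolated with spherical splines and its surface
#' Laplacian evaluated analytically at the electrode sites, yielding a
#' reference-free, spatially sharpened current-source-density (CSD) estimate.
#' Two kernels are built from the Legendre polynomial series over electrode
#' pairs (cos theta = dot product of unit-sphere positions):
#'
#' \deqn{g(x) = \frac{1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^m} P_n(x)}
#' \deqn{h(x) = \frac{1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^{m-1}} P_n(x)}
#'
#' with spline order `m` (default 4), maximum series degree `N` (default 10)
#' and Tikhonov regularization `lambda` (default 1e-5) added to the diagonal
#' of G only. The spline coefficients solve the augmented system with a
#' zero-sum constraint and a free constant term; the output is `H c / r^2`,
#' the negative surface Laplacian of the interpolated potential
#' (CSD-positive = current source).
#'
#' @name csd
NULL

#' CSD parameters
#'
#' @param m Spline order (stiffness exponent), integer >= 2. Default 4.
#' @param n_legendre Maximum degree of the Legendre series. Default 10.
#' @param lambda Regularization added to the diagonal of G. Default 1e-5.
#' @param head_radius Sphere radius; output scales as `head_radius^-2`.
#'   Default 1 (unitless output; percent-change endpoints cancel the scale).
#' @return A list of class `"csd_params"`.
#' @export
csd_params <- function(m = 4L, n_legendre = 10L, lambda = 1e-5,
                       head_radius = 1) {
  stopifnot(m >= 2, n_legendre >= 1, lambda >= 0, head_radius > 0)
  structure(list(m = as.integer(m), n_legendre = as.integer(n_legendre),
                 lambda = lambda, head_radius = head_radius),
            class = "csd_params")
}

# Legendre polynomials P_1..P_n at x (vector), via Bonnet recurrence.
# Returns a length(x) x n matrix.
legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  out[, 1] <- p_cur
  if (n >= 2) {
    for (k in 2:n) {
      p_next <- ((2 * k - 1) * x * p_cur - (k - 1) * p_prev) / k
      out[, k] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# evaluate the g (deriv = 0) or h (deriv = 1) series at cosine values
csd_kernel <- function(cosang, m, n_legendre, deriv = 0L) {
  n <- seq_len(n_legendre)
  denom <- (n * (n + 1))^(m - deriv)
  w <- (2 * n + 1) / denom / (4 * pi)
  p <- legendre_table(as.vector(cosang), n_legendre)
  out <- drop(p %*% w)
  if (is.matrix(cosang)) dim(out) <- dim(cosang)
  out
}

#' Build the spherical-spline basis for a montage
#'
#' @param montage A montage (unit-sphere positions, >= 4 channels).
#' @param params A [csd_params()] object.
#' @return A list of class `"csd_basis"` with symmetric matrices `G` and `H`,
#'   the precomputed CSD transform matrix, and the montage.
#' @export
csd_basis <- function(montage, params = csd_params()) {
  validate_montage(montage, require_roi = FALSE)
  stopifnot(inherits(params, "csd_params"))
  pos <- montage_positions(montage)
  cosang <- pmin(pmax(tcrossprod(pos), -1), 1)
  dup <- which(cosang > 1 - 1e-12 & row(cosang) < col(cosang), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    pairs <- apply(dup, 1L, function(ij)
      paste(montage$label[ij[1]], montage$label[ij[2]], sep = "/"))
    stop("Coincident electrode positions (singular spline system): ",
         paste(pairs, collapse = ", "), call. = FALSE)
  }
  G <- csd_kernel(cosang, params$m, params$n_legendre, deriv = 0L)
  H <- csd_kernel(cosang, params$m, params$n_legendre, deriv = 1L)

  # augmented system: [G + lambda I, 1; 1', 0] [c; c0] = [v; 0]
  n <- nrow(G)
  A <- rbind(cbind(G + diag(params$lambda, n), rep(1, n)),
             c(rep(1, n), 0))
  Ainv <- solve(A)
  # v -> c is the top-left n x n block of Ainv; CSD = H c / r^2
  transform <- (H %*% Ainv[seq_len(n), seq_len(n)]) / params$head_radius^2

  structure(list(G = G, H = H, transform = transform,
                 montage = montage, params = params),
            class = "csd_basis")
}

#' Apply the surface-Laplacian transform to epoched EEG
#'
#' Linear, reference-free: adding any signal that is constant across
#' channels (at each time point) leaves the output unchanged, and the output
#' of a spatially constant input is zero.
#'
#' @param epochs An [epoch_array()] whose channels match the basis montage.
#' @param basis A [csd_basis()].
#' @return An [epoch_array()] of CSD values with the same shape and axes.
#' @export
csd_transform <- function(epochs, basis) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(basis, "csd_basis"))
  if (!identical(epochs$channels, basis$montage$label)) {
    extra <- setdiff(epochs$channels, basis$montage$label)
    missing <- setdiff(basis$montage$label, epochs$channels)
    stop("Channel sets differ between epochs and CSD basis.",
         if (length(extra)) paste0(" Not in basis: ",
                                   paste(extra, collapse = ", "), "."),
         if (length(missing)) paste0(" Missing from epochs: ",
                                     paste(missing, collapse = ", "), "."),
         if (!length(extra) && !length(missing)) " Channel order differs.",
         call. = FALSE)
  }
  d <- dim(epochs$data)
  x <- epochs$data
  dim(x) <- c(d[1], d[2] * d[3])
  out <- basis$transform %*% x
  dim(out) <- d
  epoch_array(out, epochs$srate, epochs$channels, epochs$trial_labels,
              epochs$subject_id, t_start = epochs$times[1])
}
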