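#' Acquisition pose
#'
#' A pose pairs the optical axis \eqn{\hat n} (direction of projection
#' through the sample) with the interferometer sensitivity axis \eqn{\hat e}
#' (perpendicular to the grating bars), both unit vectors in the sample
#' frame with \eqn{\hat n \perp \hat e}.
#'
#' @param n_hat unit 3-vector, optical axis.
#' @param e_hat unit 3-vector, sensitivity axis, orthogonal to \code{n_hat}.
#' @param tol orthonormality tolerance.
#' @return A list of class \code{df_pose} with components \code{n} and
#'   \code{e}.
#' @export
pose <- function(n_hat, e_hat, tol = 1e-10) {
  n_hat <- as.numeric(n_hat); e_hat <- as.numeric(e_hat)
  stopifnot(length(n_hat) == 3L, length(e_hat) == 3L)
  if (abs(sum(n_hat^2) - 1) > tol || abs(sum(e_hat^2) - 1) > tol ||
      abs(sum(n_hat * e_hat)) > tol)
    stop("pose vectors must be orthonormal unit vectors")
  structure(list(n = n_hat, e = e_hat), class = "df_pose")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Express a tensor in the instrument frame of a pose
#'
#' The forward model is stated in the grating interferometer's coordinate
#' system, in which \eqn{\hat e} is the x-axis and \eqn{\hat n} the z-axis
#' (y completes the right-handed basis as \eqn{\hat n \times \hat e}).
#' For an arbitrary pose the tensor is rotated into that frame before
#' evaluating the signal: \eqn{T' = B^T T B} with
#' \eqn{B = [\hat e, \hat n \times \hat e, \hat n]}.
#'
#' @param tens symmetric 3x3 mass-distribution tensor in the sample frame.
#' @param p a \code{\link{pose}}.
#' @return The tensor in instrument coordinates (same eigenvalues).
#' @export
instrument_frame_tensor <- function(tens, p) {
  if (!inherits(p, "df_pose")) p <- pose(p$n, p$e)
  B <- cbind(p$e, cross3(p$n, p$e), p$n)
  t(B) %*% tens %*% B
}

#' Dark-field extinction signal of an anisotropic volume element
#'
#' Evaluates the nonlinear physical model of dark-field orientation
#' dependence for a Gaussian mass distribution with precision tensor
#' \eqn{T}: in instrument coordinates
#' \deqn{\mu_{DF} = \frac{1}{\sqrt{T'_{zz}}}\left(T'_{xx} -
#'   \frac{T_{xz}'^2}{T'_{zz}}\right),}
#' where the prefactor \eqn{T_{zz}'^{-1/2}} is the structure's extent along
#' the optical axis (leading order of the scattering cross section) and the
#' bracket is the precision of the projected density along the sensitivity
#' axis (auto-correlation term, a Schur complement of the z block). The
#' global proportionality constant is fixed at 1; only the orientation
#' dependence is modelled.
#'
#' @param tens symmetric positive-(semi)definite 3x3 tensor, sample frame.
#' @param p a \code{\link{pose}}.
#' @return Non-negative scalar extinction coefficient.
#' @export
#' @examples
#' p <- pose(c(0, 0, 1), c(1, 0, 0))
#' darkfield_signal(diag(3) / 3, p)  # isotropic: 1/sqrt(3)
darkfield_signal <- function(tens, p) {
  tp <- instrument_frame_tensor(tens, p)
  if (tp[3L, 3L] <= 0)
    stop("degenerate input: non-positive variance along the optical axis")
  (tp[1L, 1L] - tp[1L, 3L]^2 / tp[3L, 3L]) / sqrt(tp[3L, 3L])
}

#' Decompose the dark-field signal into its two orientation factors
#'
#' Splits the signal into the cross-section factor \eqn{T_{zz}'^{-1/2}}
#' (extent along the optical axis) and the correlation factor
#' \eqn{T'_{xx} - T_{xz}'^2 / T'_{zz}} (inverse variance of the projected
#' density along the sensitivity axis). Their product is the signal, and the
#' two factors isolate the limiting cases of constant cross section versus
#' constant auto-correlation width.
#'
#' @inheritParams darkfield_signal
#' @return Named numeric vector \code{c(cross_section, correlation)}.
#' @export
signal_factors <- function(tens, p) {
  tp <- instrument_frame_tensor(tens, p)
  if (tp[3L, 3L] <= 0)
    stop("degenerate input: non-positive variance along the optical axis")
  c(cross_section = 1 / sqrt(tp[3L, 3L]),
    correlation = tp[1L, 1L] - tp[1L, 3L]^2 / tp[3L, 3L])
}

#' Synthesize signals for a whole acquisition geometry
#'
#' Vectorized evaluation of \code{\link{darkfield_signal}} over every pose of
#' an \code{\link{full_geometry}}-style geometry, using the quadratic-form
#' identities \eqn{T'_{xx} = \hat e^T T \hat e}, \eqn{T'_{zz} = \hat n^T T
#' \hat n}, \eqn{T'_{xz} = \hat e^T T \hat n}.
#'
#' @param tens symmetric 3x3 tensor.
#' @param geom a geometry with pose matrices \code{n} and \code{e}.
#' @return Numeric vector of one extinction value per pose.
#' @export
darkfield_signals <- function(tens, geom) {
  N <- geom$n; E <- geom$e
  tnn <- rowSums((N %*% tens) * N)
  tee <- rowSums((E %*% tens) * E)
  ten <- rowSums((E %*% tens) * N)
  if (any(tnn <= 0))
    stop("degenerate input: non-positive variance along the optical axis")
  (tee - ten^2 / tnn) / sqrt(tnn)
}
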