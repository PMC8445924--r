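#' Normalized root-mean-square error
#'
#' Root of the mean squared residual between data and model prediction,
#' normalized by the mean of the data, putting deviations in relation to the
#' approximated signal.
#'
#' @param data numeric vector of observed signals.
#' @param model_pred numeric vector of model predictions, same length.
#' @return Non-negative scalar (fraction; 0.2 means 20\%).
#' @export
nrmse <- function(data, model_pred) {
  stopifnot(length(data) == length(model_pred), length(data) > 0L)
  m <- mean(data)
  if (m <= 0) stop("invalid normalization: mean(data) must be positive")
  sqrt(mean((data - model_pred)^2)) / m
}

#' Angular deviation between two axes
#'
#' \eqn{\Delta\theta = \arccos |\hat v_1 \cdot \hat v_2|} in degrees, the
#' acute angle between undirected axes; invariant to the sign of either
#' vector, hence to the eigenvector sign convention.
#'
#' @param v_ref,v_est unit 3-vectors.
#' @return Angle in degrees, in [0, 90].
#' @export
angular_error <- function(v_ref, v_est) {
  v_ref <- as.numeric(v_ref); v_est <- as.numeric(v_est)
  stopifnot(length(v_ref) == 3L, length(v_est) == 3L)
  d <- abs(sum(v_ref * v_est))
  if (d > 1 + 1e-9) stop("inputs are not unit vectors: |dot| > 1")
  acos(min(d, 1)) * 180 / pi
}

#' Width parameter of an inclination-angle error distribution
#'
#' A normal distribution of inclination angles, integrated over the
#' azimuth, has density \eqn{\propto \sin(\Delta\theta)
#' \exp(-\Delta\theta^2 / 2\sigma^2) \approx \Delta\theta
#' \exp(-\Delta\theta^2 / 2\sigma^2)} for small angles, whose maximum lies
#' exactly at \eqn{\Delta\theta = \sigma}. The width is therefore estimated
#' as the location of the empirical mode: a histogram with
#' Freedman-Diaconis bin width \eqn{2\,\mathrm{IQR}\,n^{-1/3}} is formed
#' over [0, max], the counts are locally averaged over 5 bins (the density
#' is flat at its maximum, so neighbouring bins differ only by sampling
#' noise), and the center of the tallest averaged bin is returned
#' (\code{method = "mode"}). As a cross-check, \code{method = "fit"}
#' fits the small-angle density to the histogram up to and including the
#' peak bin (the empirical distributions follow the model only up to their
#' maximum) by profiled least squares on the bin counts.
#'
#' @param angles_deg angular errors in degrees, in [0, 90].
#' @param method \code{"mode"} (default) or \code{"fit"}.
#' @return Estimated \eqn{\sigma_{\Delta\theta}} in degrees.
#' @export
fit_sigma_theta <- function(angles_deg, method = c("mode", "fit")) {
  method <- match.arg(method)
  angles_deg <- as.numeric(angles_deg)
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (length(angles_deg) == 0L) stop("empty angle list")
  h <- sigma_histogram(angles_deg)
  if (is.null(h)) return(angles_deg[1L])  # point mass
  peak <- which.max(h$smoothed)
  mode_est <- h$mids[peak]
  if (method == "mode") return(mode_est)
  # profiled LS fit of c * theta * exp(-theta^2 / (2 s^2)) up to the peak bin
  th <- h$mids[seq_len(peak)]
  ct <- h$counts[seq_len(peak)]
  obj <- function(s) {
    f <- th * exp(-th^2 / (2 * s^2))
    cc <- sum(ct * f) / sum(f^2)
    sum((ct - cc * f)^2)
  }
  stats::optimize(obj, lower = h$width / 10, upper = 90)$minimum
}

# Freedman-Diaconis histogram over [0, max]; NULL for a point mass.
# `smoothed` holds a 5-bin centered moving average of the counts (partial
# windows at the edges): adjacent bins near a flat density maximum differ
# only by sampling noise, and peak-picking on the averaged counts suppresses
# the resulting bin-to-bin wander of the mode without shifting it.
sigma_histogram <- function(x) {
  n <- length(x)
  if (diff(range(x)) == 0) return(NULL)
  width <- 2 * stats::IQR(x) * n^(-1 / 3)
  if (!is.finite(width) || width <= 0)  # fall back on a sqrt-n rule
    width <- diff(range(x)) / max(1, ceiling(sqrt(n)))
  breaks <- seq(0, max(x) + width, by = width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  nb <- length(counts)
  half <- 2L
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(nb) - half, 1L)
  hi <- pmin(seq_len(nb) + half, nb)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  list(breaks = breaks, counts = counts, smoothed = smoothed,
       mids = (breaks[-1L] + breaks[-length(breaks)]) / 2, width = width)
}

#' Pair the normalized eigenspectra of ground truth and surrogate
#'
#' Eigenvalues of each tensor are sorted ascending and normalized by their
#' sum (trace). For the optical-axis surrogate N the sorted order is
#' reversed before pairing, reflecting its anti-correlation with the
#' ground-truth spectrum (large N eigenvalues correspond to long structural
#' axes); the sensitivity-axis surrogate E pairs in like order.
#'
#' @param tens ground-truth symmetric 3x3 tensor.
#' @param surrogate reconstructed symmetric 3x3 tensor.
#' @param model \code{"E"} or \code{"N"}.
#' @param trace_tol surrogate spectra whose trace magnitude falls below
#'   \code{trace_tol} times the largest eigenvalue magnitude cannot be
#'   normalized; such records are returned flagged with NA pairs.
#' @return A 3x2 matrix of (truth, surrogate) normalized eigenvalue pairs,
#'   with logical attribute \code{flagged}.
#' @export
compare_spectra <- function(tens, surrogate, model = c("E", "N"),
                            trace_tol = 1e-6) {
  model <- match.arg(model)
  ev_t <- sort(eigen(tens, symmetric = TRUE, only.values = TRUE)$values)
  ev_u <- sort(eigen(surrogate, symmetric = TRUE, only.values = TRUE)$values)
  st <- sum(ev_t); su <- sum(ev_u)
  if (abs(st) <= 1e-12 || abs(su) <= trace_tol * max(abs(ev_u))) {
    out <- matrix(NA_real_, nrow = 3L, ncol = 2L)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  ev_t <- ev_t / st
  ev_u <- ev_u / su
  if (model == "N") ev_u <- rev(ev_u)
  out <- cbind(truth = ev_t, surrogate = ev_u)
  attr(out, "flagged") <- FALSE
  out
}

#' Mean-eigenvalue versus mean-signal pair
#'
#' The zeroth order of the linear model: averaged over directions whose
#' second-moment matrix is isotropic, \eqn{E[\hat r^T U \hat r] =
#' \mathrm{trace}(U)/3}, so the surrogate's mean eigenvalue should
#' reproduce the mean observed dark-field signal. Returns the pair for
#' ensemble-level scatter/regression; no thresholding here.
#'
#' @param surrogate reconstructed symmetric 3x3 tensor.
#' @param signals the signals it was reconstructed from.
#' @return Named numeric \code{c(mean_eigenvalue, mean_signal)}.
#' @export
mean_signal_check <- function(surrogate, signals) {
  if (length(signals) == 0L) stop("empty signal list")
  c(mean_eigenvalue = sum(diag(surrogate)) / 3,
    mean_signal = mean(signals))
}
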