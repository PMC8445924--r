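#' Circular acquisition trajectory about an axis
#'
#' Models one mounting orientation of a sample on a tomographic rotation
#' stage: the optical axis \eqn{\hat n} orbits the given rotation axis on a
#' great circle (pointing towards the center) and the interferometer
#' sensitivity axis \eqn{\hat e} is tangential to the orbit,
#' \eqn{\hat e = a \times \hat n}. The in-plane reference direction is the
#' coordinate axis least aligned with the trajectory axis (projected and
#' normalized), and sampling starts at phase 0 with spacing
#' \eqn{2\pi/n} over the full circle (no duplicated endpoint).
#'
#' @param axis unit 3-vector rotation axis.
#' @param n_samples number of equidistant poses on the circle (>= 1).
#' @return A list of class \code{df_trajectory} with \code{axis} and pose
#'   matrices \code{n}, \code{e} (\code{n_samples} x 3).
#' @export
trajectory <- function(axis, n_samples = 29L) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("'axis' must be a nonzero vector")
  axis <- axis / nrm
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  ref <- diag(3)[, which.min(abs(axis))]
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  theta <- 2 * pi * (seq_len(n_samples) - 1L) / n_samples
  nhat <- -(outer(cos(theta), u) + outer(sin(theta), v))
  ehat <- t(apply(nhat, 1L, function(nh) cross3(axis, nh)))
  structure(list(axis = axis, n = nhat, e = ehat), class = "df_trajectory")
}

geometry_axes <- function(which = c("full", "orthogonal")) {
  which <- match.arg(which)
  coord <- diag(3)
  if (which == "orthogonal") return(coord)
  face <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  space <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)) / sqrt(3)
  rbind(coord, face, space)
}

build_geometry <- function(axes, n_samples) {
  trajs <- lapply(seq_len(nrow(axes)),
                  function(i) trajectory(axes[i, ], n_samples))
  structure(list(
    n = do.call(rbind, lapply(trajs, `[[`, "n")),
    e = do.call(rbind, lapply(trajs, `[[`, "e")),
    trajectory_id = rep(seq_len(nrow(axes)), each = n_samples),
    axes = axes
  ), class = "df_geometry")
}

#' Full 13-trajectory acquisition geometry
#'
#' Concatenates circular trajectories about the 3 coordinate axes, the 6
#' face diagonals and the 4 space diagonals of the coordinate cube (one
#' representative per antipodal pair), each sampled at \code{n_samples}
#' equidistant poses. At the default 29 samples this yields 377 pairwise
#' distinct \eqn{(\hat n, \hat e)} combinations covering both orientation
#' dependencies of the dark-field signal.
#'
#' @param n_samples poses per trajectory (default 29).
#' @return A list of class \code{df_geometry} with pose matrices \code{n},
#'   \code{e} (P x 3), integer \code{trajectory_id}, and the \code{axes}.
#' @export
full_geometry <- function(n_samples = 29L) {
  build_geometry(geometry_axes("full"), as.integer(n_samples))
}

#' Reduced geometry of the three coordinate-axis trajectories
#'
#' The minimal orthogonal-trajectory scheme that would suffice if either
#' linear surrogate model were exact; a subset of
#' \code{\link{full_geometry}} (87 poses at 29 samples per circle).
#'
#' @inheritParams full_geometry
#' @return A \code{df_geometry} with 3 trajectories.
#' @export
orthogonal_subset <- function(n_samples = 29L) {
  build_geometry(geometry_axes("orthogonal"), as.integer(n_samples))
}

#' @export
print.df_geometry <- function(x, ...) {
  cat("acquisition geometry:", nrow(x$axes), "trajectories,",
      nrow(x$n), "poses\n")
  invisible(x)
}

#' Geometry as a data frame
#'
#' @param x a \code{df_geometry}.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return Data frame with \code{pose_index}, \code{trajectory_id},
#'   \code{n1..n3}, \code{e1..e3}.
#' @export
as.data.frame.df_geometry <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  out <- data.frame(pose_index = seq_len(nrow(x$n)),
                    trajectory_id = x$trajectory_id,
                    n1 = x$n[, 1L], n2 = x$n[, 2L], n3 = x$n[, 3L],
                    e1 = x$e[, 1L], e2 = x$e[, 2L], e3 = x$e[, 3L])
  out
}
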