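#' Eigenvalue simplex grid for the mass-distribution tensor
#'
#' Samples the feasible inverse-variance eigenvalue triplets
#' \eqn{(\sigma_1^{-2}, \sigma_2^{-2}, \sigma_3^{-2})} of a trace-normalized
#' Gaussian mass-distribution tensor on a regular grid: one linear ramp runs
#' from 0 to 1/3 along the first grid index, an orthogonal ramp from 0 to 1/2
#' along the second (endpoints inclusive), and the third eigenvalue follows
#' from the trace constraint \eqn{\sum_i \sigma_i^{-2} = 1}. Each triplet is
#' sorted ascending. Redundant triplets arising in the overlap region
#' \eqn{[1/3, 1/2]} are retained, so an \code{n_grid = 20} grid yields the
#' full set of 400 parameter combinations used for the ensemble study.
#'
#' @param n_grid grid points per ramp (>= 2); the default 20 gives 400
#'   triplets.
#' @return A data frame with \code{n_grid^2} rows and columns \code{grid_i},
#'   \code{grid_j} (0-based grid indices), \code{lam1 <= lam2 <= lam3}.
#' @export
#' @examples
#' g <- eigenvalue_grid(20)
#' nrow(g)              # 400
#' range(g$lam1)        # within [0, 1/3]
eigenvalue_grid <- function(n_grid = 20L) {
  n_grid <- as.integer(n_grid)
  if (length(n_grid) != 1L || is.na(n_grid) || n_grid < 2L)
    stop("'n_grid' must be a single integer >= 2")
  a <- seq(0, 1 / 3, length.out = n_grid)
  b <- seq(0, 1 / 2, length.out = n_grid)
  idx <- expand.grid(grid_i = seq_len(n_grid) - 1L,
                     grid_j = seq_len(n_grid) - 1L)
  av <- a[idx$grid_i + 1L]
  bv <- b[idx$grid_j + 1L]
  cv <- 1 - av - bv
  trip <- t(apply(cbind(av, bv, cv), 1L, sort))
  data.frame(grid_i = idx$grid_i, grid_j = idx$grid_j,
             lam1 = trip[, 1L], lam2 = trip[, 2L], lam3 = trip[, 3L])
}

#' Clamp eigenvalues away from zero
#'
#' The simplex grid contains triplets with one or two exactly zero
#' eigenvalues (infinitely extended volume elements), for which the forward
#' signal diverges. Clamping each eigenvalue at a small positive floor keeps
#' these limiting cases in the ensemble with finite arithmetic.
#'
#' @param lam numeric vector of eigenvalues.
#' @param floor smallest admissible eigenvalue.
#' @return The clamped vector, with attribute \code{clamped} (logical) saying
#'   whether any component was raised.
#' @export
clamp_triplet <- function(lam, floor = 1e-9) {
  out <- pmax(lam, floor)
  attr(out, "clamped") <- any(lam < floor)
  out
}

#' Draw Haar-uniform random rotation matrices
#'
#' Rotations are sampled via uniform unit quaternions (four i.i.d. standard
#' normals, normalized), which induces the rotation-invariant (Haar) measure
#' on SO(3): the image of any fixed direction is uniform on the unit sphere.
#' Uses R's current RNG stream, so results are reproducible under
#' \code{set.seed}.
#'
#' @param n number of rotations to draw.
#' @return For \code{n = 1} a 3x3 rotation matrix; otherwise a
#'   \code{3 x 3 x n} array.
#' @export
#' @examples
#' set.seed(1)
#' R <- random_rotation()
#' max(abs(R %*% t(R) - diag(3)))  # ~ 0
random_rotation <- function(n = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  q <- matrix(stats::rnorm(4L * n), nrow = n, ncol = 4L)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  out <- array(0, dim = c(3L, 3L, n))
  out[1L, 1L, ] <- 1 - 2 * (y^2 + z^2)
  out[1L, 2L, ] <- 2 * (x * y - w * z)
  out[1L, 3L, ] <- 2 * (x * z + w * y)
  out[2L, 1L, ] <- 2 * (x * y + w * z)
  out[2L, 2L, ] <- 1 - 2 * (x^2 + z^2)
  out[2L, 3L, ] <- 2 * (y * z - w * x)
  out[3L, 1L, ] <- 2 * (x * z - w * y)
  out[3L, 2L, ] <- 2 * (y * z + w * x)
  out[3L, 3L, ] <- 1 - 2 * (x^2 + y^2)
  if (n == 1L) out[, , 1L] else out
}

#' Assemble a mass-distribution tensor from eigenvalues and orientation
#'
#' Builds \eqn{T = R \, \mathrm{diag}(\lambda_1, \lambda_2, \lambda_3) R^T},
#' the symmetric positive-(semi)definite precision tensor of the Gaussian
#' density model describing one volume element's microstructure. The
#' eigenvalues are inverse variances along the structure's principal axes, so
#' small eigenvalues correspond to long structural axes.
#'
#' @param eigs numeric length-3 eigenvalue triplet.
#' @param rotation 3x3 rotation matrix giving the principal-axis orientation.
#' @return Symmetric 3x3 matrix with the given eigen-decomposition.
#' @export
assemble_tensor <- function(eigs, rotation) {
  stopifnot(length(eigs) == 3L, is.matrix(rotation),
            all(dim(rotation) == c(3L, 3L)))
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8)
    stop("'rotation' is not orthonormal")
  tens <- rotation %*% diag(as.numeric(eigs)) %*% t(rotation)
  (tens + t(tens)) / 2
}

#' Principal structural axis of a symmetric tensor
#'
#' Returns the unit eigenvector of the smallest or largest eigenvalue. For a
#' ground-truth precision tensor, \code{which = "smallest"} selects the
#' longest structural axis (largest standard deviation); the optical-axis
#' surrogate encodes the same axis at its largest eigenvalue. The sign is
#' fixed so that the last nonzero component is non-negative. If the selected
#' extreme eigenvalue is (numerically) degenerate the returned vector is one
#' arbitrary member of the eigenspace and the attribute \code{degenerate} is
#' set.
#'
#' @param tens symmetric 3x3 matrix.
#' @param which \code{"smallest"} or \code{"largest"}.
#' @param tol eigenvalue-gap tolerance used to flag degeneracy.
#' @return Unit length-3 vector with logical attribute \code{degenerate}.
#' @export
principal_axis <- function(tens, which = c("smallest", "largest"),
                           tol = 1e-8) {
  which <- match.arg(which)
  stopifnot(is.matrix(tens), all(dim(tens) == c(3L, 3L)))
  if (max(abs(tens - t(tens))) > 1e-8) stop("'tens' must be symmetric")
  ed <- eigen((tens + t(tens)) / 2, symmetric = TRUE)  # values descending
  if (which == "smallest") {
    v <- ed$vectors[, 3L]
    gap <- abs(ed$values[2L] - ed$values[3L])
  } else {
    v <- ed$vectors[, 1L]
    gap <- abs(ed$values[1L] - ed$values[2L])
  }
  v <- v / sqrt(sum(v^2))
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[max(nz)] < 0) v <- -v
  attr(v, "degenerate") <- gap <= tol
  v
}

#' Generate the ensemble of ground-truth tensors
#'
#' Crosses the eigenvalue simplex grid with Haar-uniform random orientations:
#' every triplet receives \code{rotations_per_triplet} independent rotations.
#' Each instance's rotation is drawn from its own substream seeded by an
#' affine hash of \code{(seed, instance_id)}, so the ensemble is reproducible
#' and order-independent.
#'
#' @param grid_size grid points per ramp (default 20).
#' @param rotations_per_triplet random orientations per triplet (default 300).
#' @param seed integer master seed.
#' @param clamp_floor eigenvalue floor applied before tensor assembly.
#' @return A list with \code{table} (data frame: \code{instance_id},
#'   \code{grid_i}, \code{grid_j}, \code{rotation_index}, \code{lam1..lam3}
#'   clamped, \code{r11..r33} row-major rotation entries, \code{clamped},
#'   \code{seed}) and \code{tensors} (a \code{3 x 3 x n} array of assembled
#'   mass-distribution tensors).
#' @export
generate_ensemble <- function(grid_size = 20L, rotations_per_triplet = 300L,
                              seed = 1L, clamp_floor = 1e-9) {
  grid <- eigenvalue_grid(grid_size)
  n_trip <- nrow(grid)
  n_rot <- as.integer(rotations_per_triplet)
  if (n_rot < 1L) stop("'rotations_per_triplet' must be >= 1")
  n <- n_trip * n_rot
  tensors <- array(0, dim = c(3L, 3L, n))
  rot_flat <- matrix(0, nrow = n, ncol = 9L)
  lam_cl <- matrix(0, nrow = n, ncol = 3L)
  clamped <- logical(n)
  id <- 0L
  for (tr in seq_len(n_trip)) {
    lam <- clamp_triplet(as.numeric(grid[tr, c("lam1", "lam2", "lam3")]),
                         floor = clamp_floor)
    for (ro in seq_len(n_rot)) {
      id <- id + 1L
      set.seed(instance_seed(seed, id))
      rot <- random_rotation()
      tensors[, , id] <- assemble_tensor(lam, rot)
      rot_flat[id, ] <- as.numeric(t(rot))  # row-major
      lam_cl[id, ] <- lam
      clamped[id] <- attr(lam, "clamped")
    }
  }
  tab <- data.frame(
    instance_id = seq_len(n),
    grid_i = rep(grid$grid_i, each = n_rot),
    grid_j = rep(grid$grid_j, each = n_rot),
    rotation_index = rep(seq_len(n_rot), times = n_trip),
    lam1 = lam_cl[, 1L], lam2 = lam_cl[, 2L], lam3 = lam_cl[, 3L],
    clamped = clamped, seed = seed
  )
  colnames(rot_flat) <- paste0("r", rep(1:3, each = 3L), rep(1:3, 3L))
  list(table = cbind(tab, as.data.frame(rot_flat)), tensors = tensors)
}

# deterministic per-instance seed; affine hash keeps values in [1, 2^31 - 2]
instance_seed <- function(seed, instance_id) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(instance_id)) %%
               2147483647)
}
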