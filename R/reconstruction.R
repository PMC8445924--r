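#' Iteration schedule for the damped back-projection
#'
#' The relaxation factor decays geometrically, \eqn{\lambda_k = \lambda_0
#' 2^{-k/\tau}}, over \eqn{k_{max} = n_{passes} \times P} iterations
#' (\eqn{P} projections, each visited \code{n_passes} times). At the default
#' \code{n_passes = 25} the decay constant is \eqn{\tau = 3 k_{max} / 25},
#' i.e. the relaxation halves every three sweeps, damping the impact of
#' individual projections (and of their ordering) as the iteration settles
#' on a mean solution. There is no early stopping: the schedule runs to
#' exhaustion.
#'
#' @param n_projections number of projections P.
#' @param lambda0 initial relaxation in (0, 1].
#' @param n_passes sweeps through the projection set.
#' @return List of class \code{df_schedule} with \code{lambda0},
#'   \code{n_passes}, \code{k_max}, \code{tau}.
#' @export
iteration_schedule <- function(n_projections, lambda0 = 0.2, n_passes = 25L) {
  n_projections <- as.integer(n_projections)
  n_passes <- as.integer(n_passes)
  stopifnot(n_projections >= 1L, n_passes >= 1L)
  if (!is.finite(lambda0) || lambda0 <= 0 || lambda0 > 1)
    stop("'lambda0' must lie in (0, 1]")
  k_max <- n_passes * n_projections
  structure(list(lambda0 = lambda0, n_passes = n_passes, k_max = k_max,
                 tau = 3 * k_max / 25), class = "df_schedule")
}

#' Relaxation factor at iteration k
#'
#' @param k iteration index, 0..k_max.
#' @param schedule an \code{\link{iteration_schedule}}.
#' @return \eqn{\lambda_0 2^{-k/\tau}}.
#' @export
relaxation <- function(k, schedule) {
  stopifnot(all(k >= 0), all(k <= schedule$k_max))
  schedule$lambda0 * 2^(-k / schedule$tau)
}

check_directions <- function(directions) {
  stopifnot(is.matrix(directions), ncol(directions) == 3L)
  if (nrow(directions) == 0L) stop("empty projection set")
  if (max(abs(rowSums(directions^2) - 1)) > 1e-8)
    stop("direction vectors must be unit norm")
  invisible(directions)
}

recon_order <- function(n_projections, n_passes, shuffle = FALSE,
                        shuffle_seed = NULL) {
  if (!shuffle) return(rep(seq_len(n_projections) - 1L, times = n_passes))
  if (!is.null(shuffle_seed)) set.seed(shuffle_seed)
  unlist(lapply(seq_len(n_passes),
                function(p) sample.int(n_projections) - 1L))
}

#' Reconstruct a surrogate tensor by damped iterative back-projection
#'
#' Fits the linear model \eqn{\mu^{(i)} \approx \hat r^{(i)T} U \hat
#' r^{(i)}} for a symmetric 3x3 tensor \eqn{U} by the Kaczmarz-type update
#' \deqn{U \leftarrow U + \lambda_k \, \hat r \hat r^T (\mu^{(i_k)} -
#' \hat r^T U \hat r),} starting from \eqn{U = 0}. For a unit direction the
#' update is a pseudo-inverse step: with \eqn{\lambda_k = 1} a single update
#' makes the model exactly consistent with the visited projection. The
#' decaying relaxation (see \code{\link{iteration_schedule}}) averages over
#' the inconsistencies of the surrogate model. Passing the optical axes
#' \eqn{\hat n^{(i)}} yields the cross-section surrogate N; passing the
#' sensitivity axes \eqn{\hat e^{(i)}} yields the auto-correlation
#' surrogate E.
#'
#' @param signals numeric vector of scalar dark-field signals.
#' @param directions matrix (length(signals) x 3) of unit vectors
#'   \eqn{\hat r}.
#' @param lambda0,n_passes schedule parameters (defaults 0.2 and 25).
#' @param shuffle if \code{TRUE}, visit projections in a freshly shuffled
#'   order each pass instead of the default deterministic cyclic sweep.
#' @param shuffle_seed optional seed for the shuffled order.
#' @return Symmetric 3x3 matrix U (not necessarily positive definite).
#' @export
reconstruct <- function(signals, directions, lambda0 = 0.2, n_passes = 25L,
                        shuffle = FALSE, shuffle_seed = NULL) {
  signals <- as.numeric(signals)
  if (length(signals) == 0L) stop("empty signal list")
  check_directions(directions)
  if (nrow(directions) != length(signals))
    stop("signals and directions differ in length")
  u6 <- reconstruct_batch(matrix(signals, nrow = 1L), directions,
                          lambda0 = lambda0, n_passes = n_passes,
                          shuffle = shuffle, shuffle_seed = shuffle_seed)
  sym6_to_mat(u6[1L, ])
}

#' Batch reconstruction over many instances
#'
#' Runs \code{\link{reconstruct}} for every row of a signal matrix sharing
#' one direction set (one acquisition geometry), via the compiled kernel.
#'
#' @param signal_matrix numeric matrix, one instance per row.
#' @inheritParams reconstruct
#' @return Matrix (instances x 6) of the free components
#'   (xx, yy, zz, xy, xz, yz).
#' @export
reconstruct_batch <- function(signal_matrix, directions, lambda0 = 0.2,
                              n_passes = 25L, shuffle = FALSE,
                              shuffle_seed = NULL) {
  stopifnot(is.matrix(signal_matrix))
  if (ncol(signal_matrix) == 0L) stop("empty signal list")
  check_directions(directions)
  if (nrow(directions) != ncol(signal_matrix))
    stop("signals and directions differ in length")
  sched <- iteration_schedule(nrow(directions), lambda0 = lambda0,
                              n_passes = n_passes)
  ord <- recon_order(nrow(directions), sched$n_passes, shuffle, shuffle_seed)
  recon_batch_cpp(signal_matrix, directions, sched$lambda0, sched$tau,
                  as.integer(ord))
}

#' Closed-form least-squares fit of the linear tensor model
#'
#' Solves \eqn{\min_U \sum_i (\mu_i - \hat r_i^T U \hat r_i)^2} directly in
#' the 6 free components of the symmetric tensor via QR on the design matrix
#' with rows \eqn{(r_1^2, r_2^2, r_3^2, 2 r_1 r_2, 2 r_1 r_3, 2 r_2 r_3)}.
#' Serves as the independent fixed-point reference for the iterative
#' scheme.
#'
#' @inheritParams reconstruct
#' @return Symmetric 3x3 matrix, the unique least-squares solution.
#' @export
least_squares_fit <- function(signals, directions) {
  signals <- as.numeric(signals)
  if (length(signals) == 0L) stop("empty signal list")
  check_directions(directions)
  if (nrow(directions) != length(signals))
    stop("signals and directions differ in length")
  r1 <- directions[, 1L]; r2 <- directions[, 2L]; r3 <- directions[, 3L]
  A <- cbind(r1^2, r2^2, r3^2, 2 * r1 * r2, 2 * r1 * r3, 2 * r2 * r3)
  dec <- qr(A)
  if (dec$rank < 6L)
    stop(sprintf("rank-deficient design: rank %d < 6", dec$rank))
  sym6_to_mat(qr.coef(dec, signals))
}

sym6_to_mat <- function(v) {
  matrix(c(v[1L], v[4L], v[5L],
           v[4L], v[2L], v[6L],
           v[5L], v[6L], v[3L]), nrow = 3L)
}

mat_to_sym6 <- function(m) {
  c(m[1L, 1L], m[2L, 2L], m[3L, 3L], m[1L, 2L], m[1L, 3L], m[2L, 3L])
}
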