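# Shared fixtures and independent oracles, all built in code.

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random positive-definite trace-normalized tensor
rand_tensor <- function(lam_min = 0.05) {
  lam <- sort(stats::runif(3, lam_min, 1))
  assemble_tensor(lam / sum(lam), random_rotation())
}

# random pose from a random trajectory point
rand_pose <- function() {
  tr <- trajectory(rand_unit3(), n_samples = 1L +
                     sample.int(12L, 1L))
  j <- sample.int(nrow(tr$n), 1L)
  pose(tr$n[j, ], tr$e[j, ])
}

# Independent signal oracle: invert the precision tensor to the covariance,
# marginalize the optical (z) axis, invert the in-plane block, take its xx
# entry (precision of the projected density along the sensitivity axis) and
# apply the cross-section prefactor.
schur_oracle <- function(tens, p) {
  tp <- instrument_frame_tensor(tens, p)
  covm <- solve(tp)
  marg_prec <- solve(covm[1:2, 1:2])
  marg_prec[1, 1] / sqrt(tp[3, 3])
}

# Inverse-CDF sampler of the small-angle inclination density
# theta * exp(-theta^2 / (2 sigma^2)) (a Rayleigh distribution).
sample_small_angle <- function(n, sigma) {
  sigma * sqrt(-2 * log(1 - stats::runif(n)))
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), nrow = 3)
}
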