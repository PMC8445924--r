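test_that("nrmse is the mean-normalized RMS residual", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), (1 / sqrt(3)) / 2)
  expect_equal(nrmse(c(1, 3), c(2, 2)), 0.5)
  expect_error(nrmse(c(-1, 1), c(0, 0)), "normalization")
  expect_error(nrmse(1:3, 1:2), "length")
})

test_that("angular error is the acute axis angle, sign-invariant", {
  v <- c(1 / sqrt(2), 1 / sqrt(2), 0)
  # |dot| reaches 1 only up to rounding; the acute angle collapses to ~0
  expect_lt(angular_error(v, v), 1e-5)
  expect_lt(angular_error(v, -v), 1e-5)
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  # symmetric in its arguments and invariant under simultaneous rotation
  set.seed(17)
  for (i in 1:20) {
    a <- rand_unit3(); b <- rand_unit3()
    expect_equal(angular_error(a, b), angular_error(b, a))
    Q <- random_rotation()
    expect_equal(angular_error(as.numeric(Q %*% a), as.numeric(Q %*% b)),
                 angular_error(a, b), tolerance = 1e-8)
  }
  # dots slightly above 1 from rounding are clamped; larger ones rejected
  expect_equal(angular_error(c(1, 0, 0), c(1 + 1e-12, 0, 0)), 0)
  expect_error(angular_error(c(2, 0, 0), c(1, 0, 0)), "unit")
})

test_that("sigma fit recovers the width of the inclination density", {
  set.seed(18)
  for (sigma in c(0.3, 1, 5)) {
    ang <- sample_small_angle(1e5, sigma)
    est <- fit_sigma_theta(ang)
    expect_lt(abs(est - sigma) / sigma, 0.10)
    # truncated-density cross-check is coarser (few bins below the peak)
    est_fit <- fit_sigma_theta(ang, method = "fit")
    expect_lt(abs(est_fit - sigma) / sigma, 0.15)
  }
  # degenerate point mass
  expect_equal(fit_sigma_theta(rep(5, 10)), 5)
  expect_error(fit_sigma_theta(numeric(0)), "empty")
})

test_that("small-angle and sin-weighted densities share their mode", {
  # the small-angle form peaks exactly at sigma; the exact sin-weighted
  # density agrees within 1% relative for sigma <= 5 degrees
  for (sigma in c(1, 3, 5)) {
    exact_mode <- stats::optimize(function(th)
      sin(th * pi / 180) * exp(-th^2 / (2 * sigma^2)),
      lower = 0, upper = 4 * sigma, maximum = TRUE)$maximum
    expect_lt(abs(exact_mode - sigma) / sigma, 0.01)
  }
})

test_that("spectra pairing normalizes, sorts, and reverses for model N", {
  tens <- diag(c(0.2, 0.3, 0.5))
  sp <- compare_spectra(tens, tens, model = "E")
  expect_equal(sp[, 1], sp[, 2], ignore_attr = TRUE)
  expect_false(attr(sp, "flagged"))
  # scale invariance of the normalization
  sp2 <- compare_spectra(tens, diag(c(2, 3, 5)), model = "E")
  expect_equal(sp2[, 2], c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  # reversal for the anti-correlated optical-axis model: the largest
  # surrogate eigenvalue is paired with the smallest truth eigenvalue
  sp3 <- compare_spectra(tens, diag(c(5, 3, 2)), model = "N")
  expect_equal(sp3[, 1], c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  expect_equal(sp3[, 2], c(0.5, 0.3, 0.2), ignore_attr = TRUE)
  # E pairs in like order: monotone in both columns
  set.seed(19)
  for (i in 1:10) {
    spr <- compare_spectra(rand_tensor(), rand_tensor(), model = "E")
    expect_true(!is.unsorted(spr[, 1]) && !is.unsorted(spr[, 2]))
  }
  # near-zero trace cannot be normalized: flagged, not divided
  spf <- compare_spectra(tens, diag(c(-1, 1e-9, 1)), model = "N")
  expect_true(attr(spf, "flagged"))
  expect_true(all(is.na(spf)))
})

test_that("mean eigenvalue estimates the direction-averaged signal", {
  expect_equal(mean_signal_check(2 * diag(3), rep(2, 5)),
               c(mean_eigenvalue = 2, mean_signal = 2))
  expect_equal(mean_signal_check(matrix(0, 3, 3), rep(0, 4)),
               c(mean_eigenvalue = 0, mean_signal = 0))
  # Monte-Carlo oracle: mean of r' U r over uniform directions -> trace/3
  set.seed(20)
  u <- matrix(stats::rnorm(9), 3); u <- (u + t(u)) / 2
  dirs <- matrix(stats::rnorm(3 * 2e4), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sig <- rowSums((dirs %*% u) * dirs)
  msc <- mean_signal_check(u, sig)
  expect_equal(unname(msc["mean_signal"]), unname(msc["mean_eigenvalue"]),
               tolerance = 0.02)
})
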