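test_that("eigenvalue grid covers the simplex with the stated ramps", {
  g <- eigenvalue_grid(20)
  expect_equal(nrow(g), 400L)
  # every triplet sorted ascending, trace-normalized, within Eq.-range bounds
  expect_true(all(g$lam1 <= g$lam2 & g$lam2 <= g$lam3))
  expect_true(all(abs(g$lam1 + g$lam2 + g$lam3 - 1) < 1e-12))
  expect_true(all(g$lam1 >= 0 & g$lam1 <= 1 / 3 + 1e-12))
  expect_true(all(g$lam2 <= 1 / 2 + 1e-12))
  expect_true(all(g$lam3 >= 1 / 3 - 1e-12))
  # grid corner: both ramps at zero, normalization forces (0, 0, 1)
  corner <- g[g$grid_i == 0 & g$grid_j == 0, ]
  expect_equal(as.numeric(corner[c("lam1", "lam2", "lam3")]), c(0, 0, 1))
  # ramp endpoints inclusive: first ramp reaches 1/3 exactly
  end_row <- g[g$grid_i == 19 & g$grid_j == 0, ]
  expect_equal(as.numeric(end_row[c("lam1", "lam2", "lam3")]),
               c(0, 1 / 3, 2 / 3))
  expect_equal(max(g$lam2[g$grid_j == 19]), 1 / 2)
  expect_error(eigenvalue_grid(1), "n_grid")
})

test_that("random rotations are proper, seeded, and Haar-uniform", {
  set.seed(11)
  for (i in 1:20) {
    R <- random_rotation()
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  set.seed(99); a <- random_rotation(5)
  set.seed(99); b <- random_rotation(5)
  expect_identical(a, b)

  # area-uniformity: polar cosine of the image of e_z is uniform on [-1, 1]
  set.seed(5)
  n <- 1e5
  rots <- random_rotation(n)
  z <- rots[3, 3, ]  # third component of R %*% c(0,0,1)
  ks <- suppressWarnings(stats::ks.test(z, "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
  expect_lt(max(abs(apply(rots, c(1, 2), mean))), 5 / sqrt(n))
})

test_that("tensor assembly reproduces the eigen-decomposition", {
  expect_equal(assemble_tensor(c(0.2, 0.3, 0.5), diag(3)),
               diag(c(0.2, 0.3, 0.5)))
  rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), nrow = 3)
  expect_equal(assemble_tensor(c(0.2, 0.3, 0.5), rz90),
               diag(c(0.3, 0.2, 0.5)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    lam <- sort(stats::runif(3)); lam <- lam / sum(lam)
    tens <- assemble_tensor(lam, random_rotation())
    expect_lt(max(abs(tens - t(tens))), 1e-12)
    expect_equal(sum(diag(tens)), 1, tolerance = 1e-10)
    expect_equal(sort(eigen(tens, symmetric = TRUE)$values), lam,
                 tolerance = 1e-10)
  }
  expect_error(assemble_tensor(c(1, 2, 3), matrix(1, 3, 3)), "orthonormal")
})

test_that("eigenvalue clamping keeps divergent limits finite and flags them", {
  lam <- clamp_triplet(c(0, 0, 1))
  expect_true(attr(lam, "clamped"))
  expect_true(all(lam >= 1e-9))
  lam2 <- clamp_triplet(c(0.2, 0.3, 0.5))
  expect_false(attr(lam2, "clamped"))
  expect_equal(as.numeric(lam2), c(0.2, 0.3, 0.5))
})

test_that("principal axis selects the extreme eigenvector with fixed sign", {
  d <- diag(c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(principal_axis(d, "smallest")), c(1, 0, 0))
  expect_equal(as.numeric(principal_axis(d, "largest")), c(0, 0, 1))
  set.seed(3)
  for (i in 1:10) {
    R <- random_rotation()
    tens <- R %*% d %*% t(R)
    v <- principal_axis(tens, "smallest")
    expect_equal(abs(sum(v * R[, 1])), 1, tolerance = 1e-8)
    expect_false(attr(v, "degenerate"))
    nz <- which(abs(v) > 1e-12)
    expect_gte(v[max(nz)], 0)
  }
  # degenerate extreme pair is flagged
  vdeg <- principal_axis(diag(c(0.25, 0.25, 0.5)), "smallest")
  expect_true(attr(vdeg, "degenerate"))
})

test_that("ensemble generation is reproducible and records clamping", {
  e1 <- generate_ensemble(3, 4, seed = 7)
  e2 <- generate_ensemble(3, 4, seed = 7)
  expect_identical(e1$table, e2$table)
  expect_identical(e1$tensors, e2$tensors)
  expect_equal(nrow(e1$table), 9L * 4L)
  expect_true(any(e1$table$clamped))   # the (0,0,1) corner
  # clamped rows still assemble to finite positive-definite tensors
  ev <- apply(e1$tensors, 3, function(m)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(ev > 0))
  # rotation entries stored row-major reproduce the tensor
  i <- 5L
  rot <- matrix(as.numeric(e1$table[i, paste0("r", c(11, 12, 13, 21, 22, 23,
                                                     31, 32, 33))]),
                nrow = 3, byrow = TRUE)
  lam <- as.numeric(e1$table[i, c("lam1", "lam2", "lam3")])
  expect_equal(assemble_tensor(lam, rot), e1$tensors[, , i],
               tolerance = 1e-12)
})
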