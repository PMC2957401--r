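test_that("rotation_matrix reproduces known rotations", {
  expect_equal(rotation_matrix(c(1, 0, 0, 0)), diag(3))
  expect_equal(rotation_matrix(c(0, 0, 0, 1)), diag(c(-1, -1, 1)))
  R90 <- rotation_matrix(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2))
  expect_equal(R90, matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
  # the x-axis maps onto the y-axis
  expect_equal(as.numeric(R90 %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_error(rotation_matrix(c(1, 1, 0, 0)), "unit norm")
})

test_that("every unit quaternion gives a proper rotation", {
  set.seed(11)
  for (i in 1:50) {
    q <- random_unit_quat()
    R <- rotation_matrix(q)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("apply_transform is an order-preserving isometry", {
  tf <- rigid_transform(c(1, 0, 0, 0), c(1, 2, 3))
  expect_equal(apply_transform(tf, c(0, 0, 0)), matrix(c(1, 2, 3), 1))
  set.seed(2)
  P <- random_point_cloud(15)
  expect_equal(apply_transform(identity_transform(), P), P)
  a <- rigid_transform(random_unit_quat(), runif(3, -5, 5))
  Pa <- apply_transform(a, P)
  expect_equal(as.numeric(dist(Pa)), as.numeric(dist(P)),
               tolerance = 1e-9)
  # 90-degree rotation example
  rot <- rigid_transform(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2), c(0, 0, 0))
  expect_equal(apply_transform(rot, c(1, 0, 0)), matrix(c(0, 1, 0), 1),
               tolerance = 1e-12)
  expect_error(apply_transform(a, matrix(numeric(0), 0, 3)), "empty")
})

test_that("quaternions are canonicalized and composition/inversion agree", {
  a <- rigid_transform(-c(0.5, 0.5, 0.5, 0.5), c(1, 0, 0))
  expect_gte(a$q[1], 0)  # sign flipped to the canonical representative
  set.seed(3)
  for (i in 1:10) {
    a <- rigid_transform(random_unit_quat(), runif(3, -5, 5))
    b <- rigid_transform(random_unit_quat(), runif(3, -5, 5))
    P <- random_point_cloud(6)
    expect_equal(apply_transform(transform_compose(a, b), P),
                 apply_transform(a, apply_transform(b, P)),
                 tolerance = 1e-9)
    expect_lt(composition_error(a, a), 1e-9)
    expect_equal(apply_transform(transform_invert(a), apply_transform(a, P)),
                 P, tolerance = 1e-9)
  }
})

test_that("optimal_transform recovers a planted rigid motion exactly", {
  expect_identical(optimal_transform(diag(3), diag(3))$msd, 0)
  # pure translation
  P <- random_point_cloud(8)
  sol <- optimal_transform(P, sweep(P, 2, c(5, 0, 0), "+"))
  expect_equal(sol$transform$q, c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(sol$transform$t, c(5, 0, 0), tolerance = 1e-9)
  expect_lt(sol$msd, 1e-18)
  set.seed(4)
  for (i in 1:20) {
    P <- random_point_cloud(10)
    truth <- rigid_transform(random_unit_quat(), runif(3, -10, 10))
    Q <- apply_transform(truth, P)
    sol <- optimal_transform(P, Q)
    expect_lt(composition_error(sol$transform, truth), 1e-6)
    expect_lt(sol$msd, 1e-12)
    # returned msd equals the independently computed mean square error
    expect_equal(sol$msd,
                 mean_square_error(P, Q, seq_len(nrow(P)), sol$transform),
                 tolerance = 1e-8)
  }
})

test_that("optimal_transform matches dense numerical minimization", {
  set.seed(5)
  for (rep in 1:3) {
    P <- random_point_cloud(5)
    Q <- random_point_cloud(5)
    sol <- optimal_transform(P, Q)
    # independent numeric oracle: multi-start Nelder-Mead over the raw
    # 7-vector with quaternion renormalization inside the loss
    loss <- function(x) {
      nq <- sqrt(sum(x[1:4]^2))
      if (nq < 1e-8) return(1e9)
      mean_square_error(P, Q, 1:5, rigid_transform(x[1:4] / nq, x[5:7]))
    }
    best <- Inf
    for (s in 1:12) {
      x0 <- c(random_unit_quat(), colMeans(Q) - colMeans(P) + rnorm(3))
      o <- optim(x0, loss, control = list(maxit = 4000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_lt(sol$msd, best + 1e-4)
    expect_equal(sol$msd, best, tolerance = 1e-3)
  }
})

test_that("degenerate mappings fall back to centroid translation", {
  P <- random_point_cloud(4)
  Qc <- matrix(rep(c(1, 2, 3), each = 4), ncol = 3)  # all targets coincide
  sol <- optimal_transform(P, Qc)
  expect_equal(sol$transform$q, c(1, 0, 0, 0))
  expect_equal(sol$transform$t, c(1, 2, 3) - colMeans(P), tolerance = 1e-9)
})

test_that("random_transform is seeded, in-bounds and sphere-uniform", {
  dom <- search_domain(c(-3, -2, -1), c(3, 2, 1))
  set.seed(9); a <- random_transform(dom)
  set.seed(9); b <- random_transform(dom)
  expect_identical(as_vector7(a), as_vector7(b))
  set.seed(10)
  draws <- t(replicate(1e4, as_vector7(random_transform(dom))))
  expect_true(all(sweep(draws[, 5:7], 2, dom$lower, ">=")))
  expect_true(all(sweep(draws[, 5:7], 2, dom$upper, "<=")))
  # vector part averages to zero on the sphere (a0 is sign-canonical)
  expect_true(all(abs(colMeans(draws[, 2:4])) < 0.05))
  expect_equal(sqrt(rowSums(draws[, 1:4]^2)), rep(1, 1e4), tolerance = 1e-9)
})

test_that("normalize_candidate renormalizes the quaternion block only", {
  a <- normalize_candidate(c(2, 0, 0, 0, 1, 1, 1))
  expect_equal(a$q, c(1, 0, 0, 0))
  expect_equal(a$t, c(1, 1, 1))
  expect_equal(normalize_candidate(c(1, 1, 1, 1, 0, 0, 0))$q,
               c(0.5, 0.5, 0.5, 0.5))
  # idempotent on already-normalized candidates
  v <- as_vector7(rigid_transform(random_unit_quat(), c(4, 5, 6)))
  expect_equal(as_vector7(normalize_candidate(v)), v, tolerance = 1e-12)
  expect_error(normalize_candidate(c(0, 0, 0, 0, 1, 1, 1)), "degenerate")
})

test_that("transform serialization round-trips", {
  a <- rigid_transform(c(0.5, 0.5, 0.5, 0.5), c(1.25, -2, 3))
  expect_lt(composition_error(transform_from_json(transform_to_json(a)), a),
            1e-12)
  H <- as_homogeneous_matrix(a)
  expect_equal(dim(H), c(4, 4))
  expect_equal(H[4, ], c(0, 0, 0, 1))
  expect_equal(H[1:3, 1:3], rotation_matrix(a$q))
  P <- random_point_cloud(5)
  expect_equal(t(H %*% rbind(t(P), 1))[, 1:3], apply_transform(a, P),
               tolerance = 1e-12)
})
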