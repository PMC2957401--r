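P2 <- matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
Q2 <- matrix(c(0.1, 0, 0, 5, 0, 0), ncol = 3, byrow = TRUE)

test_that("mean_square_error computes the mean squared residual", {
  P <- random_point_cloud(6)
  expect_equal(mean_square_error(P, P, 1:6), 0)
  expect_equal(mean_square_error(matrix(c(0, 0, 0), 1),
                                 matrix(c(1, 0, 0), 1), 1), 1.0)
  Pm <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  Qm <- matrix(c(0, 0, 1, 1, 0, 2), ncol = 3, byrow = TRUE)
  expect_equal(mean_square_error(Pm, Qm, 1:2), 2.5)
  expect_error(mean_square_error(Pm, Qm, c(1, 3)), "out of range")
})

test_that("closest_point_mapping is the exact nearest-neighbour map", {
  P <- random_point_cloud(7)
  expect_equal(closest_point_mapping(P, P), 1:7)
  # non-injectivity: both query atoms collapse onto the near target
  expect_equal(closest_point_mapping(P2, Q2), c(1L, 1L))
  # tie -> lowest index
  expect_equal(closest_point_mapping(matrix(c(0, 0, 0), 1),
                                     matrix(c(1, 0, 0, -1, 0, 0),
                                            ncol = 3, byrow = TRUE)), 1L)
  # exhaustive check against a brute-force nearest neighbour
  set.seed(21)
  A <- random_point_cloud(9); B <- random_point_cloud(13)
  psi <- closest_point_mapping(A, B)
  D <- as.matrix(dist(rbind(A, B)))[1:9, 10:22]
  expect_equal(psi, unname(apply(D, 1, which.min)))
  # no single-entry change can lower the objective
  f0 <- mean_square_error(A, B, psi)
  for (i in 1:9) for (j in 1:13) {
    alt <- psi; alt[i] <- j
    expect_gte(mean_square_error(A, B, alt), f0 - 1e-12)
  }
})

test_that("build_cost_graph filters edges and computes exact costs", {
  g <- build_cost_graph(P2, rbind(Q2, c(9, 9, 9)))
  expect_equal(nrow(g$edges), 6)
  g2 <- build_cost_graph(P2, rbind(Q2, c(9, 9, 9)),
                         labels_P = c("ACC", "DO"),
                         labels_Q = c("DO", "ACC", "PI"),
                         mode = "same-property")
  expect_equal(nrow(g2$edges), 2)
  expect_equal(g2$edges$q[g2$edges$p == 1], 2L)  # ACC pairs with ACC
  g3 <- build_cost_graph(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1))
  expect_equal(g3$edges$cost, 25)
  expect_error(
    build_cost_graph(P2, Q2, labels_P = c("ACC", "PI"),
                     labels_Q = c("ACC", "ACC"), mode = "same-property"),
    "infeasible.*2")
})

test_that("solve_aap is exact on hand-enumerable instances", {
  gr <- structure(list(
    edges = data.frame(p = c(1, 1, 2, 2), q = c(1, 2, 1, 2),
                       cost = c(1, 2, 2, 4)),
    n = 2L, m = 2L, mode = "all-pairs", excluded_p = integer(0),
    included_p = 1:2), class = "cost_graph")
  sol <- solve_aap(gr)
  expect_equal(sol$assignment, c(2L, 1L))  # cross pairing beats identity
  expect_equal(sol$total_cost, 4)
  # 1 x 3 row: the minimum wins
  gr1 <- structure(list(
    edges = data.frame(p = 1, q = 1:3, cost = c(7, 2, 5)),
    n = 1L, m = 3L, mode = "all-pairs", excluded_p = integer(0),
    included_p = 1L), class = "cost_graph")
  expect_equal(solve_aap(gr1)$assignment, 2L)
  expect_equal(solve_aap(gr1)$total_cost, 2)
  # identical superposed sets: identity permutation at zero cost
  P <- random_point_cloud(5)
  sol <- solve_aap(build_cost_graph(P, P))
  expect_equal(sol$assignment, 1:5)
  expect_equal(sol$total_cost, 0)
})

test_that("solve_aap equals brute-force enumeration on random graphs", {
  set.seed(31)
  for (trial in 1:100) {
    n <- sample(2:6, 1); m <- sample(n:7, 1)
    cost <- matrix(round(runif(n * m, 0, 20), 3), n, m)
    g <- build_cost_graph(random_point_cloud(n), random_point_cloud(m))
    g$edges <- data.frame(p = rep(1:n, each = m), q = rep(1:m, n),
                          cost = as.vector(t(cost)))
    g$n <- n; g$m <- m; g$included_p <- 1:n
    sol <- solve_aap(g)
    oracle <- brute_force_aap(cost)
    expect_equal(sol$total_cost, oracle$total_cost, tolerance = 1e-12)
    expect_equal(sum(cost[cbind(1:n, sol$assignment)]), sol$total_cost)
    expect_false(anyDuplicated(sol$assignment) > 0)
  }
})

test_that("matching distance dominates the closest-point objective", {
  # hand-worked instance: injectivity forces the far pairing
  md <- matching_distance(P2, Q2)
  expect_equal(md$value, (0.01 + 9) / 2)
  expect_equal(md$assignment, c(1L, 2L))
  cp <- objective(P2, Q2, identity_transform(), kind = "closest")
  expect_equal(cp, (0.01 + 3.61) / 2)
  expect_gt(md$value, cp)
  # single-point sets: squared distance
  expect_equal(matching_distance(matrix(c(0, 0, 0), 1),
                                 matrix(c(1, 1, 1), 1))$value, 3)
  # identity at the generating transform
  set.seed(41)
  a <- rigid_transform(random_unit_quat(), c(1, -2, 0.5))
  P <- random_point_cloud(8)
  md0 <- matching_distance(P, apply_transform(a, P), a)
  expect_lt(md0$value, 1e-18)
  expect_equal(md0$assignment, 1:8)
  # property over random triples
  for (i in 1:100) {
    n <- sample(3:7, 1); m <- sample(n:9, 1)
    P <- random_point_cloud(n); Q <- random_point_cloud(m)
    tr <- rigid_transform(random_unit_quat(), runif(3, -3, 3))
    expect_gte(objective(P, Q, tr, kind = "matching") + 1e-12,
               objective(P, Q, tr, kind = "closest"))
  }
})

test_that("matching objective equals brute force over injective maps", {
  set.seed(51)
  P <- random_point_cloud(6); Q <- random_point_cloud(8)
  tr <- rigid_transform(random_unit_quat(), runif(3, -2, 2))
  got <- objective(P, Q, tr, kind = "matching")
  Pa <- apply_transform(tr, P)
  cost <- as.matrix(dist(rbind(Pa, Q)))[1:6, 7:14]^2
  expect_equal(got, brute_force_aap(cost)$total_cost / 6, tolerance = 1e-9)
})

test_that("same-property restriction only raises the matching distance", {
  set.seed(61)
  classes <- c("ACC", "DO", "AD", "ALI", "PI")
  for (i in 1:20) {
    n <- sample(4:6, 1); m <- n + sample(0:3, 1)
    P <- random_point_cloud(n); Q <- random_point_cloud(m)
    lp <- sample(classes, n, replace = TRUE)
    lq <- c(lp, sample(classes, m - n, replace = TRUE))[sample(m)]
    tr <- rigid_transform(random_unit_quat(), runif(3, -2, 2))
    all_p <- matching_distance(P, Q, tr, lp, lq, "all-pairs")$value
    same <- matching_distance(P, Q, tr, lp, lq, "same-property")$value
    expect_gte(same + 1e-12, all_p)
    ga <- build_cost_graph(apply_transform(tr, P), Q, lp, lq, "all-pairs")
    gs <- build_cost_graph(apply_transform(tr, P), Q, lp, lq, "same-property")
    expect_true(all(paste(gs$edges$p, gs$edges$q) %in%
                    paste(ga$edges$p, ga$edges$q)))
  }
})

test_that("NONE query atoms are excluded in same-property mode", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  Q <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  md <- matching_distance(P, Q, labels_P = c("ACC", "NONE", "ACC"),
                          labels_Q = c("ACC", "ACC", "ACC"),
                          mode = "same-property")
  expect_true(is.na(md$assignment[2]))
  expect_equal(md$assignment[c(1, 3)], c(1L, 3L))
  expect_equal(md$value, 0)
})

test_that("objectives are invariant under consistent frame changes", {
  set.seed(71)
  for (i in 1:10) {
    P <- random_point_cloud(6); Q <- random_point_cloud(8)
    a <- rigid_transform(random_unit_quat(), runif(3, -3, 3))
    b <- rigid_transform(random_unit_quat(), runif(3, -3, 3))
    # moving the query frame by b and composing the candidate leaves g fixed
    Pb <- apply_transform(b, P)
    a_adj <- transform_compose(a, transform_invert(b))
    for (kind in c("closest", "matching")) {
      expect_equal(objective(P, Q, a, kind = kind),
                   objective(Pb, Q, a_adj, kind = kind), tolerance = 1e-9)
    }
  }
})

test_that("relaxed mode keeps incompatible pairs at a finite penalty", {
  P <- matrix(c(0, 0, 0), 1)
  Q <- matrix(c(1, 0, 0), 1)
  expect_error(matching_distance(P, Q, labels_P = "ACC", labels_Q = "DO",
                                 mode = "same-property"), "infeasible")
  rel <- matching_distance(P, Q, labels_P = "ACC", labels_Q = "DO",
                           mode = "relax")
  expect_true(is.finite(rel$value))
  expect_gt(rel$value, 0)
})
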