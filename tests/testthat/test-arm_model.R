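p <- fx_params()

# independent scalar evaluation of the two-link inertia terms, written out
# from the standard Lagrangian derivation (oracle for the matrix code)
inertia_oracle <- function(p, q2) {
  a1 <- p$Iz1 + p$m1 * p$r1^2 + p$Iz2 + p$m2 * (p$l1^2 + p$r2^2)
  a2 <- p$m2 * p$l1 * p$r2
  a3 <- p$Iz2 + p$m2 * p$r2^2
  matrix(c(a1 + 2 * a2 * cos(q2), a3 + a2 * cos(q2),
           a3 + a2 * cos(q2), a3), 2, 2)
}

test_that("inertia matrix matches the closed-form oracle and is SPD", {
  for (q2 in c(0, pi / 2, 1.2, 2.8)) {
    M <- inertia_matrix(p, c(0.3, q2))
    expect_equal(M, inertia_oracle(p, q2), tolerance = 1e-12)
  }
  # symmetry is exact and configuration enters through the elbow only
  set.seed(1)
  for (i in 1:1000) {
    q <- runif(2, -pi, pi)
    M <- inertia_matrix(p, q)
    expect_identical(M[1, 2], M[2, 1])
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_equal(inertia_matrix(p, c(0.7, 1)), inertia_matrix(p, c(-2, 1)))
  # cosine coupling maximal at full extension
  expect_gt(inertia_matrix(p, c(0, 0))[1, 1], inertia_matrix(p, c(0, pi))[1, 1])
})

test_that("Coriolis matrix vanishes at rest and Mdot - 2C is skew-symmetric", {
  expect_equal(coriolis_matrix(p, c(0.3, 1.2), c(0, 0)), matrix(0, 2, 2))
  set.seed(2)
  h <- 1e-6
  for (i in 1:25) {
    q <- runif(2, -2, 2); qd <- runif(2, -3, 3)
    Mdot <- (inertia_matrix(p, q + h * qd) - inertia_matrix(p, q - h * qd)) / (2 * h)
    S <- Mdot - 2 * coriolis_matrix(p, q, qd)
    expect_lt(max(abs(S + t(S))), 1e-8)
  }
})

test_that("Jacobian agrees with numeric differentiation of the kinematics", {
  set.seed(3)
  h <- 1e-7
  for (i in 1:20) {
    q <- c(runif(1, -pi, pi), runif(1, 0.2, 2.9))
    J <- jacobian(p, q)
    for (k in 1:2) {
      dq <- c(0, 0); dq[k] <- h
      num <- (forward_kinematics(p, q + dq) - forward_kinematics(p, q - dq)) / (2 * h)
      expect_equal(J[, k], num, tolerance = 1e-6)
    }
  }
  # kinematic singularity at full extension; controlled point at the elbow
  expect_equal(det(jacobian(p, c(0.5, 0))), 0, tolerance = 1e-12)
  expect_equal(jacobian(p, c(0.5, 1.2), d = 0)[, 2], c(0, 0))
})

test_that("inverse kinematics round-trips and flags the reach boundary", {
  for (x in c(0.25, 0.55))
    expect_gt(inverse_kinematics(p, c(x, 0))$q[2], 0)
  set.seed(4)
  for (i in 1:100) {
    r <- runif(1, abs(p$l1 - p$l2) + 0.02, p$l1 + p$l2 - 0.02)
    th <- runif(1, -pi, pi)
    pt <- r * c(cos(th), sin(th))
    ik <- inverse_kinematics(p, pt)
    expect_equal(forward_kinematics(p, ik$q), pt, tolerance = 1e-9)
    expect_true(ik$q[2] > 0 && ik$q[2] < pi)
  }
  ik <- inverse_kinematics(p, c(p$l1 + p$l2, 0))
  expect_true(ik$singular)
  expect_error(inverse_kinematics(p, c(p$l1 + p$l2 + 0.05, 0)), "reachable")
})

test_that("kinetostatic stiffness transform handles force-dependent terms", {
  q <- c(-0.6, 1.6)
  Kq <- matrix(c(25, 10, 10, 30), 2, 2)
  # zero hand force: pure congruence, symmetry and positive definiteness kept
  Kx0 <- joint_to_cartesian_stiffness(Kq, q, c(0, 0), p)
  J <- jacobian(p, q)
  expect_equal(Kx0, t(solve(J)) %*% Kq %*% solve(J), tolerance = 1e-12)
  expect_equal(Kx0, t(Kx0), tolerance = 1e-10)
  expect_gt(min(eigen(Kx0, symmetric = TRUE, only.values = TRUE)$values), 0)
  # non-zero force: the configuration-dependent term matches a numeric
  # differentiation of tau = J^T F at fixed F
  Fh <- c(4, -3)
  h <- 1e-7
  G_num <- matrix(0, 2, 2)
  for (k in 1:2) {
    dq <- c(0, 0); dq[k] <- h
    G_num[, k] <- (t(jacobian(p, q + dq)) %*% Fh -
                   t(jacobian(p, q - dq)) %*% Fh) / (2 * h)
  }
  Kx <- joint_to_cartesian_stiffness(Kq, q, Fh, p)
  expect_equal(Kx, t(solve(J)) %*% (Kq - G_num) %*% solve(J), tolerance = 1e-6)
  # for a constant (dead-load) hand force, Gamma is the Hessian of the
  # scalar F.x(q), hence symmetric: a symmetric Kq keeps K_x symmetric;
  # the dynamic asymmetry of the arm lives in the Coriolis-derivative
  # matrix instead (see the dynamic-field and steady-state tests)
  expect_equal(G_num, t(G_num), tolerance = 1e-6)
  expect_lt(max(abs(Kx - t(Kx))) / max(abs(Kx)), 1e-6)
  expect_error(joint_to_cartesian_stiffness(Kq, c(0.5, 0), c(0, 0), p), "singular")
})

test_that("dynamic field matrix is the positional derivative of the Coriolis torque", {
  expect_equal(dynamic_field_matrix(p, c(0.3, 1.2), c(0, 0)), matrix(0, 2, 2))
  set.seed(5)
  h <- 1e-6
  for (i in 1:10) {
    q <- runif(2, -2, 2); qd <- runif(2, -2, 2)
    D <- dynamic_field_matrix(p, q, qd)
    D_num <- matrix(0, 2, 2)
    for (k in 1:2) {
      dq <- c(0, 0); dq[k] <- h
      D_num[, k] <- (coriolis_matrix(p, q + dq, qd) %*% qd -
                     coriolis_matrix(p, q - dq, qd) %*% qd) / (2 * h)
    }
    expect_equal(D, D_num, tolerance = 1e-6)
  }
  # asymmetric at mid-movement speeds
  D <- dynamic_field_matrix(p, c(-0.5, 1.5), c(0.8, -0.6))
  expect_gt(max(abs(D - t(D))), 1e-3)
})

test_that("inertia square root factors and inverts exactly", {
  expect_equal(normalize_system(diag(2))$M_half, diag(2))
  expect_equal(normalize_system(diag(c(4, 9)))$M_half, diag(c(2, 3)))
  M <- inertia_matrix(p, c(0, pi / 2))
  ns <- normalize_system(M)
  expect_equal(ns$M_half %*% ns$M_half, M, tolerance = 1e-10)
  expect_equal(ns$M_half_inv %*% M %*% ns$M_half_inv, diag(2), tolerance = 1e-10)
  expect_error(normalize_system(matrix(c(1, 2, 2, 1), 2, 2)), "positive definite")
})

test_that("free rigid-arm energy is conserved by the integrator", {
  out <- simulate_rigid_free(p, q0 = c(0.3, 1.4), qdot0 = c(1.2, -0.8),
                             t_total = 5, fs = 500)
  drift <- abs(out$energy - out$energy[1]) / out$energy[1]
  expect_lt(max(drift), 1e-6)
})
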