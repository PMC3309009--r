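#' Anthropometric parameters of the planar two-link arm
#'
#' Bundles the body-segment parameters (BSP) of the upper-arm link (shoulder
#' joint, index 1) and the forearm+hand link (elbow joint, index 2): segment
#' lengths, proximal-joint-to-centre-of-mass distances, masses, and moments of
#' inertia about the segment centre of mass (z axis, orthogonal to the plane
#' of movement). All quantities in SI units.
#'
#' @param l1,l2 segment lengths (m)
#' @param r1,r2 distance from the proximal joint to the segment COM (m)
#' @param m1,m2 segment masses (kg)
#' @param Iz1,Iz2 segment moments of inertia about the COM, z axis (kg m^2)
#' @return an object of class `arm_params`
#' @export
arm_params <- function(l1, r1, m1, Iz1, l2, r2, m2, Iz2) {
  p <- list(l1 = l1, r1 = r1, m1 = m1, Iz1 = Iz1,
            l2 = l2, r2 = r2, m2 = m2, Iz2 = Iz2)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arm parameters must be finite and strictly positive")
  if (p$r1 > p$l1 || p$r2 > p$l2)
    stop("segment COM must lie within the segment (r_i <= l_i)")
  structure(p, class = "arm_params")
}

#' Default body-segment parameter set
#'
#' BSP values for one averagely built adult used throughout the simulations
#' (Zatsiorsky-style regression estimates).
#' @return an `arm_params` object
#' @export
arm_params_default <- function() {
  arm_params(l1 = 0.29, r1 = 0.132, m1 = 1.99, Iz1 = 0.0161,
             l2 = 0.40, r2 = 0.17,  m2 = 1.10, Iz2 = 0.0146)
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar two-link arm parameters (SI units):\n")
  cat(sprintf("  upper arm   : l1=%.3f m, r1=%.3f m, m1=%.2f kg, Iz1=%.4f kg m^2\n",
              x$l1, x$r1, x$m1, x$Iz1))
  cat(sprintf("  forearm+hand: l2=%.3f m, r2=%.3f m, m2=%.2f kg, Iz2=%.4f kg m^2\n",
              x$l2, x$r2, x$m2, x$Iz2))
  invisible(x)
}

#' Serialize arm parameters to / from a flat key-value list
#'
#' @param x an `arm_params` object
#' @param lst a named list or vector with keys l1, r1, m1, Iz1, l2, r2, m2, Iz2
#' @return `arm_params_to_list` returns a plain named list;
#'   `arm_params_from_list` an `arm_params` object.
#' @export
arm_params_to_list <- function(x) {
  stopifnot(inherits(x, "arm_params"))
  lapply(unclass(x), identity)
}

#' @rdname arm_params_to_list
#' @export
arm_params_from_list <- function(lst) {
  keys <- c("l1", "r1", "m1", "Iz1", "l2", "r2", "m2", "Iz2")
  if (!all(keys %in% names(lst)))
    stop("missing arm parameter keys: ", paste(setdiff(keys, names(lst)), collapse = ", "))
  do.call(arm_params, lapply(lst[keys], as.numeric))
}

#' Inertia matrix of the two-link arm
#'
#' Rigid-body inertia M(q) in joint coordinates. Depends on the configuration
#' only through the elbow angle `q[2]` (relative elbow angle, 0 = full
#' extension).
#'
#' @param params `arm_params`
#' @param q joint angles, length-2 numeric (rad), `[shoulder, elbow]`
#' @return symmetric positive-definite 2x2 matrix (kg m^2)
#' @export
inertia_matrix <- function(params, q) {
  c2 <- cos(q[2])
  with(params, {
    m22 <- Iz2 + m2 * r2^2
    m12 <- m22 + m2 * l1 * r2 * c2
    m11 <- Iz1 + m1 * r1^2 + m22 + m2 * (l1^2 + 2 * l1 * r2 * c2)
    matrix(c(m11, m12, m12, m22), 2, 2)
  })
}

#' Coriolis/centripetal matrix of the two-link arm
#'
#' Returns C(q, qdot) such that the Coriolis and centripetal torques are
#' `C %*% qdot` and `dM/dt - 2 C` is skew-symmetric.
#'
#' @inheritParams inertia_matrix
#' @param qdot joint angular velocities (rad/s)
#' @return 2x2 matrix (kg m^2 / s)
#' @export
coriolis_matrix <- function(params, q, qdot) {
  h <- params$m2 * params$l1 * params$r2 * sin(q[2])
  matrix(c(-h * qdot[2], h * qdot[1],
           -h * (qdot[1] + qdot[2]), 0), 2, 2)
}

#' Forward kinematics of a point on the forearm link
#'
#' Position of the point at distance `d` from the elbow along link 2,
#' origin at the shoulder.
#'
#' @inheritParams inertia_matrix
#' @param d distance of the controlled point from the elbow along link 2 (m);
#'   default is the full forearm+hand length (hand COM convention)
#' @return numeric length-2 `(x, y)` in metres
#' @export
forward_kinematics <- function(params, q, d = params$l2) {
  c(params$l1 * cos(q[1]) + d * cos(q[1] + q[2]),
    params$l1 * sin(q[1]) + d * sin(q[1] + q[2]))
}

#' Jacobian of the controlled point
#'
#' Analytic Jacobian of [forward_kinematics()] with respect to the joint
#' angles. Singular when the elbow is at full extension or full flexion.
#'
#' @inheritParams forward_kinematics
#' @return 2x2 matrix (m/rad)
#' @export
jacobian <- function(params, q, d = params$l2) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-params$l1 * s1 - d * s12, params$l1 * c1 + d * c12,
           -d * s12, d * c12), 2, 2)
}

#' Inverse kinematics for the controlled point
#'
#' Closed-form two-link inverse kinematics for the point at distance `d`
#' along link 2. By default the elbow-positive branch (elbow angle in
#' `(0, pi)`) is selected, matching the arm geometry used in the simulations.
#'
#' @inheritParams forward_kinematics
#' @param p target point, numeric `(x, y)` in metres (shoulder origin)
#' @param elbow_up logical; `TRUE` selects the branch with positive elbow angle
#' @return list with `q` (joint angles, rad) and `singular` (logical flag set
#'   when the target lies on the reach boundary)
#' @export
inverse_kinematics <- function(params, p, d = params$l2, elbow_up = TRUE) {
  l1 <- params$l1
  rr <- sqrt(sum(p^2))
  if (rr > l1 + d + 1e-12 || rr < abs(l1 - d) - 1e-12)
    stop(sprintf("point (%.3f, %.3f) is not reachable (|l1-d|=%.3f <= r <= l1+d=%.3f)",
                 p[1], p[2], abs(l1 - d), l1 + d))
  cq2 <- (rr^2 - l1^2 - d^2) / (2 * l1 * d)
  cq2 <- min(1, max(-1, cq2))
  q2 <- acos(cq2)
  if (!elbow_up) q2 <- -q2
  q1 <- atan2(p[2], p[1]) - atan2(d * sin(q2), l1 + d * cos(q2))
  singular <- abs(sin(q2)) < 1e-6
  list(q = c(q1, q2), singular = singular)
}

# Analytic configuration-dependent correction d(J^T F)/dq at fixed hand force.
# Gamma_{ij} = d (J^T F)_i / d q_j.
kinetostatic_gamma <- function(params, q, F_hand, d = params$l2) {
  l1 <- params$l1
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  Fx <- F_hand[1]; Fy <- F_hand[2]
  # (J^T F)_1 = (-l1 s1 - d s12) Fx + (l1 c1 + d c12) Fy
  # (J^T F)_2 = (-d s12) Fx + (d c12) Fy
  g11 <- (-l1 * c1 - d * c12) * Fx + (-l1 * s1 - d * s12) * Fy
  g12 <- (-d * c12) * Fx + (-d * s12) * Fy
  g21 <- g12
  g22 <- g12
  matrix(c(g11, g21, g12, g22), 2, 2)
}

#' Joint-to-Cartesian stiffness transform
#'
#' Kinetostatic mapping of a joint stiffness matrix to endpoint (Cartesian)
#' stiffness, `K_x = J^-T (Kq - Gamma) J^-1`, where `Gamma = d(J^T F)/dq` is
#' the configuration-dependent correction that appears when a non-zero force
#' is applied at the hand. With `F_hand = 0` this reduces to the congruence
#' transform and preserves symmetry.
#'
#' @inheritParams forward_kinematics
#' @param Kq joint stiffness, 2x2 (Nm/rad)
#' @param F_hand force applied at the hand, numeric `(Fx, Fy)` in N
#' @return 2x2 endpoint stiffness (N/m)
#' @export
joint_to_cartesian_stiffness <- function(Kq, q, F_hand = c(0, 0), params = arm_params_default(),
                                         d = params$l2) {
  J <- jacobian(params, q, d)
  dj <- det(J)
  if (abs(dj) < 1e-10)
    stop("Jacobian is singular at this configuration; endpoint stiffness undefined")
  G <- kinetostatic_gamma(params, q, F_hand, d)
  Jinv <- solve(J)
  t(Jinv) %*% (Kq - G) %*% Jinv
}

#' Positional derivative of the Coriolis/centripetal torques
#'
#' The matrix `D(q, qdot) = d(C(q, qdot) qdot)/dq` entering the variational
#' (perturbation) dynamics along a reference trajectory. Generally
#' non-symmetric; it vanishes at rest.
#'
#' @inheritParams coriolis_matrix
#' @return 2x2 matrix
#' @export
dynamic_field_matrix <- function(params, q, qdot) {
  hc <- params$m2 * params$l1 * params$r2 * cos(q[2])
  matrix(c(0, 0,
           -hc * (2 * qdot[1] * qdot[2] + qdot[2]^2),
           hc * qdot[1]^2), 2, 2)
}

# Velocity derivative of the Coriolis/centripetal torques,
# V = d(C(q,qdot) qdot)/dqdot, used in the linearized dynamics.
coriolis_velocity_matrix <- function(params, q, qdot) {
  h <- params$m2 * params$l1 * params$r2 * sin(q[2])
  matrix(c(-2 * h * qdot[2], 2 * h * qdot[1],
           -2 * h * (qdot[1] + qdot[2]), 0), 2, 2)
}

# Positional derivative of the inertial torque M(q) qddot along the reference,
# d(M(q) qddot)/dq; only the elbow column is non-zero.
inertial_position_matrix <- function(params, q, qddot) {
  hs <- params$m2 * params$l1 * params$r2 * sin(q[2])
  dM <- matrix(c(-2 * hs, -hs, -hs, 0), 2, 2)
  cbind(c(0, 0), dM %*% qddot)
}

#' Symmetric positive-definite matrix square root
#'
#' @param M symmetric positive-definite matrix
#' @return list with `M_half`, `M_half_inv` and the original `M`
#' @export
normalize_system <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  M_half <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  M_half_inv <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  structure(list(M = M, M_half = M_half, M_half_inv = M_half_inv),
            class = "normalized_system")
}
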