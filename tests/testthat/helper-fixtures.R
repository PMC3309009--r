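# Shared fixtures, computed lazily and cached for the session: full
# pipeline runs are expensive, and many tests interrogate the same
# simulated free response.
.fx <- new.env(parent = emptyenv())

fx_params <- function() arm_params_default()

fx_posture_traj <- function() {
  if (is.null(.fx$posture_traj))
    .fx$posture_traj <- reference_trajectory(
      trajectory_spec(start = c(0.4, 0), mode = "posture"),
      fx_params(), fs = 4000)
  .fx$posture_traj
}

fx_reach_traj <- function() {
  if (is.null(.fx$reach_traj))
    .fx$reach_traj <- reference_trajectory(trajectory_spec(mode = "reach"),
                                           fx_params(), fs = 4000)
  .fx$reach_traj
}

fx_impulse <- function(direction = 3)
  perturbation_spec("force_impulse", direction = octant_direction(direction))

# posture free response of the constant reference Kelvin-Voigt arm
fx_posture_record <- function() {
  if (is.null(.fx$posture_record))
    .fx$posture_record <- simulate_record(kv_reference(), fx_posture_traj(),
                                          fx_impulse())
  .fx$posture_record
}

fx_posture_estimate <- function() {
  if (is.null(.fx$posture_estimate))
    .fx$posture_estimate <- estimate_impedance(fx_posture_record())
  .fx$posture_estimate
}

# frozen-time damped modal truth of a (possibly gain-scaled) KV arm at a
# configuration: quadratic-pencil eigenvalues, sorted by |Im|
fx_qep_truth <- function(model, q, params = fx_params(), t = 0) {
  M <- inertia_matrix(params, q)
  imp <- imposed_impedance(model, t)
  quadratic_eigen(M, imp$C[, , 1], imp$K[, , 1])
}

# random well-separated underdamped 2-dof systems for stationary checks
fx_random_system <- function(seed) {
  set.seed(seed)
  # SPD stiffness with eigenvalues in a physiological band, light damping
  th <- runif(1, 0, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  K <- R %*% diag(runif(2, c(15, 45), c(25, 70))) %*% t(R)
  C <- R %*% diag(runif(2, 0.15, 0.45)) %*% t(R) +
    diag(runif(2, 0, 0.05))
  list(K = (K + t(K)) / 2, C = (C + t(C)) / 2)
}
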