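#' Time-varying gain profiles
#'
#' Scalar dimensionless multipliers g(t) applied to the reference stiffness or
#' damping matrices. All profiles equal 1 up to the onset time and (for the
#' non-constant ones) approach a final plateau gain. Four shapes are
#' provided:
#' \describe{
#'   \item{constant}{g(t) = 1 everywhere.}
#'   \item{sigmoid}{logistic rise, 10--90% rise time `rise` (default 1 s).}
#'   \item{sharp}{logistic rise with a fast 10--90% rise time (default 0.1 s).}
#'   \item{sinlin}{unit baseline plus a linear ramp and one full sinusoid
#'     cycle spanning `period` seconds after onset, holding the final gain
#'     afterwards.}
#' }
#'
#' @param name one of `"constant"`, `"sigmoid"`, `"sinlin"`, `"sharp"`
#' @param t_onset time at which the profile starts changing (s)
#' @param final_gain plateau gain reached by the non-constant profiles
#' @param rise 10--90% rise time of the logistic profiles (s); defaults to
#'   1 s for `sigmoid` and 0.1 s for `sharp`
#' @param midpoint centre of the logistic rise (s); default `t_onset + 0.75`
#'   for `sigmoid` and `t_onset + 0.2` for `sharp`
#' @param amplitude sinusoid amplitude of the `sinlin` profile (gain units)
#' @param period ramp/sinusoid span of the `sinlin` profile (s)
#' @return an object of class `gain_profile`
#' @export
gain_profile <- function(name = c("constant", "sigmoid", "sinlin", "sharp"),
                         t_onset = 2.5, final_gain = 2,
                         rise = NULL, midpoint = NULL,
                         amplitude = 0.25, period = 2.5) {
  name <- match.arg(name)
  if (is.null(rise)) rise <- switch(name, sharp = 0.1, 1.0)
  if (is.null(midpoint)) midpoint <- t_onset + switch(name, sharp = 0.2, 0.75)
  if (final_gain <= 0) stop("final_gain must be positive")
  structure(list(name = name, t_onset = t_onset, final_gain = final_gain,
                 rise = rise, midpoint = midpoint,
                 amplitude = amplitude, period = period),
            class = "gain_profile")
}

#' Evaluate a gain profile
#'
#' @param profile a [gain_profile()]
#' @param t time(s) in seconds, vectorized
#' @return numeric vector of positive gains; exactly 1 for `t <= t_onset`
#' @export
gain <- function(profile, t) {
  stopifnot(inherits(profile, "gain_profile"))
  p <- profile
  g <- switch(p$name,
    constant = rep(1, length(t)),
    sigmoid = ,
    sharp = {
      k <- 2 * log(9) / p$rise
      s <- stats::plogis(k * (t - p$midpoint))
      s0 <- stats::plogis(k * (p$t_onset - p$midpoint))
      # rescale so the profile leaves exactly 1 at onset and tops out at final_gain
      1 + (p$final_gain - 1) * pmax(0, (s - s0) / (1 - s0))
    },
    sinlin = {
      u <- pmin(pmax(t - p$t_onset, 0), p$period)
      1 + (p$final_gain - 1) * u / p$period +
        p$amplitude * sin(2 * pi * u / p$period)
    })
  g[t <= p$t_onset] <- 1
  if (any(g <= 0)) stop("gain profile is not strictly positive; reduce 'amplitude'")
  g
}

check_sym_2x2 <- function(A, what) {
  if (!is.matrix(A) || !all(dim(A) == c(2, 2)))
    stop(what, " must be a 2x2 matrix")
  if (max(abs(A - t(A))) > 1e-10 * max(1, max(abs(A))))
    stop(what, " must be symmetric")
  invisible(A)
}

#' Kelvin-Voigt viscoelastic model
#'
#' Spring and damper in parallel, with independent time-varying gains on the
#' stiffness and damping matrices and an optional rotation `phi` of the
#' damping eigenvectors that renders the system non-classically damped.
#'
#' @param K0 reference joint stiffness, symmetric positive-definite 2x2 (Nm/rad)
#' @param C0 reference joint damping, symmetric positive-semi-definite 2x2 (Nm s/rad)
#' @param gK,gC [gain_profile()]s modulating stiffness and damping
#' @param phi rotation angle of the damping eigenvectors (rad); `phi = 0`
#'   keeps the system classically damped whenever `C0` commutes with `K0`
#' @return object of class `kv_model`
#' @export
kv_model <- function(K0, C0, gK = gain_profile("constant"),
                     gC = gain_profile("constant"), phi = 0) {
  check_sym_2x2(K0, "K0"); check_sym_2x2(C0, "C0")
  if (any(eigen(K0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("K0 must be positive definite")
  if (any(eigen(C0, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("C0 must be positive semi-definite")
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  structure(list(K0 = K0, C0 = C0, C_rot = R %*% C0 %*% t(R),
                 gK = gK, gC = gC, phi = phi),
            class = c("kv_model", "ve_model"))
}

#' Reference Kelvin-Voigt parameter set
#'
#' Literature-compatible reference joint stiffness and damping for a planar
#' reaching task: shoulder/elbow stiffness of the order of tens of Nm/rad
#' with positive inter-joint coupling, and sub-Nm s/rad damping as reported
#' for postural and single-joint measurements.
#'
#' @param gK,gC gain profiles for stiffness and damping
#' @param phi damping eigenvector rotation (rad)
#' @param amplify_damping multiply the reference damping (use 4 for the
#'   "significant damping" preset, whose elbow damping reaches 1.75 Nm s/rad)
#' @return a `kv_model`
#' @export
kv_reference <- function(gK = gain_profile("constant"),
                         gC = gain_profile("constant"),
                         phi = 0, amplify_damping = 1) {
  K0 <- matrix(c(29.5, 14.3, 14.3, 39.3), 2, 2)
  C0 <- matrix(c(0.42, 0.10, 0.10, 0.22), 2, 2) * amplify_damping
  kv_model(K0, C0, gK = gK, gC = gC, phi = phi)
}

#' Kelvin-Voigt restoring torque
#'
#' `tau = gK(t) K0 dq + gC(t) R(phi) C0 R(phi)^T dqdot`.
#'
#' @param model a [kv_model()]
#' @param t time (s)
#' @param dq,dqdot joint-angle deviation (rad) and its rate (rad/s)
#' @return length-2 torque vector (Nm)
#' @export
kv_torque <- function(model, t, dq, dqdot) {
  drop(gain(model$gK, t) * model$K0 %*% dq +
       gain(model$gC, t) * model$C_rot %*% dqdot)
}

#' Poynting-Thomson (muscle-tendon) viscoelastic model
#'
#' A Kelvin-Voigt element (muscle fibres: stiffness `K_f`, damping `C_f`) in
#' series with a tendon spring `K_t`. The coupled arm system is third order
#' per degree of freedom; the internal state is the tendon deflection.
#'
#' @param K_t series (tendon) stiffness, symmetric PD 2x2 (Nm/rad)
#' @param K_f parallel (fibre) stiffness, symmetric PD 2x2 (Nm/rad)
#' @param C_f fibre damping, symmetric PD 2x2 (Nm s/rad)
#' @return object of class `pt_model`
#' @export
pt_model <- function(K_t, K_f, C_f) {
  check_sym_2x2(K_t, "K_t"); check_sym_2x2(K_f, "K_f"); check_sym_2x2(C_f, "C_f")
  for (nm in c("K_t", "K_f")) {
    A <- get(nm)
    if (any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop(nm, " must be positive definite")
  }
  structure(list(K_t = K_t, K_f = K_f, C_f = C_f, C_f_inv = solve(C_f)),
            class = c("pt_model", "ve_model"))
}

#' Reference Poynting-Thomson parameter set
#'
#' Placeholder defaults compatible with reported muscle-tendon measures:
#' fibre stiffness and damping at the Kelvin-Voigt reference values and a
#' tendon stiffness ten times stiffer than the fibres (well inside the
#' oscillatory regime for physiological damping).
#' @param tendon_ratio tendon-to-fibre stiffness ratio
#' @return a `pt_model`
#' @export
pt_reference <- function(tendon_ratio = 10) {
  kv <- kv_reference()
  pt_model(K_t = tendon_ratio * kv$K0, K_f = kv$K0, C_f = kv$C0)
}

#' Poynting-Thomson torque and internal-state derivative
#'
#' First-order form of the series-tendon/parallel-fibre network. With tendon
#' deflection `u` as the auxiliary state, the fibre stretch is `dq - u` and
#' \deqn{C_f du/dt = C_f dqdot - (K_t + K_f) u + K_f dq, \quad tau = K_t u.}
#' As `K_t` grows the tendon deflection collapses and the torque converges to
#' the Kelvin-Voigt torque of `(K_f, C_f)`.
#'
#' @param model a [pt_model()]
#' @param dq,dqdot joint deviation (rad) and rate (rad/s)
#' @param aux_state tendon deflection, length-2 (rad)
#' @return list with `torque` (Nm) and `aux_dot` (rad/s)
#' @export
pt_state_derivative <- function(model, dq, dqdot, aux_state) {
  u <- aux_state
  udot <- dqdot - drop(model$C_f_inv %*% ((model$K_t + model$K_f) %*% u - model$K_f %*% dq))
  list(torque = drop(model$K_t %*% u), aux_dot = udot)
}

#' Steady-state (series) stiffness of a Poynting-Thomson model
#'
#' Static torque per unit deflection: the series combination
#' `K_t (K_t + K_f)^-1 K_f`.
#' @param model a [pt_model()]
#' @return 2x2 matrix (Nm/rad)
#' @export
pt_series_stiffness <- function(model) {
  model$K_t %*% solve(model$K_t + model$K_f) %*% model$K_f
}

#' Oscillatory condition of the scalar Poynting-Thomson free response
#'
#' The scalar third-order system `m xdd = -k_t u`, `c_f (xd - ud) =
#' (k_t + k_f) u - k_f x` has characteristic polynomial
#' \deqn{\lambda^3 + \frac{k_t + k_f}{c_f}\lambda^2 + \frac{k_t}{m}\lambda
#'       + \frac{k_t k_f}{m c_f} = 0.}
#' The free response is oscillatory iff the cubic has a complex-conjugate
#' pair, i.e. its discriminant is negative. A non-oscillatory region (in the
#' fibre damping) exists only when the tendon/fibre stiffness ratio exceeds
#' eight.
#'
#' @param k_tendon,k_fiber,c_fiber,inertia positive scalars
#' @return logical: `TRUE` if the free response has a complex pole pair
#' @export
pt_is_oscillatory <- function(k_tendon, k_fiber, c_fiber, inertia) {
  stopifnot(k_tendon > 0, k_fiber > 0, c_fiber > 0, inertia > 0)
  b <- (k_tendon + k_fiber) / c_fiber
  cc <- k_tendon / inertia
  d <- k_tendon * k_fiber / (inertia * c_fiber)
  disc <- 18 * b * cc * d - 4 * b^3 * d + b^2 * cc^2 - 4 * cc^3 - 27 * d^2
  disc < 0
}

#' Duffing (cubic hardening) viscoelastic model
#'
#' Linear stiffness and damping plus a componentwise cubic stiffness term
#' approximating tendon slack: `tau = K dq + K3 dq^3 + C dqdot`.
#'
#' @param K,C linear stiffness and damping, symmetric 2x2
#' @param K3 cubic stiffness coefficients, 2x2 with non-negative entries
#'   (Nm/rad^3); diagonal by default
#' @return object of class `duffing_model`
#' @export
duffing_model <- function(K, C, K3) {
  check_sym_2x2(K, "K"); check_sym_2x2(C, "C")
  if (!is.matrix(K3) || !all(dim(K3) == c(2, 2)) || any(K3 < 0))
    stop("K3 must be a 2x2 matrix with non-negative entries (hardening)")
  structure(list(K = K, C = C, K3 = K3),
            class = c("duffing_model", "ve_model"))
}

#' Reference Duffing parameter set
#'
#' Linear part at the Kelvin-Voigt reference; the cubic coefficient is sized
#' so that at the joint oscillation amplitude induced by the standard
#' 5 N / 20 ms impulse (about 0.015 rad) the cubic term contributes roughly
#' 20% of the restoring torque.
#' @return a `duffing_model`
#' @export
duffing_reference <- function() {
  kv <- kv_reference()
  duffing_model(K = kv$K0, C = kv$C0, K3 = diag(c(30000, 30000)))
}

#' Duffing restoring torque
#'
#' @param model a [duffing_model()]
#' @param dq,dqdot joint deviation (rad) and rate (rad/s)
#' @return length-2 torque vector (Nm)
#' @export
duffing_torque <- function(model, dq, dqdot) {
  drop(model$K %*% dq + model$K3 %*% (dq^3) + model$C %*% dqdot)
}

# --- internal generic surface used by the simulator -------------------------

ve_state_dim <- function(model) if (inherits(model, "pt_model")) 2L else 0L

# torque (and auxiliary-state derivative when the model carries state)
ve_force <- function(model, t, dq, dqdot, aux = NULL) {
  if (inherits(model, "kv_model")) {
    list(torque = kv_torque(model, t, dq, dqdot), aux_dot = NULL)
  } else if (inherits(model, "pt_model")) {
    pt_state_derivative(model, dq, dqdot, aux)
  } else if (inherits(model, "duffing_model")) {
    list(torque = duffing_torque(model, dq, dqdot), aux_dot = NULL)
  } else stop("unknown viscoelastic model")
}

#' Imposed (ground-truth) stiffness and damping of a model at given times
#'
#' Returns the instantaneous linear stiffness and damping matrices imposed by
#' the simulation, used as ground truth when scoring estimates. For the
#' Poynting-Thomson model the low-frequency (series) stiffness and the fibre
#' damping are returned; for the Duffing model the linear part.
#'
#' @param model a viscoelastic model object
#' @param t vector of times (s)
#' @return list of `K` and `C`, each a `2 x 2 x length(t)` array
#' @export
imposed_impedance <- function(model, t) {
  n <- length(t)
  K <- array(0, c(2, 2, n)); C <- array(0, c(2, 2, n))
  if (inherits(model, "kv_model")) {
    gk <- gain(model$gK, t); gc <- gain(model$gC, t)
    for (i in seq_len(n)) { K[, , i] <- gk[i] * model$K0; C[, , i] <- gc[i] * model$C_rot }
  } else if (inherits(model, "pt_model")) {
    Ks <- pt_series_stiffness(model)
    for (i in seq_len(n)) { K[, , i] <- Ks; C[, , i] <- model$C_f }
  } else {
    for (i in seq_len(n)) { K[, , i] <- model$K; C[, , i] <- model$C }
  }
  list(K = K, C = C)
}
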