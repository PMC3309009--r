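#' Reference trajectory specification
#'
#' Straight-line reach with a sigmoidal time course, or a static posture.
#' The hand path runs from `start` to `target` (shoulder-centred
#' coordinates); the logistic time course crosses the midpoint at `t_mid`
#' and its 10--90% traversal takes `effective_duration` seconds, so the
#' sigmoid starts with essentially zero curvature.
#'
#' @param start,target hand waypoints `(x, y)` in metres
#' @param t_total total simulated time (s)
#' @param effective_duration time between 10% and 90% of the displacement (s)
#' @param t_mid time at which the path midpoint is crossed (s)
#' @param mode `"reach"` or `"posture"` (posture holds `start`)
#' @return object of class `trajectory_spec`
#' @export
trajectory_spec <- function(start = c(0.25, 0), target = c(0.55, 0),
                            t_total = 7.5, effective_duration = 1.5,
                            t_mid = 2.5, mode = c("reach", "posture")) {
  mode <- match.arg(mode)
  structure(list(start = start, target = target, t_total = t_total,
                 effective_duration = effective_duration, t_mid = t_mid,
                 mode = mode),
            class = "trajectory_spec")
}

# dJ/dt along a trajectory (analytic)
jacobian_dot <- function(params, q, qdot, d = params$l2) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  w1 <- qdot[1]; w12 <- qdot[1] + qdot[2]
  matrix(c(-params$l1 * c1 * w1 - d * c12 * w12,
           -params$l1 * s1 * w1 - d * s12 * w12,
           -d * c12 * w12,
           -d * s12 * w12), 2, 2)
}

#' Generate the reference joint-space trajectory
#'
#' Samples the trajectory at `fs`, converts hand kinematics to joint space
#' through inverse kinematics, and differentiates analytically
#' (`qdot = J^-1 v`, `qddot = J^-1 (a - Jdot qdot)`).
#'
#' @param spec a [trajectory_spec()]
#' @param params an [arm_params()]
#' @param d controlled-point distance from the elbow along link 2 (m)
#' @param fs sampling rate (Hz)
#' @return object of class `joint_trajectory`: time vector plus `2 x N`
#'   matrices `q`, `qdot`, `qddot`, `x` (hand position)
#' @export
reference_trajectory <- function(spec, params = arm_params_default(),
                                 d = params$l2, fs = 4000) {
  t <- seq(0, spec$t_total, by = 1 / fs)
  n <- length(t)
  delta <- spec$target - spec$start
  if (spec$mode == "posture" || sqrt(sum(delta^2)) < 1e-12) {
    q0 <- inverse_kinematics(params, spec$start, d)$q
    out <- list(t = t, q = matrix(q0, 2, n), qdot = matrix(0, 2, n),
                qddot = matrix(0, 2, n), x = matrix(spec$start, 2, n))
  } else {
    k <- 2 * log(9) / spec$effective_duration
    s <- stats::plogis(k * (t - spec$t_mid))
    sd <- k * s * (1 - s)
    sdd <- k * sd * (1 - 2 * s)
    x <- rbind(spec$start[1] + delta[1] * s, spec$start[2] + delta[2] * s)
    v <- rbind(delta[1] * sd, delta[2] * sd)
    a <- rbind(delta[1] * sdd, delta[2] * sdd)
    q <- qd <- qdd <- matrix(0, 2, n)
    for (i in seq_len(n)) {
      ik <- inverse_kinematics(params, x[, i], d)
      q[, i] <- ik$q
      J <- jacobian(params, ik$q, d)
      qd[, i] <- solve(J, v[, i])
      Jd <- jacobian_dot(params, ik$q, qd[, i], d)
      qdd[, i] <- solve(J, a[, i] - Jd %*% qd[, i])
    }
    out <- list(t = t, q = q, qdot = qd, qddot = qdd, x = x)
  }
  out$fs <- fs; out$spec <- spec; out$params <- params; out$d <- d
  class(out) <- "joint_trajectory"
  out
}

#' Perturbation specification
#'
#' @param kind `"force_impulse"` (default 5 N for 20 ms),
#'   `"force_pulse"` (default 5 N for 200 ms), or `"servo_displacement"`
#'   (ramp-plateau-ramp hand displacement, default 8 mm over 100/100/100 ms)
#' @param magnitude force magnitude (N) or displacement amplitude (m)
#' @param duration total duration (s); for the servo kind the sum of the three
#'   segments in `ramp`
#' @param direction unit 2-vector, or an octant index 1--8 (45 degree spacing)
#' @param t_onset perturbation onset (s)
#' @param ramp servo segment durations `(ramp-up, plateau, ramp-down)` (s)
#' @return object of class `perturbation_spec`
#' @export
perturbation_spec <- function(kind = c("force_impulse", "force_pulse", "servo_displacement"),
                              magnitude = NULL, duration = NULL,
                              direction = c(1, 0), t_onset = 2.5,
                              ramp = c(0.1, 0.1, 0.1)) {
  kind <- match.arg(kind)
  if (is.null(magnitude))
    magnitude <- switch(kind, servo_displacement = 0.008, 5)
  if (is.null(duration))
    duration <- switch(kind, force_impulse = 0.02, force_pulse = 0.2,
                       servo_displacement = sum(ramp))
  if (length(direction) == 1)
    direction <- c(cos((direction - 1) * pi / 4), sin((direction - 1) * pi / 4))
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("perturbation direction must be non-zero")
  direction <- direction / nrm
  if (duration <= 0) stop("perturbation duration must be positive")
  structure(list(kind = kind, magnitude = magnitude, duration = duration,
                 direction = direction, t_onset = t_onset, ramp = ramp),
            class = "perturbation_spec")
}

#' Octant unit directions
#' @param i index 1--8 (45 degree spacing, 1 = +x)
#' @return unit 2-vector
#' @export
octant_direction <- function(i) {
  c(cos((i - 1) * pi / 4), sin((i - 1) * pi / 4))
}

# force at time t for a force-type perturbation (vectorized over t)
perturbation_force <- function(pert, t) {
  on <- as.numeric(t >= pert$t_onset & t < pert$t_onset + pert$duration)
  rbind(pert$magnitude * pert$direction[1] * on,
        pert$magnitude * pert$direction[2] * on)
}

# servo displacement profile (scalar amplitude vs time): ramp-plateau-ramp
servo_profile <- function(pert, t) {
  u <- t - pert$t_onset
  r <- pert$ramp
  amp <- numeric(length(t))
  amp[u >= 0 & u < r[1]] <- pert$magnitude * u[u >= 0 & u < r[1]] / r[1]
  amp[u >= r[1] & u < r[1] + r[2]] <- pert$magnitude
  i3 <- u >= r[1] + r[2] & u < sum(r)
  amp[i3] <- pert$magnitude * (sum(r) - u[i3]) / r[3]
  amp
}

#' Noise specification
#'
#' @param mode `"none"`, `"constant_snr"` (i.i.d. Gaussian at a fixed SNR) or
#'   `"sdn"` (signal-dependent: noise std follows a gain profile, reaching the
#'   configured SNR floor at peak gain)
#' @param snr_db signal-to-noise ratio, RMS convention (dB)
#' @param seed RNG seed for reproducibility
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(mode = c("none", "constant_snr", "sdn"),
                       snr_db = 20, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

# linear interpolation closure over a 2x2xN array on grid tt
interp_mat22 <- function(tt, A) {
  f <- vector("list", 4)
  for (k in 1:4) {
    i <- (k - 1) %% 2 + 1; j <- (k - 1) %/% 2 + 1
    f[[k]] <- stats::approxfun(tt, A[i, j, ], rule = 2)
  }
  function(t) matrix(c(f[[1]](t), f[[2]](t), f[[3]](t), f[[4]](t)), 2, 2)
}

#' Simulate the perturbed variational dynamics
#'
#' Integrates the joint-angle deviation `dq` about the imposed reference
#' trajectory:
#' \deqn{M(q_r)\,\delta\ddot q + V(q_r,\dot q_r)\,\delta\dot q +
#'       [D(q_r,\dot q_r) + G_M(q_r,\ddot q_r)]\,\delta q +
#'       f_{ve}(\delta q, \delta\dot q, t) = J^T F_{pert}(t),}
#' where `V` and `D` are the velocity and position derivatives of the
#' Coriolis/centripetal torques, `G_M` the position derivative of the
#' inertial torque, and `f_ve` the internal viscoelastic field of the chosen
#' model. Integration uses an adaptive stiff-capable solver (`lsoda`) in
#' segments aligned with the perturbation edges, with dense output resampled
#' on the trajectory grid.
#'
#' @param model a `kv_model`, `pt_model` or `duffing_model`
#' @param traj a [reference_trajectory()]
#' @param pert a force-type [perturbation_spec()]
#' @param rtol,atol solver tolerances
#' @return object of class `simulation_record` with fields `fs`, `t`,
#'   `q_ref`, `dq`, `dqdot`, `hand_force`, `perturbation`, `noise`, `model`,
#'   `traj`
#' @export
simulate_record <- function(model, traj, pert, rtol = 1e-9, atol = 1e-12) {
  if (pert$kind == "servo_displacement")
    stop("servo perturbations are kinematic; use servo_response()")
  t <- traj$t; fs <- traj$fs; n <- length(t)
  params <- traj$params
  posture <- traj$spec$mode == "posture"
  nav <- ve_state_dim(model)

  if (posture) {
    q0 <- traj$q[, 1]
    M <- inertia_matrix(params, q0)
    Minv <- solve(M)
    Jt <- t(jacobian(params, q0, traj$d))
    Mf <- function(tt) Minv; Vf <- function(tt) matrix(0, 2, 2)
    Df <- function(tt) matrix(0, 2, 2); Jf <- function(tt) Jt
  } else {
    Ma <- array(0, c(2, 2, n)); Va <- Ma; Da <- Ma; Ja <- Ma
    for (i in seq_len(n)) {
      qi <- traj$q[, i]; qdi <- traj$qdot[, i]
      Ma[, , i] <- solve(inertia_matrix(params, qi))
      Va[, , i] <- coriolis_velocity_matrix(params, qi, qdi)
      Da[, , i] <- dynamic_field_matrix(params, qi, qdi) +
        inertial_position_matrix(params, qi, traj$qddot[, i])
      Ja[, , i] <- t(jacobian(params, qi, traj$d))
    }
    Mf <- interp_mat22(t, Ma); Vf <- interp_mat22(t, Va)
    Df <- interp_mat22(t, Da); Jf <- interp_mat22(t, Ja)
  }

  rhs <- function(tt, y, parms) {
    dq <- y[1:2]; dqd <- y[3:4]
    aux <- if (nav > 0) y[5:(4 + nav)] else NULL
    ve <- ve_force(model, tt, dq, dqd, aux)
    Fp <- parms$force(tt)
    tau <- Jf(tt) %*% Fp - Vf(tt) %*% dqd - Df(tt) %*% dq - ve$torque
    dy <- c(dqd, drop(Mf(tt) %*% tau))
    if (nav > 0) dy <- c(dy, ve$aux_dot)
    list(dy)
  }

  t0 <- pert$t_onset; t1 <- pert$t_onset + pert$duration
  i0 <- which.min(abs(t - t0)); i1 <- which.min(abs(t - t1))
  y <- rep(0, 4 + nav)
  sol <- matrix(0, n, 4 + nav)
  seg_force_on <- function(tt) pert$magnitude * pert$direction
  seg_force_off <- function(tt) c(0, 0)
  run_seg <- function(y0, idx, force) {
    times <- t[idx]
    out <- deSolve::lsoda(y0, times, rhs, parms = list(force = force),
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out[, -1])))
      stop(sprintf("integration failed near t = %.4f s", out[nrow(out), 1]))
    out[, -1, drop = FALSE]
  }
  # dq == 0 identically before the perturbation
  if (i1 > i0) {
    seg <- run_seg(y, i0:i1, seg_force_on)
    sol[i0:i1, ] <- seg
    y <- seg[nrow(seg), ]
  }
  if (i1 < n) {
    seg <- run_seg(y, i1:n, seg_force_off)
    sol[i1:n, ] <- seg
  }

  rec <- structure(list(
    fs = fs, t = t, q_ref = traj$q, qdot_ref = traj$qdot,
    dq = t(sol[, 1:2]), dqdot = t(sol[, 3:4]),
    hand_force = perturbation_force(pert, t),
    perturbation = pert, noise = noise_spec("none"),
    model = model, traj = traj), class = "simulation_record")
  rec
}

#' Free response of the full nonlinear rigid arm
#'
#' Integrates `M(q) qddot + C(q, qdot) qdot = 0` (no gravity, no muscle
#' field) with the same solver settings as the variational simulator. Used to
#' validate the rigid-body dynamics through energy conservation.
#'
#' @param params [arm_params()]
#' @param q0,qdot0 initial state
#' @param t_total duration (s)
#' @param fs output sampling rate (Hz)
#' @return list with `t`, `q`, `qdot` and kinetic `energy`
#' @export
simulate_rigid_free <- function(params, q0, qdot0, t_total = 5, fs = 1000) {
  rhs <- function(tt, y, p) {
    q <- y[1:2]; qd <- y[3:4]
    M <- inertia_matrix(params, q)
    tau <- -coriolis_matrix(params, q, qd) %*% qd
    list(c(qd, drop(solve(M, tau))))
  }
  times <- seq(0, t_total, by = 1 / fs)
  out <- deSolve::lsoda(c(q0, qdot0), times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  q <- t(out[, 2:3]); qd <- t(out[, 4:5])
  en <- vapply(seq_len(ncol(q)), function(i) {
    0.5 * drop(t(qd[, i]) %*% inertia_matrix(params, q[, i]) %*% qd[, i])
  }, numeric(1))
  list(t = out[, 1], q = q, qdot = qd, energy = en)
}

#' Corrupt a simulation record with measurement noise
#'
#' Adds zero-mean Gaussian noise to the joint-deviation channels. In
#' `constant_snr` mode the per-channel noise std is set from the RMS of the
#' post-onset response; in `sdn` mode the std is scaled by
#' `g(t)/max(g)` of the supplied gain profile so that the configured SNR
#' floor is reached at peak gain (a proxy for co-activation-dependent motor
#' noise). Deterministic for a fixed seed.
#'
#' @param record a [simulate_record()] result
#' @param noise a [noise_spec()]
#' @param gain_profile required for `sdn` mode: the [gain_profile()] driving
#'   the noise amplitude (typically the stiffness profile)
#' @return a `simulation_record` with noisy `dq` (and the noise spec attached)
#' @export
add_noise <- function(record, noise, gain_profile = NULL) {
  if (noise$mode == "none") return(record)
  post <- record$t >= record$perturbation$t_onset
  set.seed(noise$seed)
  fac <- 10^(noise$snr_db / 20)
  for (ch in 1:2) {
    rms <- sqrt(mean(record$dq[ch, post]^2))
    sigma <- rms / fac
    if (noise$mode == "constant_snr") {
      record$dq[ch, ] <- record$dq[ch, ] + stats::rnorm(length(record$t), 0, sigma)
    } else {
      if (is.null(gain_profile))
        stop("sdn noise requires the driving gain profile")
      g <- gain(gain_profile, record$t)
      record$dq[ch, ] <- record$dq[ch, ] +
        stats::rnorm(length(record$t), 0, 1) * sigma * g / max(g)
    }
  }
  record$noise <- noise
  record
}

#' Write / read a simulation record as a delimited table
#'
#' The table holds columns `t, q1_ref, q2_ref, dq1, dq2, F_x, F_y`; a JSON
#' sidecar (`<path>.meta.json`) stores the sampling rate, perturbation,
#' noise spec, arm parameters and a model descriptor.
#'
#' @param record a `simulation_record`
#' @param path output file path (tab-separated)
#' @return `write_record` returns `path` invisibly; `read_record` a
#'   `simulation_record` (with `dqdot` recovered by finite differences).
#' @export
write_record <- function(record, path) {
  df <- data.frame(t = record$t,
                   q1_ref = record$q_ref[1, ], q2_ref = record$q_ref[2, ],
                   dq1 = record$dq[1, ], dq2 = record$dq[2, ],
                   F_x = record$hand_force[1, ], F_y = record$hand_force[2, ])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(fs = record$fs,
               perturbation = unclass(record$perturbation),
               noise = unclass(record$noise),
               model_class = class(record$model)[1],
               arm_params = arm_params_to_list(record$traj$params),
               d = record$traj$d,
               mode = record$traj$spec$mode)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  pert <- do.call(perturbation_spec, meta$perturbation[c("kind", "magnitude",
                                                         "duration", "direction",
                                                         "t_onset")])
  fs <- meta$fs
  dq <- rbind(df$dq1, df$dq2)
  dqdot <- rbind(c(0, diff(df$dq1)) * fs, c(0, diff(df$dq2)) * fs)
  qdot_ref <- rbind(pracma::gradient(df$q1_ref, 1 / fs),
                    pracma::gradient(df$q2_ref, 1 / fs))
  params <- arm_params_from_list(meta$arm_params)
  structure(list(fs = fs, t = df$t, q_ref = rbind(df$q1_ref, df$q2_ref),
                 qdot_ref = qdot_ref,
                 dq = dq, dqdot = dqdot,
                 hand_force = rbind(df$F_x, df$F_y),
                 perturbation = pert,
                 noise = do.call(noise_spec, meta$noise),
                 model = NULL,
                 traj = list(params = params, d = meta$d,
                             spec = list(mode = meta$mode))),
            class = "simulation_record")
}
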