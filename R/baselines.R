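#' @rdname simulate_record
#' @param t_stop optional truncation time (s): integrate and return the
#'   record only up to `t_stop` (used for short regression windows)
#' @export
simulate_trial <- function(model, traj, pert, t_stop = NULL,
                           rtol = 1e-9, atol = 1e-12) {
  if (is.null(t_stop)) return(simulate_record(model, traj, pert, rtol, atol))
  keep <- traj$t <= t_stop + 0.5 / traj$fs
  tr2 <- traj
  tr2$t <- traj$t[keep]
  tr2$q <- traj$q[, keep, drop = FALSE]
  tr2$qdot <- traj$qdot[, keep, drop = FALSE]
  tr2$qddot <- traj$qddot[, keep, drop = FALSE]
  tr2$x <- traj$x[, keep, drop = FALSE]
  simulate_record(model, tr2, pert, rtol, atol)
}

# Savitzky-Golay derivative used when differentiating (possibly noisy)
# kinematic channels before a regression.
sg_derivative <- function(x, fs, order = 3, window_s = 0.025) {
  n <- round(window_s * fs); if (n %% 2 == 0) n <- n + 1
  n <- max(n, order + 3); if (n %% 2 == 0) n <- n + 1
  signal::sgolayfilt(x, p = order, n = n, m = 1, ts = 1 / fs)
}

# least squares for d_tau = M dqdd + C dqd + K dq across stacked samples
fit_linear_impedance <- function(dq, dqd, dqdd, dtau, estimate_inertia = TRUE) {
  S <- ncol(dq)
  npar <- if (estimate_inertia) 12 else 8
  X <- matrix(0, 2 * S, npar)
  y <- numeric(2 * S)
  for (s in seq_len(S)) {
    for (i in 1:2) {
      row <- 2 * (s - 1) + i
      y[row] <- dtau[i, s]
      cols <- if (estimate_inertia)
        c(dqdd[, s], dqd[, s], dq[, s]) else c(dqd[, s], dq[, s])
      # parameters ordered row-wise per equation: eq1 uses cols 1..npar/2
      off <- (i - 1) * npar / 2
      X[row, off + seq_len(npar / 2)] <- cols
    }
  }
  qrX <- qr(X)
  if (qrX$rank < npar) {
    sv <- svd(X)$d
    stop(sprintf("rank-deficient regressor (rank %d of %d, cond %.2e): add perturbation directions",
                 qrX$rank, npar, sv[1] / max(sv[length(sv)], 1e-300)))
  }
  th <- qr.coef(qrX, y)
  res <- sqrt(mean((X %*% th - y)^2))
  half <- npar / 2
  unpack <- function(start) {
    matrix(c(th[start], th[half + start], th[start + 1], th[half + start + 1]),
           2, 2, byrow = FALSE)
  }
  if (estimate_inertia) {
    M_hat <- rbind(th[1:2], th[7:8]); C_hat <- rbind(th[3:4], th[9:10])
    K_hat <- rbind(th[5:6], th[11:12])
  } else {
    M_hat <- NULL; C_hat <- rbind(th[1:2], th[5:6]); K_hat <- rbind(th[3:4], th[7:8])
  }
  list(M_hat = M_hat, C_hat = C_hat, K_hat = K_hat, residual = res)
}

punctual_estimate <- function(t_star, K_hat, C_hat = NULL, M_hat = NULL,
                              method, n_perturbations, residual = NA_real_) {
  structure(list(t_star = t_star, K_hat = K_hat, C_hat = C_hat, M_hat = M_hat,
                 method = method, n_perturbations = n_perturbations,
                 residual = residual),
            class = "punctual_estimate")
}

#' Force-pulse full regression
#'
#' Classical multi-trial estimator: a 200 ms force pulse is applied in eight
#' directions at the same trajectory instant; inertia, damping and stiffness
#' are recovered by least squares on
#' `J^T F = M dqddot + C dqdot + K dq` over the response window.
#'
#' @param records list of `simulation_record`s sharing the reference
#'   trajectory, one per perturbation direction (force pulses at `t_star`)
#' @param t_star perturbation onset common to the trials (s)
#' @param window_s regression window from the onset (s)
#' @return a `punctual_estimate` with `K_hat`, `C_hat`, `M_hat`
#' @export
force_full_regression <- function(records, t_star, window_s = 0.2) {
  if (length(records) < 8)
    stop("force full regression requires at least 8 perturbation directions")
  dq <- dqd <- dqdd <- dtau <- NULL
  for (rec in records) {
    fs <- rec$fs
    sel <- which(rec$t >= t_star & rec$t <= t_star + window_s)
    if (rec$noise$mode == "none" && !is.null(rec$dqdot)) {
      # clean records carry the integrator's exact velocities
      d1 <- rec$dq
      v <- rec$dqdot
      a <- rbind(pracma::gradient(v[1, ], 1 / fs),
                 pracma::gradient(v[2, ], 1 / fs))
    } else {
      d1 <- rbind(signal::sgolayfilt(rec$dq[1, ], p = 3, n = 101),
                  signal::sgolayfilt(rec$dq[2, ], p = 3, n = 101))
      v <- rbind(sg_derivative(rec$dq[1, ], fs), sg_derivative(rec$dq[2, ], fs))
      a <- rbind(sg_derivative(v[1, ], fs), sg_derivative(v[2, ], fs))
    }
    # applied torque from the known hand force and reference configuration
    tau <- matrix(0, 2, length(sel))
    for (k in seq_along(sel)) {
      i <- sel[k]
      J <- jacobian(rec$traj$params, rec$q_ref[, i], rec$traj$d)
      tau[, k] <- t(J) %*% rec$hand_force[, i]
    }
    dq <- cbind(dq, d1[, sel]); dqd <- cbind(dqd, v[, sel])
    dqdd <- cbind(dqdd, a[, sel]); dtau <- cbind(dtau, tau)
  }
  fit <- fit_linear_impedance(dq, dqd, dqdd, dtau, estimate_inertia = TRUE)
  punctual_estimate(t_star, fit$K_hat, fit$C_hat, fit$M_hat,
                    method = "force_full", n_perturbations = length(records),
                    residual = fit$residual)
}

#' Kinematic response to a servo-displacement perturbation
#'
#' Models an ideally stiff robot imposing a ramp-plateau-ramp hand
#' displacement on top of the reference trajectory. The joint deviation
#' follows by inverse kinematics; velocities and accelerations by finite
#' differences; the reaction torque from the linearized plant plus the
#' viscoelastic field. Only Kelvin-Voigt models are supported (the paper's
#' regressive comparisons are KV-only).
#'
#' @param model a `kv_model`
#' @param traj a [reference_trajectory()]
#' @param pert a `servo_displacement` [perturbation_spec()]
#' @param t_stop optional truncation time (s)
#' @return a `simulation_record` whose `hand_force` holds the reaction force
#' @export
servo_response <- function(model, traj, pert, t_stop = NULL) {
  if (!inherits(model, "kv_model"))
    stop("servo_response supports Kelvin-Voigt models only")
  if (pert$kind != "servo_displacement")
    stop("perturbation must be of kind 'servo_displacement'")
  keep <- if (is.null(t_stop)) rep(TRUE, length(traj$t)) else
    traj$t <= t_stop + 0.5 / traj$fs & traj$t >= pert$t_onset - 0.02
  t <- traj$t[keep]; fs <- traj$fs
  params <- traj$params
  amp <- servo_profile(pert, t)
  n <- length(t)
  dq <- matrix(0, 2, n)
  nz <- which(amp != 0)
  for (i in nz) {
    xp <- traj$x[, which(keep)[i]] + amp[i] * pert$direction
    dq[, i] <- inverse_kinematics(params, xp, traj$d)$q - traj$q[, which(keep)[i]]
  }
  grad2 <- function(m) rbind(pracma::gradient(m[1, ], 1 / fs),
                             pracma::gradient(m[2, ], 1 / fs))
  dqd <- grad2(dq); dqdd <- grad2(dqd)
  tau <- matrix(0, 2, n)
  Fh <- matrix(0, 2, n)
  for (i in seq_len(n)) {
    ii <- which(keep)[i]
    q <- traj$q[, ii]; qd <- traj$qdot[, ii]
    M <- inertia_matrix(params, q)
    V <- coriolis_velocity_matrix(params, q, qd)
    D <- dynamic_field_matrix(params, q, qd) +
      inertial_position_matrix(params, q, traj$qddot[, ii])
    tau[, i] <- M %*% dqdd[, i] + V %*% dqd[, i] + D %*% dq[, i] +
      kv_torque(model, t[i], dq[, i], dqd[, i])
    Fh[, i] <- solve(t(jacobian(params, q, traj$d)), tau[, i])
  }
  structure(list(fs = fs, t = t, q_ref = traj$q[, keep, drop = FALSE],
                 qdot_ref = traj$qdot[, keep, drop = FALSE],
                 dq = dq, dqdot = dqd, dqddot = dqdd, tau_reaction = tau,
                 hand_force = Fh, perturbation = pert,
                 noise = noise_spec("none"), model = model, traj = traj),
            class = "simulation_record")
}

#' Servo-displacement full regression
#'
#' Least-squares recovery of inertia, damping and stiffness from the
#' reaction torque over the first 200 ms of a ramp-plateau-ramp
#' displacement, across eight directions.
#'
#' @param records list of [servo_response()] records (one per direction)
#' @param t_star perturbation onset (s)
#' @param window_s regression window (s); 200 ms matches the force-pulse
#'   sample count
#' @return a `punctual_estimate`
#' @export
displacement_full_regression <- function(records, t_star, window_s = 0.2) {
  if (length(records) < 8)
    stop("displacement full regression requires at least 8 perturbation directions")
  dq <- dqd <- dqdd <- dtau <- NULL
  for (rec in records) {
    sel <- which(rec$t >= t_star & rec$t <= t_star + window_s)
    dq <- cbind(dq, rec$dq[, sel])
    dqd <- cbind(dqd, rec$dqdot[, sel])
    dqdd <- cbind(dqdd, rec$dqddot[, sel])
    dtau <- cbind(dtau, rec$tau_reaction[, sel])
  }
  fit <- fit_linear_impedance(dq, dqd, dqdd, dtau, estimate_inertia = TRUE)
  punctual_estimate(t_star, fit$K_hat, fit$C_hat, fit$M_hat,
                    method = "disp_full", n_perturbations = length(records),
                    residual = fit$residual)
}

#' Steady-state displacement regression (stiffness only)
#'
#' Uses the last 50 ms of the servo plateau, where velocity and acceleration
#' deviations are negligible, and regresses the plateau-mean reaction torque
#' on the plateau-mean displacement across directions.
#'
#' @param records list of [servo_response()] records
#' @param t_star perturbation onset (s)
#' @param steady_s steady window at the end of the plateau (s)
#' @param vel_tol warning threshold on plateau RMS joint velocity (rad/s)
#' @return a `punctual_estimate` carrying `K_hat` only
#' @export
steady_state_regression <- function(records, t_star, steady_s = 0.05,
                                    vel_tol = 0.05) {
  pert <- records[[1]]$perturbation
  plateau_end <- t_star + pert$ramp[1] + pert$ramp[2]
  mq <- mtau <- NULL
  for (rec in records) {
    # keep clear of the ramp-down corner: the finite-difference acceleration
    # spikes there and would contaminate the plateau means
    guard <- 3 / rec$fs
    sel <- which(rec$t >= plateau_end - steady_s & rec$t <= plateau_end - guard)
    if (sqrt(mean(rec$dqdot[, sel]^2)) > vel_tol)
      warning("plateau not steady: RMS joint velocity above threshold")
    mq <- cbind(mq, rowMeans(rec$dq[, sel, drop = FALSE]))
    mtau <- cbind(mtau, rowMeans(rec$tau_reaction[, sel, drop = FALSE]))
  }
  S <- ncol(mq)
  X <- matrix(0, 2 * S, 4); y <- numeric(2 * S)
  for (s in seq_len(S)) for (i in 1:2) {
    row <- 2 * (s - 1) + i
    y[row] <- mtau[i, s]
    X[row, (i - 1) * 2 + 1:2] <- mq[, s]
  }
  th <- qr.solve(X, y)
  K_hat <- rbind(th[1:2], th[3:4])
  punctual_estimate(t_star, K_hat, method = "disp_steady",
                    n_perturbations = length(records))
}

#' Cubic Hermite interpolation of punctual estimates
#'
#' Builds a C1, shape-preserving cubic Hermite (pchip) time profile through
#' a sequence of punctual matrix estimates, coefficient by coefficient: the
#' unique continuous representation used to compare punctual estimators with
#' the continuous spectrogram profiles.
#'
#' @param points list of `punctual_estimate`s with strictly increasing
#'   `t_star`
#' @return a function `f(t)` returning `list(K, C)` of `2 x 2 x length(t)`
#'   arrays (`C` is `NULL` when the estimates carry no damping)
#' @export
hermite_profile <- function(points) {
  if (length(points) < 2) stop("need at least two punctual estimates")
  ts <- vapply(points, function(p) p$t_star, numeric(1))
  if (any(diff(ts) <= 0)) stop("t_star values must be strictly increasing")
  has_C <- !is.null(points[[1]]$C_hat)
  Kk <- array(0, c(2, 2, length(points)))
  Ck <- if (has_C) array(0, c(2, 2, length(points))) else NULL
  for (p in seq_along(points)) {
    Kk[, , p] <- points[[p]]$K_hat
    if (has_C) Ck[, , p] <- points[[p]]$C_hat
  }
  function(t) {
    tc <- pmin(pmax(t, ts[1]), ts[length(ts)])
    K <- array(0, c(2, 2, length(t)))
    C <- if (has_C) array(0, c(2, 2, length(t))) else NULL
    for (i in 1:2) for (j in 1:2) {
      K[i, j, ] <- pracma::pchip(ts, Kk[i, j, ], tc)
      if (has_C) C[i, j, ] <- pracma::pchip(ts, Ck[i, j, ], tc)
    }
    list(K = K, C = C)
  }
}

#' Run a simulation-estimation experiment
#'
#' Executes a factorial sweep (estimation method x stiffness profile x
#' damping profile x noise level x static/dynamic condition), reproducing
#' the standard comparison protocol: the spectrogram method uses a single
#' 5 N / 20 ms impulse per condition; each regressive point uses eight
#' perturbation directions at five instants (2.5 to 4.5 s every 0.5 s),
#' interpolated with a cubic Hermite spline. Per-condition percentage RMS
#' errors are reported over the full estimation interval and over the
#' interval between the first two regressive estimation points
#' (2.6--3.175 s by default). Individual condition failures are recorded
#' and the sweep continues.
#'
#' @param config list with optional entries `methods`, `k_profiles`,
#'   `c_profiles`, `noises` (list of [noise_spec()]s), `conditions`
#'   (`"posture"`, `"reach"`), `fs`, `seed`, `t_stars`, `intervals`
#'   (list of length-2 vectors), `params` ([arm_params()])
#' @return list with `report` (long data frame of errors), `failures`, and
#'   the resolved `config`
#' @export
run_experiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    methods = c("spectrogram", "force_full", "disp_full", "disp_steady"),
    k_profiles = c("constant", "sigmoid", "sinlin", "sharp"),
    c_profiles = c("constant"),
    noises = list(noise_spec("none")),
    conditions = c("posture"),
    fs = 4000, seed = 1L,
    t_stars = seq(2.5, 4.5, by = 0.5),
    intervals = list(full = c(2.6, 5), early = c(2.6, 3.175)),
    params = arm_params_default()), config)
  report <- list(); failures <- list()
  run_id <- 0L
  for (cond in cfg$conditions) {
    spec <- trajectory_spec(mode = if (cond == "posture") "posture" else "reach",
                            start = if (cond == "posture") c(0.4, 0) else c(0.25, 0))
    traj <- reference_trajectory(spec, cfg$params, fs = cfg$fs)
    for (kp in cfg$k_profiles) for (cp in cfg$c_profiles) {
      model <- kv_reference(gK = gain_profile(kp), gC = gain_profile(cp))
      for (nz in seq_along(cfg$noises)) {
        noise <- cfg$noises[[nz]]
        for (method in cfg$methods) {
          run_id <- run_id + 1L
          seed_i <- cfg$seed + 7919L * run_id
          res <- tryCatch(
            run_condition(method, model, traj, noise, seed_i, cfg),
            error = function(e) e)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1]] <-
              data.frame(method = method, k_profile = kp, c_profile = cp,
                         noise = noise$mode, condition = cond,
                         message = conditionMessage(res))
            next
          }
          for (iv in names(cfg$intervals)) {
            err <- res$errors[[iv]]
            report[[length(report) + 1]] <- data.frame(
              method = method, k_profile = kp, c_profile = cp,
              noise = noise$mode, snr_db = noise$snr_db, condition = cond,
              interval = iv, coefficient = names(err), rmse_pct = unname(err),
              seed = seed_i)
          }
        }
      }
    }
  }
  list(report = if (length(report)) do.call(rbind, report) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else NULL,
       config = cfg)
}

# one (method, model, noise) condition; returns per-interval error vectors
run_condition <- function(method, model, traj, noise, seed, cfg) {
  t_grid <- seq(min(cfg$t_stars), max(cfg$t_stars), by = 0.01)
  imp <- imposed_impedance(model, t_grid)
  idx <- list(k11 = c(1, 1), k12 = c(1, 2), k22 = c(2, 2))
  score <- function(Kf, Cf, tt, interval) {
    out <- c()
    impi <- imposed_impedance(model, tt)
    for (nm in names(idx)) {
      i <- idx[[nm]]
      out[nm] <- percent_rmse(Kf[i[1], i[2], ], impi$K[i[1], i[2], ], tt, interval)
    }
    if (!is.null(Cf)) for (nm in names(idx)) {
      i <- idx[[nm]]
      out[sub("k", "c", nm)] <- percent_rmse(Cf[i[1], i[2], ], impi$C[i[1], i[2], ], tt, interval)
    }
    out
  }
  if (method == "spectrogram") {
    set.seed(seed)
    dir <- sample(1:8, 1)
    pert <- perturbation_spec("force_impulse", direction = octant_direction(dir),
                              t_onset = min(cfg$t_stars))
    rec <- simulate_record(model, traj, pert)
    if (noise$mode != "none")
      rec <- add_noise(rec, noise_spec(noise$mode, noise$snr_db, seed),
                       gain_profile = model$gK)
    est <- estimate_impedance(rec)
    errors <- lapply(cfg$intervals, function(iv) {
      sel <- est$mask
      Kf <- est$K_hat; Cf <- est$C_hat
      for (i in 1:2) for (j in 1:2) {
        Kf[i, j, !sel] <- NA; Cf[i, j, !sel] <- NA
      }
      score(Kf, Cf, est$t, iv)
    })
    return(list(errors = errors))
  }
  # regressive methods: punctual estimates at the knots
  pts <- list()
  for (p in seq_along(cfg$t_stars)) {
    ts <- cfg$t_stars[p]
    recs <- list()
    for (dct in 1:8) {
      if (method == "force_full") {
        pert <- perturbation_spec("force_pulse", direction = octant_direction(dct),
                                  t_onset = ts)
        rec <- simulate_trial(model, traj, pert, t_stop = ts + 0.3)
      } else {
        pert <- perturbation_spec("servo_displacement",
                                  direction = octant_direction(dct), t_onset = ts)
        rec <- servo_response(model, traj, pert, t_stop = ts + 0.35)
      }
      if (noise$mode != "none")
        rec <- add_noise(rec, noise_spec(noise$mode, noise$snr_db,
                                         seed + 100 * p + dct),
                         gain_profile = model$gK)
      recs[[dct]] <- rec
    }
    pts[[p]] <- switch(method,
      force_full = force_full_regression(recs, ts),
      disp_full = displacement_full_regression(recs, ts),
      disp_steady = steady_state_regression(recs, ts))
  }
  prof <- hermite_profile(pts)
  pr <- prof(t_grid)
  errors <- lapply(cfg$intervals, function(iv) score(pr$K, pr$C, t_grid, iv))
  list(errors = errors, points = pts)
}
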