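#' Single-trial time-frequency impedance estimation
#'
#' Full estimation pipeline on one perturbed record:
#' \enumerate{
#'   \item decimate the joint-deviation signals to the analysis rate;
#'   \item normalize by the (known) inertia square root,
#'     `rho = M(q_ref)^1/2 dq`, so the system is monic;
#'   \item reassigned spectrogram of each normalized channel (movement
#'     band masked);
#'   \item ridge extraction and Savitzky-Golay smoothing into instantaneous
#'     resonant frequencies and amplitudes;
#'   \item mode separation, inter-channel phase-lag estimation and
#'     re-synchronization (non-classical damping support);
#'   \item eigenvectors from amplitude ratios, natural frequencies and
#'     damping ratios from the free-vibration relations;
#'   \item reconstruction of `K(t)` and `C(t)` and subtraction of the known
#'     rigid-body (Coriolis/centripetal) contributions.
#' }
#'
#' @param record a [simulate_record()] result (or [read_record()] output)
#' @param window analysis [window_spec()]
#' @param fs_analysis internal analysis rate (Hz); the record is decimated
#'   when sampled faster
#' @param t_end end of the estimation interval (s); the interval starts
#'   0.1 s after the perturbation onset
#' @param neglect_damping approximate the natural frequency by the resonant
#'   frequency when rebuilding the stiffness (sensitivity analysis switch)
#' @param synchronize estimate and correct inter-channel mode phase lags
#' @param correct_rigid subtract the configuration/velocity-dependent
#'   rigid-body stiffness and damping contributions evaluated along the
#'   reference trajectory
#' @param symmetric symmetrize the reconstructed matrices
#' @param smooth_output apply the track Savitzky-Golay smoothing to the
#'   reconstructed coefficient profiles
#' @param fmin ridge/mask low-frequency cutoff (Hz)
#' @param fmax analysis band upper edge (Hz)
#' @return an `impedance_estimate` (see [reconstruct_matrices()]) with extra
#'   fields: `tracks`, `U`, `psi`, `modal`, `interval`
#' @export
estimate_impedance <- function(record, window = window_spec(),
                               fs_analysis = 400, t_end = 5,
                               neglect_damping = FALSE, synchronize = TRUE,
                               correct_rigid = TRUE, symmetric = TRUE,
                               smooth_output = TRUE, fmin = 1.2, fmax = 30) {
  params <- record$traj$params
  t_on <- record$perturbation$t_onset
  fs <- record$fs
  r <- max(1L, round(fs / fs_analysis))
  if (r > 1) {
    dq <- rbind(signal::decimate(record$dq[1, ], r, ftype = "fir"),
                signal::decimate(record$dq[2, ], r, ftype = "fir"))
    idx <- seq(1L, length(record$t), by = r)[seq_len(ncol(dq))]
    t <- record$t[idx]
    q_ref <- record$q_ref[, idx, drop = FALSE]
    qdot_ref <- if (!is.null(record$qdot_ref)) record$qdot_ref[, idx, drop = FALSE]
                else matrix(0, 2, length(idx))
    fs_a <- fs / r
  } else {
    dq <- record$dq; t <- record$t; q_ref <- record$q_ref
    qdot_ref <- if (!is.null(record$qdot_ref)) record$qdot_ref else matrix(0, 2, ncol(dq))
    fs_a <- fs
  }

  # monic normalization with the known inertia along the reference
  n <- ncol(dq)
  rho <- matrix(0, 2, n)
  Mh_t <- array(0, c(2, 2, n))
  for (i in seq_len(n)) {
    ns <- normalize_system(inertia_matrix(params, q_ref[, i]))
    Mh_t[, , i] <- ns$M_half
    rho[, i] <- ns$M_half %*% dq[, i]
  }

  rs <- lapply(1:2, function(ch) reassign(rho[ch, ], fs_a, window, fmax = fmax))
  rs <- lapply(rs, segregate_movement, t_onset = t_on, cutoff_hz = fmin,
               subtract_pre = FALSE)
  tracks <- extract_ridges(rs, n_modes = 2, t_onset = t_on, fmin = fmin)
  tracks <- smooth_tracks(tracks)

  # refine the ridge readout with decay-adjusted demixing: first-pass decay
  # rates feed window transforms at the complex modal frequencies
  modal0 <- modal_parameters(tracks)
  # the free oscillation is born when the impulse ends
  t_free <- t_on + record$perturbation$duration
  tracks <- demix_tracks(tracks, rs, modal0$sigma, t_free = t_free)
  tracks <- smooth_tracks(tracks)

  sep <- separate_modes(rho, fs_a, tracks, window = window,
                        fmin = fmin, fmax = fmax)
  interval <- c(t_on + 0.1, min(t_end, max(t)))
  psi <- c(0, 0); psi_info <- NULL
  if (synchronize) {
    psi_info <- lapply(1:2, function(j) {
      tryCatch({
        wj <- stats::approx(tracks$t, fill_gaps(tracks$t, tracks$omega[j, ]),
                            xout = sep$t, rule = 2)$y
        estimate_phase_lag(sep$components[j, 1, ], sep$components[j, 2, ],
                           sep$t, wj, fs_a, interval = interval,
                           window_s = window$duration)
      }, error = function(e) NULL)
    })
    psi <- vapply(psi_info, function(p) if (is.null(p)) 0 else p$psi, numeric(1))
    sep <- synchronize_modes(sep, psi, tracks, fs_a)
  }

  signs <- vapply(psi_info, function(p) if (is.null(p)) 1 else p$sign, numeric(1))
  if (!synchronize || !length(signs)) signs <- NULL
  eig <- estimate_eigenvectors(tracks, sep, signs = signs,
                               orthogonal = symmetric)
  if (!is.null(eig$psi_cross)) {
    # the cross-spectral phase at the ridge is the robust estimate of the
    # inter-channel mode lag; the time-domain cross-correlation estimate is
    # kept as a diagnostic
    for (j in 1:2) {
      ps <- eig$psi_cross[j, eig$mask[j, ]]
      if (sum(is.finite(ps)) > 5) psi[j] <- stats::median(ps, na.rm = TRUE)
    }
  }
  modal <- modal_parameters(tracks)
  omega_use <- if (neglect_damping) {
    ww <- tracks$omega
    for (j in 1:2) ww[j, ] <- fill_gaps(tracks$t, ww[j, ])
    ww
  } else modal$omega_n

  # inertia square root at the frame times
  Mh_frames <- array(0, c(2, 2, length(tracks$t)))
  for (k in 1:2) for (l in 1:2)
    Mh_frames[k, l, ] <- stats::approx(t, Mh_t[k, l, ], xout = tracks$t, rule = 2)$y

  est <- reconstruct_matrices(eig$U, omega_use, modal$zeta, Mh_frames,
                              t = tracks$t, neglect_damping = neglect_damping,
                              symmetric = symmetric)

  if (correct_rigid) {
    qd_fr <- matrix(0, 2, length(tracks$t))
    q_fr <- matrix(0, 2, length(tracks$t))
    for (k in 1:2) {
      q_fr[k, ] <- stats::approx(t, q_ref[k, ], xout = tracks$t, rule = 2)$y
      qd_fr[k, ] <- stats::approx(t, qdot_ref[k, ], xout = tracks$t, rule = 2)$y
    }
    for (i in seq_along(tracks$t)) {
      if (!est$mask[i]) next
      D <- dynamic_field_matrix(params, q_fr[, i], qd_fr[, i])
      V <- coriolis_velocity_matrix(params, q_fr[, i], qd_fr[, i])
      if (symmetric) { D <- (D + t(D)) / 2; V <- (V + t(V)) / 2 }
      est$K_hat[, , i] <- est$K_hat[, , i] - D
      est$C_hat[, , i] <- est$C_hat[, , i] - V
    }
  }

  if (smooth_output) {
    # the estimate is a continuous profile: smooth the reconstructed
    # coefficients with the same Savitzky-Golay settings used on the tracks
    # (residual two-mode interference ripple is zero-mean at the beat
    # frequency and polynomial smoothing removes it)
    dt <- tracks$hop_s
    nsg <- round(0.25 / dt); if (nsg %% 2 == 0) nsg <- nsg + 1
    okk <- which(est$mask & is.finite(est$K_hat[1, 1, ]))
    if (length(okk) > nsg + 1) {
      idx <- min(okk):max(okk)
      for (i in 1:2) for (j in 1:2) {
        est$K_hat[i, j, idx] <- signal::sgolayfilt(
          fill_gaps(est$t[idx], est$K_hat[i, j, idx]), p = 3, n = nsg)
        est$C_hat[i, j, idx] <- signal::sgolayfilt(
          fill_gaps(est$t[idx], est$C_hat[i, j, idx]), p = 3, n = nsg)
      }
    }
  }

  # confine to the estimation interval; drop frames where a ridge was lost.
  # Frames whose analysis window is not yet entirely filled by the free
  # response (it still contains the forced segment or pre-onset rest) are
  # low-confidence: their spectral estimates are formed from a truncated
  # oscillation.
  inwin <- est$t >= interval[1] & est$t <= interval[2]
  full_support <- est$t >= t_free + window$duration / 2
  est$mask <- est$mask & inwin & full_support &
    tracks$valid[1, ] & tracks$valid[2, ] &
    eig$mask[1, ] & eig$mask[2, ]
  # isolated eigenvector-ratio spikes (a junk candidate slipping through
  # one frame) are masked against a running-median reference
  for (j in 1:2) {
    ok <- which(est$mask & is.finite(eig$U[2, j, ]))
    if (length(ok) > 15) {
      r <- eig$U[2, j, ok]
      med <- stats::runmed(r, 11)
      dev <- abs(r - med)
      s <- stats::median(dev) * 1.4826
      out <- dev > pmax(6 * s, 0.02 + 0.3 * abs(med))
      est$mask[ok[out]] <- FALSE
    }
  }
  est$tracks <- tracks; est$U <- eig$U; est$psi <- psi
  est$psi_info <- psi_info; est$modal <- modal; est$interval <- interval
  est
}

#' Imposed eigenvector matrix of the normalized stiffness
#'
#' Ground-truth `U(t)`: eigenvectors of `M^-1/2 K(t) M^-1/2` along the
#' reference trajectory, columns sorted by ascending eigenvalue and first
#' component normalized to one.
#'
#' @param record a simulation record carrying a `kv_model`
#' @param times evaluation times (s)
#' @return `2 x 2 x length(times)` array
#' @export
imposed_eigenvectors <- function(record, times) {
  params <- record$traj$params
  imp <- imposed_impedance(record$model, times)
  qf <- matrix(0, 2, length(times))
  for (k in 1:2)
    qf[k, ] <- stats::approx(record$t, record$q_ref[k, ], xout = times, rule = 2)$y
  U <- array(0, c(2, 2, length(times)))
  for (i in seq_along(times)) {
    ns <- normalize_system(inertia_matrix(params, qf[, i]))
    Kt <- ns$M_half_inv %*% imp$K[, , i] %*% ns$M_half_inv
    e <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    for (j in 1:2) {
      v <- e$vectors[, ord[j]]
      U[, j, i] <- v / v[1]
    }
  }
  U
}

#' Eigenvector orientation error
#'
#' Angle (degrees) between estimated and imposed eigenvectors of the
#' normalized stiffness, per mode and sample; sign-insensitive.
#'
#' @param est an [estimate_impedance()] result
#' @param record the originating record
#' @return `2 x T` matrix of angles (degrees), `NA` where masked
#' @export
eigenvector_orientation_error <- function(est, record) {
  U_true <- imposed_eigenvectors(record, est$t)
  err <- matrix(NA_real_, 2, length(est$t))
  for (i in seq_along(est$t)) {
    if (!est$mask[i]) next
    for (j in 1:2) {
      u <- est$U[, j, i]; v <- U_true[, j, i]
      if (any(!is.finite(u))) next
      ca <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      err[j, i] <- acos(min(1, ca)) * 180 / pi
    }
  }
  err
}

#' Percentage RMS error of an estimated profile
#'
#' `100 * RMS(est - true) / RMS(true)` over a time interval, the scale-free
#' profile-error metric used throughout the validation.
#'
#' @param est,truth numeric vectors on a common time grid
#' @param t time vector (s)
#' @param interval `(t0, t1)` evaluation interval (s)
#' @param na_ok drop samples where `est` is `NA` (masked) instead of failing
#' @return percentage RMS error (scalar)
#' @export
percent_rmse <- function(est, truth, t, interval = range(t), na_ok = TRUE) {
  sel <- t >= interval[1] & t <= interval[2]
  e <- est[sel]; u <- truth[sel]
  if (na_ok) { keep <- is.finite(e); e <- e[keep]; u <- u[keep] }
  if (!length(u)) stop("empty evaluation interval")
  denom <- sqrt(mean(u^2))
  if (denom == 0) stop("true profile has zero RMS on the interval")
  100 * sqrt(mean((e - u)^2)) / denom
}

#' Percentage RMS errors of all impedance coefficients
#'
#' Convenience wrapper scoring an estimate against the imposed model
#' profiles over an interval.
#'
#' @param est an [estimate_impedance()] result
#' @param record the originating record (must carry the model)
#' @param interval evaluation interval (s); defaults to the estimation
#'   interval
#' @return named numeric vector
#'   `(k11, k12, k22, c11, c12, c22)` of percentage RMS errors
#' @export
impedance_errors <- function(est, record, interval = est$interval) {
  imp <- imposed_impedance(record$model, est$t)
  sel <- est$mask
  idx <- list(k11 = c(1, 1), k12 = c(1, 2), k22 = c(2, 2))
  out <- c()
  for (nm in names(idx)) {
    i <- idx[[nm]]
    out[nm] <- percent_rmse(ifelse(sel, est$K_hat[i[1], i[2], ], NA),
                            imp$K[i[1], i[2], ], est$t, interval)
  }
  for (nm in names(idx)) {
    i <- idx[[nm]]
    out[sub("k", "c", nm)] <- percent_rmse(ifelse(sel, est$C_hat[i[1], i[2], ], NA),
                                           imp$C[i[1], i[2], ], est$t, interval)
  }
  out
}
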