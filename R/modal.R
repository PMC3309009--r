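#' Eigenvalues of the damped quadratic pencil
#'
#' Solves `det(M lambda^2 + C lambda + K) = 0` through the companion
#' linearization. For an underdamped system the eigenvalues come in complex
#' conjugate pairs `-sigma +/- i omega_d`. Utility for validation; the
#' time-frequency estimator never calls it.
#'
#' @param M,C,K system matrices (n x n)
#' @return complex eigenvalues, ordered by ascending `|Im|` within the
#'   upper-half-plane pairs
#' @export
quadratic_eigen <- function(M, C, K) {
  n <- nrow(M)
  Minv <- solve(M)
  A <- rbind(cbind(matrix(0, n, n), diag(n)),
             cbind(-Minv %*% K, -Minv %*% C))
  ev <- eigen(A, only.values = TRUE)$values
  up <- ev[Im(ev) > 0]
  up[order(Im(up))]
}

#' Band-split a two-channel signal into its vibrational modes
#'
#' Within each analysis frame, splits every channel at the midpoint between
#' the two instantaneous ridge frequencies using a spectral mask (zero-phase
#' by construction), and resynthesizes each mode by weighted overlap-add.
#' The resulting per-mode components have disjoint spectra at the cutoff.
#'
#' @param x `2 x N` matrix of (normalized) joint-deviation signals
#' @param fs sampling rate (Hz)
#' @param tracks a (smoothed) `modal_track` providing the instantaneous
#'   frequencies
#' @param window the [window_spec()] shared with the spectrogram
#' @param fmin lower band edge (Hz), excludes movement/DC content
#' @param fmax upper band edge (Hz)
#' @return list with `components` (`n_modes x 2 x N` array) and `t`
#' @export
separate_modes <- function(x, fs, tracks, window = window_spec(),
                           fmin = 1.2, fmax = 30) {
  stopifnot(is.matrix(x), nrow(x) == 2)
  n_modes <- nrow(tracks$omega)
  if (n_modes != 2) stop("mode separation assumes two tracked modes")
  vb <- tracks$valid[1, ] | tracks$valid[2, ]
  if (!any(vb)) stop("tracks carry no valid samples")
  # longest gap inside the valid span must not exceed one window
  vi <- which(vb)
  if (length(vi) > 1) {
    gap <- max(diff(tracks$t[vi]))
    if (gap > window$duration)
      stop("track gap longer than one analysis window; cannot separate modes")
  }
  mid_hz <- fill_gaps(tracks$t, (tracks$omega[1, ] + tracks$omega[2, ]) / (4 * pi))
  mid_of_t <- stats::approxfun(tracks$t, mid_hz, rule = 2)

  N <- ncol(x)
  comps <- array(0, c(2, 2, N))
  for (ch in 1:2) {
    e <- stft_engine(x[ch, ], fs, window, fmax = fmax, windows = "h")
    S <- e$S$h
    kw <- kaiser_window(e$n_win, window$beta, fs)
    starts <- seq(1L, N - e$n_win + 1L, by = e$hop)
    cutoff <- mid_of_t(e$t)
    den <- numeric(N)
    acc <- matrix(0, 2, N)
    chunk <- 512L
    for (i0 in seq(1L, length(starts), by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, length(starts))
      for (mode in 1:2) {
        full <- matrix(0i, e$nfft, length(idx))
        for (jj in seq_along(idx)) {
          ti <- idx[jj]
          mask <- if (mode == 1) e$f >= fmin & e$f <= cutoff[ti]
                  else e$f > cutoff[ti] & e$f <= fmax
          sv <- S[, ti] * mask
          full[e$keep, jj] <- sv
          # hermitian symmetry (bin 1 is DC, masked out by fmin anyway)
          ksym <- e$keep[e$keep > 1 & e$keep < e$nfft / 2 + 1]
          full[e$nfft - ksym + 2, jj] <- Conj(sv[e$keep > 1 & e$keep < e$nfft / 2 + 1])
        }
        seg <- Re(stats::mvfft(full, inverse = TRUE)) / e$nfft
        for (jj in seq_along(idx)) {
          ti <- idx[jj]
          rng <- starts[ti]:(starts[ti] + e$n_win - 1L)
          acc[mode, rng] <- acc[mode, rng] + seg[1:e$n_win, jj] * kw$h
          if (mode == 1) den[rng] <- den[rng] + kw$h^2
        }
      }
    }
    pos <- den > max(den) * 1e-6
    for (mode in 1:2) {
      comps[mode, ch, pos] <- acc[mode, pos] / den[pos]
    }
  }
  list(components = comps, t = (seq_len(N) - 1) / fs)
}

#' Inter-channel phase lag of a mode
#'
#' Estimates the phase shift `psi` between the two channel components of one
#' vibrational mode as `psi = omega_d * dt`, where `dt` maximizes the
#' windowed cross-correlation between the components. A complex
#' (non-classical) mode shows `psi != 0`; for symmetric stiffness and
#' damping, `psi` equals half the rotation angle between their eigenvector
#' sets.
#'
#' @param x1,x2 the two channel components of one mode (same length)
#' @param t time vector (s)
#' @param omega instantaneous angular frequency of the mode on `t` (rad/s)
#' @param fs sampling rate (Hz)
#' @param interval restrict the estimate to a time interval `(t0, t1)` (s)
#' @param window_s correlation window (s)
#' @return list: `psi` (rad, robust aggregate), `sign` (+1/-1 relative
#'   polarity of the two components at the correlation peak), `psi_t`
#'   per-window values, `t_centers`, and `ambiguous` (fraction of windows
#'   with a competing correlation peak within 5% of the maximum)
#' @export
estimate_phase_lag <- function(x1, x2, t, omega, fs, interval = NULL,
                               window_s = 0.75) {
  stopifnot(length(x1) == length(x2), length(t) == length(x1))
  if (is.null(interval)) interval <- range(t)
  half <- round(window_s * fs / 2)
  centers <- seq(interval[1] + window_s / 2, interval[2] - window_s / 2,
                 by = window_s / 4)
  if (!length(centers)) stop("interval shorter than the correlation window")
  psi_t <- rep(NA_real_, length(centers))
  sgn_t <- rep(NA_real_, length(centers))
  amb <- rep(FALSE, length(centers))
  wts <- rep(0, length(centers))
  for (k in seq_along(centers)) {
    ic <- which.min(abs(t - centers[k]))
    rng <- max(1, ic - half):min(length(t), ic + half)
    s1 <- x1[rng]; s2 <- x2[rng]
    n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
    if (n1 == 0 || n2 == 0) next
    w_bar <- omega[ic]
    if (!is.finite(w_bar) || w_bar <= 0) next
    # quarter-period search: the anti-phase alias sits half a period away
    # and cannot enter; an anti-phase pair shows up as a negative peak
    L <- max(2L, floor((pi / 2) / w_bar * fs))
    lags <- -L:L
    cc <- vapply(lags, function(l) {
      i1 <- rng[rng + l >= 1 & rng + l <= length(t)]
      sum(x1[i1] * x2[i1 + l])
    }, numeric(1)) / (n1 * n2)
    im <- which.max(abs(cc))
    if (im == 1L || im == length(cc)) next  # boundary hit: incoherent window
    sgn <- sign(cc[im])
    ccs <- cc * sgn
    # competing peak check among local maxima away from the main one
    lm <- local_maxima(ccs)
    lm <- lm[abs(lm - im) > 2]
    if (length(lm) && max(ccs[lm]) > 0.95 * ccs[im]) amb[k] <- TRUE
    # parabolic sub-sample refinement
    lag_hat <- lags[im]
    d1 <- (ccs[im + 1] - ccs[im - 1]) / 2
    d2 <- ccs[im + 1] - 2 * ccs[im] + ccs[im - 1]
    if (d2 < 0) lag_hat <- lag_hat - d1 / d2
    psi_t[k] <- w_bar * lag_hat / fs
    sgn_t[k] <- sgn
    wts[k] <- abs(cc[im]) * n1 * n2
  }
  ok <- is.finite(psi_t)
  if (!any(ok)) stop("phase lag could not be estimated on any window")
  use <- ok & wts > 0.01 * max(wts)
  sgn <- sign(sum(sgn_t[use] * wts[use]))
  if (sgn == 0) sgn <- 1
  list(psi = stats::median(psi_t[use]), sign = sgn,
       psi_t = psi_t, t_centers = centers, ambiguous = mean(amb[ok]))
}

#' Re-synchronize the channel components of each mode
#'
#' Advances the second channel of mode `j` by the time lag `psi_j /
#' omega_j(t)` so that the two components oscillate in phase (up to sign) and
#' the amplitude-ratio eigenvector matrix becomes real, representative of
#' both the normalized stiffness and damping.
#'
#' @param sep output of [separate_modes()]
#' @param psi numeric length-`n_modes` phase lags (rad)
#' @param tracks `modal_track` with instantaneous frequencies
#' @param fs sampling rate (Hz)
#' @return `sep` with the second-channel components re-phased
#' @export
synchronize_modes <- function(sep, psi, tracks, fs) {
  t <- sep$t
  for (j in seq_along(psi)) {
    if (!is.finite(psi[j]) || abs(psi[j]) < 1e-12) next
    wj <- fill_gaps(tracks$t, tracks$omega[j, ])
    w_of_t <- stats::approx(tracks$t, wj, xout = t, rule = 2)$y
    dt <- psi[j] / pmax(w_of_t, 1e-6)
    x2 <- sep$components[j, 2, ]
    sep$components[j, 2, ] <- stats::approx(t, x2, xout = t + dt, rule = 2)$y
  }
  sep
}

#' Estimate the eigenvector matrix from modal amplitude ratios
#'
#' Column `j` of `U(t)` is `[1, r_j(t)]`: the signed ratio of the
#' instantaneous ridge amplitudes of mode `j` between the two channels, with
#' the first component normalized to one. When the tracks carry the complex
#' ridge-bin values, the ratio is estimated cross-spectrally: the in-phase
#' cross product between the channels is smoothed over time (coherent
#' averaging, which suppresses the skirt of the other mode rotating at the
#' beat frequency) and divided by the stronger channel's smoothed power, so
#' the reference of the ratio is never the channel in which the mode is
#' weak. The sign comes out of the in-phase product; samples with
#' cross-channel coherence below `coh_min` are masked. Without complex
#' values the plain amplitude ratio is used with the sign resolved from the
#' correlation of the (synchronized) mode components.
#'
#' @param tracks a smoothed `modal_track`
#' @param sep optional [separate_modes()] output (synchronized); sign falls
#'   back to positive when absent
#' @param signs optional explicit length-2 sign vector (from
#'   [estimate_phase_lag()]), overriding the component correlation
#' @param amp_floor relative amplitude below which a sample is masked
#' @param coh_min minimum squared cross-channel coherence at the ridge
#' @param orthogonal enforce orthogonal eigenvectors (valid for a symmetric
#'   normalized system): the less coherent column is replaced by the
#'   orthogonal complement of the better one
#' @param sg_order,sg_window Savitzky-Golay smoothing of the cross-spectral
#'   moments (matching [smooth_tracks()])
#' @return list with `U` (`2 x 2 x T`), `t`, and `mask` (`2 x T` validity)
#' @export
estimate_eigenvectors <- function(tracks, sep = NULL, signs = NULL,
                                  amp_floor = 1e-6, coh_min = 0.02,
                                  orthogonal = TRUE,
                                  sg_order = 3, sg_window = 0.25) {
  T_ <- length(tracks$t)
  U <- array(NA_real_, c(2, 2, T_))
  mask <- matrix(FALSE, 2, T_)
  if (!is.null(tracks$Sc)) {
    dt <- tracks$hop_s
    # the cross moments must be averaged over several beats of the
    # inter-mode difference frequency, where the residual interference
    # rotates; below that the ratio sign flaps at the beat rate
    dw <- stats::median(tracks$omega[2, ] - tracks$omega[1, ], na.rm = TRUE)
    w_s <- max(sg_window, if (is.finite(dw) && dw > 0) 3 * 2 * pi / dw else 0)
    span <- which(colSums(tracks$valid) > 0)
    idx <- min(span):max(span)
    n <- round(w_s / dt); if (n %% 2 == 0) n <- n + 1
    n <- max(n, sg_order + 3); if (n %% 2 == 0) n <- n + 1
    n <- min(n, length(idx) - (1 - length(idx) %% 2))
    smoo <- function(x) {
      x <- fill_gaps(tracks$t[idx], x)
      if (length(idx) > n && n > sg_order + 1) signal::sgolayfilt(x, p = sg_order, n = n) else x
    }
    psi_cross <- matrix(NA_real_, 2, T_)
    for (j in 1:2) {
      s1 <- fill_gaps_cplx(tracks$t[idx], tracks$Sc[j, 1, idx])
      s2 <- fill_gaps_cplx(tracks$t[idx], tracks$Sc[j, 2, idx])
      # factor out the common exponential decay before smoothing: the raw
      # powers fall several orders of magnitude across one smoothing window
      # and a polynomial fit of that produces negative lobes; the trend
      # cancels in every ratio formed below
      ptot <- Re(s1 * Conj(s1)) + Re(s2 * Conj(s2))
      g2 <- exp(smoo(log(pmax(ptot, .Machine$double.xmin))))
      p11 <- pmax(smoo(Re(s1 * Conj(s1)) / g2), 0)
      p22 <- pmax(smoo(Re(s2 * Conj(s2)) / g2), 0)
      crc <- complex(real = smoo(Re(s2 * Conj(s1)) / g2),
                     imaginary = smoo(Im(s2 * Conj(s1)) / g2))
      coh <- Mod(crc)^2 / pmax(p11 * p22, .Machine$double.xmin)
      coh[p11 * p22 <= .Machine$double.xmin] <- 0
      # the argument of the cross spectrum is the inter-channel phase lag
      # of the mode (folded onto (-pi/2, pi/2]: a sign flip of the ratio
      # contributes pi)
      ps <- Arg(crc)
      ps <- ps - pi * round(ps / pi)
      psi_cross[j, idx] <- ps
      # reference the (magnitude) ratio on the stronger channel; the sign
      # follows the in-phase part
      sgn <- ifelse(Re(crc) >= 0, 1, -1)
      cr <- sgn * Mod(crc)
      r <- ifelse(p22 > p11, p22 / cr, cr / p11)
      ok <- is.finite(r) & coh > coh_min & p11 > 0 & p22 > 0
      U[1, j, idx[ok]] <- 1
      U[2, j, idx[ok]] <- r[ok]
      mask[j, idx] <- ok
      if (j == 1) coh1 <- coh else coh2 <- coh
    }
    if (orthogonal) {
      # for a symmetric normalized system the eigenvectors are orthogonal:
      # derive the column whose cross-channel ratio is less coherent from
      # the better-determined one, instead of trusting a junk-dominated
      # weak-channel readout. Which column is trustworthy changes slowly
      # along a record (one mode's ratio degrades as its amplitude decays),
      # so the per-sample coherence comparison is median-smoothed in time:
      # brief flips between the two inconsistent estimates would inject
      # excursions wherever the junk coherence momentarily wins.
      pick1 <- as.numeric(coh1 >= coh2)
      pick1[!is.finite(pick1)] <- 1
      k <- min(round(0.5 / dt), length(pick1) - 1 + length(pick1) %% 2)
      if (k %% 2 == 0) k <- k - 1
      if (k >= 3) pick1 <- stats::runmed(pick1, k)
      for (q in seq_along(idx)) {
        i <- idx[q]
        r1 <- U[2, 1, i]; r2 <- U[2, 2, i]
        use1 <- pick1[q] >= 0.5 && is.finite(r1)
        if (use1 && abs(r1) > 1e-9) {
          U[1, 2, i] <- 1; U[2, 2, i] <- -1 / r1
          mask[2, i] <- mask[1, i]
        } else if (!use1 && is.finite(r2) && abs(r2) > 1e-9) {
          U[1, 1, i] <- 1; U[2, 1, i] <- -1 / r2
          mask[1, i] <- mask[2, i]
        }
      }
    }
    return(list(U = U, t = tracks$t, mask = mask, psi_cross = psi_cross))
  }
  if (is.null(signs)) {
    signs <- c(1, 1)
    if (!is.null(sep)) {
      for (j in 1:2) {
        ip <- sum(sep$components[j, 1, ] * sep$components[j, 2, ])
        if (is.finite(ip) && ip != 0) signs[j] <- sign(ip)
      }
    }
  }
  for (j in 1:2) {
    a1 <- tracks$A[j, 1, ]; a2 <- tracks$A[j, 2, ]
    ok <- is.finite(a1) & is.finite(a2) & a1 > amp_floor * max(a1, na.rm = TRUE)
    U[1, j, ok] <- 1
    U[2, j, ok] <- signs[j] * a2[ok] / a1[ok]
    mask[j, ] <- ok
  }
  list(U = U, t = tracks$t, mask = mask)
}

#' Instantaneous natural frequency and damping ratio
#'
#' Free-vibration relations on the smoothed tracks: the amplitude decay rate
#' `sigma_j(t) = -d ln A_j / dt` (Savitzky-Golay differentiation of the log
#' amplitude of the dominant channel) gives
#' \deqn{\omega_{n,j}^2 = \omega_{d,j}^2 + \sigma_j^2, \qquad
#'       \zeta_j = \sigma_j / \omega_{n,j}.}
#' In the stationary limit of a decaying linear oscillator both identities
#' are exact.
#'
#' @param tracks a smoothed `modal_track`
#' @param sg_order,sg_window Savitzky-Golay differentiation parameters
#'   (matching [smooth_tracks()])
#' @return list with `omega_n`, `zeta`, `sigma` (each `n_modes x T`)
#' @export
modal_parameters <- function(tracks, sg_order = 3, sg_window = 0.25) {
  dt <- tracks$hop_s
  n <- round(sg_window / dt); if (n %% 2 == 0) n <- n + 1
  n <- max(n, sg_order + 3)
  if (n %% 2 == 0) n <- n + 1
  nm <- nrow(tracks$omega)
  T_ <- length(tracks$t)
  omega_n <- zeta <- sigma <- matrix(NA_real_, nm, T_)
  span <- which(colSums(tracks$valid) > 0)
  idx <- min(span):max(span)
  if (length(idx) <= n) stop("valid track span shorter than the differentiation window")
  for (j in seq_len(nm)) {
    dom <- which.max(apply(tracks$A[j, , idx, drop = FALSE], 2, stats::median, na.rm = TRUE))
    a <- fill_gaps(tracks$t[idx], tracks$A[j, dom, idx])
    if (any(a <= 0)) stop("non-positive amplitudes; smooth the tracks first")
    sg <- -signal::sgolayfilt(log(a), p = sg_order, n = n, m = 1, ts = dt)
    wd <- fill_gaps(tracks$t[idx], tracks$omega[j, idx])
    wn <- sqrt(wd^2 + sg^2)
    sigma[j, idx] <- sg
    omega_n[j, idx] <- wn
    zeta[j, idx] <- sg / wn
  }
  list(omega_n = omega_n, zeta = zeta, sigma = sigma, t = tracks$t)
}

#' Reconstruct stiffness and damping matrices from the modal solution
#'
#' Per sample, rebuilds the normalized matrices from the identified
#' eigenstructure,
#' \deqn{\tilde K = U \,\mathrm{diag}(\omega_n^2)\, U^{-1}, \qquad
#'       \tilde C = U \,\mathrm{diag}(2 \zeta \omega_n)\, U^{-1},}
#' and maps them back to joint coordinates with the inertia square root:
#' `K = M^1/2 K_tilde M^1/2`, `C = M^1/2 C_tilde M^1/2`. Samples with an
#' ill-conditioned eigenvector matrix are masked. In symmetric mode (the
#' default, matching the symmetry assumption on the arm) the output matrices
#' are symmetrized.
#'
#' @param U `2 x 2 x T` eigenvector array (first row 1)
#' @param omega_n,zeta `2 x T` modal parameter arrays
#' @param M_half `2 x 2 x T` array of inertia square roots along the
#'   trajectory (or a single 2x2 matrix for posture)
#' @param neglect_damping use the resonant frequency in place of the natural
#'   frequency (`omega_n ~ omega_d` shortcut) -- pass `omega_d` as `omega_n`
#' @param symmetric symmetrize the reconstructed matrices
#' @param cond_max condition-number mask threshold for `U`
#' @return object of class `impedance_estimate`: `t`, arrays `K_hat`,
#'   `C_hat` (`2 x 2 x T`), `omega_n`, `zeta`, and logical `mask`
#' @export
reconstruct_matrices <- function(U, omega_n, zeta, M_half, t = NULL,
                                 neglect_damping = FALSE, symmetric = TRUE,
                                 cond_max = 1e3) {
  T_ <- dim(U)[3]
  if (is.matrix(M_half)) M_half <- array(M_half, c(2, 2, T_))
  K_hat <- C_hat <- array(NA_real_, c(2, 2, T_))
  mask <- rep(FALSE, T_)
  for (i in seq_len(T_)) {
    Ui <- U[, , i]
    if (any(!is.finite(Ui)) || any(!is.finite(omega_n[, i]))) next
    sv <- svd(Ui)$d
    if (sv[2] <= 0 || sv[1] / sv[2] > cond_max) next
    wn <- omega_n[, i]
    zi <- zeta[, i]
    Ki <- Ui %*% diag(wn^2) %*% solve(Ui)
    Ci <- Ui %*% diag(2 * zi * wn) %*% solve(Ui)
    Mh <- M_half[, , i]
    Kj <- Mh %*% Ki %*% Mh
    Cj <- Mh %*% Ci %*% Mh
    if (symmetric) { Kj <- (Kj + t(Kj)) / 2; Cj <- (Cj + t(Cj)) / 2 }
    K_hat[, , i] <- Kj; C_hat[, , i] <- Cj
    mask[i] <- TRUE
  }
  structure(list(t = t, K_hat = K_hat, C_hat = C_hat,
                 omega_n = omega_n, zeta = zeta, mask = mask,
                 neglect_damping = neglect_damping, symmetric = symmetric),
            class = "impedance_estimate")
}

#' Tabulate an impedance estimate
#' @param x an `impedance_estimate`
#' @param row.names,optional,... standard [as.data.frame()] arguments
#' @return data frame `(t, k11, k12, k22, c11, c12, c22, wn1, wn2, z1, z2, mask)`
#' @export
as.data.frame.impedance_estimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(t = if (is.null(x$t)) seq_len(length(x$mask)) else x$t,
             k11 = x$K_hat[1, 1, ], k12 = x$K_hat[1, 2, ], k22 = x$K_hat[2, 2, ],
             c11 = x$C_hat[1, 1, ], c12 = x$C_hat[1, 2, ], c22 = x$C_hat[2, 2, ],
             wn1 = x$omega_n[1, ], wn2 = x$omega_n[2, ],
             z1 = x$zeta[1, ], z2 = x$zeta[2, ], mask = x$mask)
}

#' Non-parametric normalized restoring-force curves
#'
#' Model-free characterization of the internal elastic field: for each mode,
#' the instantaneous natural frequency weights the modal displacement
#' (amplitude envelope), tracing the normalized force-versus-displacement
#' backbone `f_j(A) = omega_n_j^2(t) A_j(t)`. A linear field yields a
#' straight line with slope equal to the normalized stiffness eigenvalue; a
#' hardening cubic field bends the curve upward.
#'
#' @param tracks a smoothed `modal_track`
#' @param modal output of [modal_parameters()] on the same tracks
#' @param channel `"dominant"` or a channel index used for the displacement
#' @return list of data frames (one per mode) with columns `t`,
#'   `displacement`, `force`
#' @export
nonparametric_force <- function(tracks, modal, channel = "dominant") {
  out <- list()
  for (j in seq_len(nrow(tracks$omega))) {
    ch <- if (identical(channel, "dominant"))
      which.max(apply(tracks$A[j, , , drop = FALSE], 2, stats::median, na.rm = TRUE))
    else channel
    ok <- is.finite(modal$omega_n[j, ]) & is.finite(tracks$A[j, ch, ])
    y <- tracks$A[j, ch, ok]
    out[[j]] <- data.frame(t = tracks$t[ok], displacement = y,
                           force = modal$omega_n[j, ok]^2 * y)
  }
  out
}
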