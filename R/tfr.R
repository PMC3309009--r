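#' Analysis window specification
#'
#' Kaiser analysis window for the short-time Fourier transform and its
#' reassignment. The defaults (0.75 s, beta = 3, 2.5 ms hop) give a base
#' resolution of 1/0.75 = 1.33 Hz in frequency and 2.5 ms in time.
#'
#' @param duration window duration (s)
#' @param beta Kaiser shape parameter
#' @param hop hop size between consecutive frames (s)
#' @param pad_factor zero-padding factor of the FFT grid (frequency-axis
#'   interpolation before reassignment readout)
#' @return object of class `window_spec`
#' @export
window_spec <- function(duration = 0.75, beta = 3, hop = 0.0025,
                        pad_factor = 4) {
  if (duration <= 0) stop("window duration must be positive")
  if (hop > duration) stop("hop must not exceed the window duration")
  structure(list(duration = duration, beta = beta, hop = hop,
                 pad_factor = pad_factor), class = "window_spec")
}

# Kaiser window samples and the analytic time derivative dh/dt.
# x in [-1, 1]; h = I0(beta sqrt(1-x^2)) / I0(beta).
kaiser_window <- function(n, beta, fs) {
  x <- if (n == 1) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  arg <- sqrt(pmax(0, 1 - x^2))
  i0b <- besselI(beta, 0)
  h <- besselI(beta * arg, 0) / i0b
  # dh/dx = -beta x I1(beta a)/(a I0(beta)); limit at a -> 0 is -beta^2 x / (2 I0)
  dhdx <- ifelse(arg > 1e-8,
                 -beta * x * besselI(beta * arg, 1) / (arg * i0b),
                 -beta^2 * x / (2 * i0b))
  dt <- 1 / fs
  list(h = h, dh = dhdx * 2 / ((n - 1) * dt),
       tau = (seq_len(n) - (n + 1) / 2) * dt)
}

stft_engine <- function(x, fs, win, fmax, windows = c("h")) {
  n_win <- round(win$duration * fs)
  if (n_win > length(x)) stop("window longer than the signal")
  hop <- max(1L, round(win$hop * fs))
  nfft <- 2^ceiling(log2(win$pad_factor * n_win))
  kw <- kaiser_window(n_win, win$beta, fs)
  starts <- seq(1L, length(x) - n_win + 1L, by = hop)
  tframes <- (starts - 1 + (n_win - 1) / 2) / fs
  f_all <- (0:(nfft / 2)) * fs / nfft
  keep <- which(f_all <= fmax)
  out <- list()
  for (wn in windows) out[[wn]] <- matrix(0i, length(keep), length(starts))
  wvecs <- list(h = kw$h, th = kw$h * kw$tau, dh = kw$dh)
  chunk <- 512L
  for (i0 in seq(1L, length(starts), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(starts))
    seg <- matrix(0, nfft, length(idx))
    for (j in seq_along(idx))
      seg[1:n_win, j] <- x[starts[idx[j]]:(starts[idx[j]] + n_win - 1L)]
    for (wn in windows) {
      segw <- seg
      segw[1:n_win, ] <- segw[1:n_win, ] * wvecs[[wn]]
      X <- stats::mvfft(segw)
      out[[wn]][, idx] <- X[keep, , drop = FALSE]
    }
  }
  list(S = out, t = tframes, f = f_all[keep], nfft = nfft, n_win = n_win,
       hop = hop, sum_h = sum(kw$h), keep = keep, fs = fs)
}

#' Short-time Fourier transform spectrogram
#'
#' Complex STFT of a uniformly sampled signal on the frame grid defined by a
#' Kaiser [window_spec()]. Frequency bins above `fmax` are discarded (the
#' arm's vibrational content lives well below 30 Hz).
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param window a [window_spec()]
#' @param fmax highest frequency bin retained (Hz); `Inf` keeps the full
#'   half-spectrum
#' @return object of class `rspec`: frame times `t` (s), frequencies `f`
#'   (Hz), complex values `S` (`length(f) x length(t)`), `energy = |S|^2`,
#'   and (after [reassign()]) reassigned coordinates `that`, `fhat`
#' @export
stft <- function(x, fs, window = window_spec(), fmax = 30) {
  e <- stft_engine(x, fs, window, fmax, windows = "h")
  structure(list(t = e$t, f = e$f, S = e$S$h, energy = abs(e$S$h)^2,
                 that = NULL, fhat = NULL,
                 fs = fs, window = window, nfft = e$nfft, n_win = e$n_win,
                 hop = e$hop, sum_h = e$sum_h, t_span = c(0, (length(x) - 1) / fs)),
            class = "rspec")
}

#' Reassigned spectrogram
#'
#' Computes the STFT with the auxiliary windows `t h(t)` and `dh/dt` and
#' relocates each cell's energy to the phase-stationary coordinates
#' \deqn{\hat t = t + \Re\{S_{th}/S_h\}, \qquad
#'       \hat f = f - \Im\{S_{dh}/S_h\} / (2\pi).}
#' Cells whose energy lies more than `floor_db` below the frame maximum get
#' `NA` coordinates. Reassigned coordinates are clipped to the record's time
#' span and the Nyquist band.
#'
#' @inheritParams stft
#' @param floor_db per-frame dynamic-range floor for valid reassignment (dB)
#' @return an `rspec` with `that` and `fhat` filled in
#' @export
reassign <- function(x, fs, window = window_spec(), fmax = 30, floor_db = 60) {
  e <- stft_engine(x, fs, window, fmax, windows = c("h", "th", "dh"))
  Sh <- e$S$h
  ratio_t <- e$S$th / Sh
  ratio_f <- e$S$dh / Sh
  that <- sweep(Re(ratio_t), 2, e$t, "+")
  fhat <- sweep(-Im(ratio_f) / (2 * pi), 1, e$f, "+")
  E <- abs(Sh)^2
  fmaxes <- apply(E, 2, max)
  low <- sweep(E, 2, fmaxes * 10^(-floor_db / 10), "<") | !is.finite(that) | !is.finite(fhat)
  that[low] <- NA_real_; fhat[low] <- NA_real_
  tspan <- c(0, (length(x) - 1) / fs)
  that <- pmin(pmax(that, tspan[1]), tspan[2])
  fhat <- pmin(pmax(fhat, 0), fs / 2)
  structure(list(t = e$t, f = e$f, S = Sh, energy = E, that = that, fhat = fhat,
                 S_dh = e$S$dh,
                 fs = fs, window = window, nfft = e$nfft, n_win = e$n_win,
                 hop = e$hop, sum_h = e$sum_h, t_span = tspan),
            class = "rspec")
}

#' Remove the movement signature from a spectrogram
#'
#' Masks all bins below `cutoff_hz` (the slow reaching component lives at the
#' inverse of the movement duration, well below the arm's vibrational modes)
#' and optionally subtracts the average pre-perturbation magnitude profile
#' from every frame (for movement components overlapping the lowest mode).
#'
#' @param rs an `rspec`
#' @param t_onset perturbation onset (s)
#' @param cutoff_hz high-pass mask cutoff (Hz)
#' @param subtract_pre subtract the mean pre-onset magnitude spectrum
#' @return the modified `rspec`
#' @export
segregate_movement <- function(rs, t_onset, cutoff_hz = 1.2, subtract_pre = FALSE) {
  stopifnot(inherits(rs, "rspec"))
  if (t_onset < rs$t_span[1] || t_onset > rs$t_span[2])
    stop("t_onset outside the record")
  if (subtract_pre) {
    pre <- rs$t + rs$window$duration / 2 <= t_onset
    if (any(pre)) {
      ref_mag <- rowMeans(abs(rs$S[, pre, drop = FALSE]))
      mag <- abs(rs$S)
      newmag <- pmax(mag - ref_mag, 0)
      scale <- ifelse(mag > 0, newmag / mag, 0)
      rs$S <- rs$S * scale
    }
  }
  rs$S[rs$f < cutoff_hz, ] <- 0i
  rs$energy <- abs(rs$S)^2
  if (!is.null(rs$fhat)) {
    rs$fhat[rs$f < cutoff_hz, ] <- NA_real_
    rs$that[rs$f < cutoff_hz, ] <- NA_real_
  }
  rs
}

# local maxima (strictly greater than left neighbour, >= right) of a vector
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Extract instantaneous-frequency ridges
#'
#' Tracks the `n_modes` strongest ridges of the reassigned energy
#' distribution after the perturbation onset. Per frame, the cell energies
#' are accumulated at their reassigned frequencies into a fine histogram
#' (this is what distinguishes a reassigned ridge from a raw STFT peak:
#' window sidelobes collapse back onto the component that generated them);
#' ridge candidates are the local maxima of that distribution above a
#' per-frame dynamic-range floor. Tracks are seeded at the first frame whose
#' window has cleared the impulse and grown backward and forward by
#' frequency continuity within `gate_hz` (ties broken by higher energy).
#' Instantaneous amplitudes are read per channel at the ridge frequency and
#' converted with the window-energy normalization `A = 2 |S| / sum(h)`.
#'
#' @param rs_list an `rspec` from [reassign()], or a list of them (one per
#'   channel, identical grids)
#' @param n_modes number of ridges to track (2 for the two-joint arm)
#' @param t_onset perturbation onset (s); tracking starts half a hop after it
#' @param gate_hz frequency-continuity association gate (Hz)
#' @param fmin lowest admissible ridge frequency (Hz), keeps the movement
#'   band out
#' @param floor_db per-frame dynamic range for admissible ridge points (dB)
#' @param df_hist reassigned-frequency histogram resolution (Hz)
#' @return object of class `modal_track`: frame times `t`, angular
#'   frequencies `omega` (`n_modes x T`, rad/s, sorted ascending), amplitudes
#'   `A` (`n_modes x n_channels x T`), validity mask `valid`
#'   (`n_modes x T`). Attribute `low_confidence` is set when more than 20%
#'   of post-onset frames miss a mode.
#' @export
extract_ridges <- function(rs_list, n_modes = 2, t_onset, gate_hz = 1.2,
                           fmin = 1.2, floor_db = 60, df_hist = 0.05) {
  if (inherits(rs_list, "rspec")) rs_list <- list(rs_list)
  nch <- length(rs_list)
  rs1 <- rs_list[[1]]
  nt <- length(rs1$t)
  active <- which(rs1$t >= t_onset + rs1$window$hop / 2)
  if (!length(active)) stop("no frames after the perturbation onset")
  fmax_band <- max(rs1$f)
  nbin <- ceiling(fmax_band / df_hist) + 1L
  fgrid <- (seq_len(nbin) - 1) * df_hist

  # per-frame ridge candidates from the reassigned energy distribution
  candidates <- vector("list", nt)
  for (ti in active) {
    hist <- numeric(nbin)
    for (ch in seq_len(nch)) {
      fh <- rs_list[[ch]]$fhat[, ti]
      ok <- is.finite(fh)
      if (!any(ok)) next
      bins <- pmin(nbin, pmax(1L, round(fh[ok] / df_hist) + 1L))
      en <- rs_list[[ch]]$energy[ok, ti]
      tb <- tapply(en, bins, sum)
      hist[as.integer(names(tb))] <- hist[as.integer(names(tb))] + as.numeric(tb)
    }
    if (max(hist) <= 0) next
    # light smoothing to merge split peaks
    hs <- stats::filter(hist, rep(1 / 3, 3), sides = 2)
    hs[is.na(hs)] <- 0
    floor_e <- max(hs) * 10^(-floor_db / 10)
    pk <- local_maxima(as.numeric(hs))
    pk <- pk[fgrid[pk] >= fmin & hs[pk] > floor_e]
    if (!length(pk)) next
    cf <- ce <- numeric(length(pk))
    for (q in seq_along(pk)) {
      nb <- max(1, pk[q] - 3):min(nbin, pk[q] + 3)
      w <- hist[nb]
      cf[q] <- if (sum(w) > 0) sum(fgrid[nb] * w) / sum(w) else fgrid[pk[q]]
      ce[q] <- sum(w)
    }
    # greedy exclusion: drop candidates closer than the window resolution
    # to a stronger one (spectral-interference artefacts between ridges)
    sep_hz <- 0.8 / rs1$window$duration
    keep <- logical(0); kf <- numeric(0)
    for (q in order(ce, decreasing = TRUE)) {
      if (!length(kf) || min(abs(cf[q] - kf)) >= sep_hz) {
        keep <- c(keep, q); kf <- c(kf, cf[q])
      }
    }
    candidates[[ti]] <- list(f = cf[keep], e = ce[keep])
  }

  omega <- matrix(NA_real_, n_modes, nt)
  A <- array(NA_real_, c(n_modes, nch, nt))
  Sc <- array(NA_complex_, c(n_modes, nch, nt))
  E_rdg <- matrix(NA_real_, n_modes, nt)
  valid <- matrix(FALSE, n_modes, nt)

  read_amp <- function(ti, fridge) {
    # per-channel complex value read at the zero-padded bin nearest the
    # ridge frequency (reading a neighbourhood maximum would pick up the
    # skirt of a stronger mode nearby)
    bin <- which.min(abs(rs1$f - fridge))
    vapply(seq_len(nch), function(ch) rs_list[[ch]]$S[bin, ti], complex(1))
  }

  # seed at the first frame whose window no longer contains the onset
  seed_t <- t_onset + rs1$window$duration / 2 + 2 * rs1$window$hop
  seed_i <- active[which.min(abs(rs1$t[active] - seed_t))]
  have_seed <- !is.null(candidates[[seed_i]])
  if (!have_seed) {
    with_cand <- active[!vapply(candidates[active], is.null, logical(1))]
    if (!length(with_cand)) stop("no ridge candidates after the onset")
    seed_i <- with_cand[1]
  }
  cc <- candidates[[seed_i]]
  ord <- order(cc$e, decreasing = TRUE)
  pick <- ord[seq_len(min(n_modes, length(ord)))]
  seed_f <- sort(cc$f[pick])

  assoc_pass <- function(frames, seed_f) {
    last_f <- seed_f
    for (ti in frames) {
      cc <- candidates[[ti]]
      if (is.null(cc)) next
      used <- rep(FALSE, length(cc$f))
      for (j in seq_len(n_modes)) {
        if (is.na(last_f[j])) next
        within <- which(!used & abs(cc$f - last_f[j]) <= gate_hz)
        if (!length(within)) next
        dd <- abs(cc$f[within] - last_f[j])
        close <- within[dd <= min(dd) + 0.1]
        p <- close[which.max(cc$e[close])]
        omega[j, ti] <<- 2 * pi * cc$f[p]
        valid[j, ti] <<- TRUE
        E_rdg[j, ti] <<- cc$e[p]
        sv <- read_amp(ti, cc$f[p])
        Sc[j, , ti] <<- sv
        A[j, , ti] <<- 2 * abs(sv) / rs1$sum_h
        # the gate anchor moves slowly: a mode's frequency drifts with the
        # gain profile and arm configuration, while interference debris
        # scatters frame to frame and must not walk the track away
        last_f[j] <- 0.95 * last_f[j] + 0.05 * cc$f[p]
        used[p] <- TRUE
      }
    }
  }
  assoc_pass(seed_i:nt, seed_f)
  back <- active[active < seed_i]
  if (length(back)) assoc_pass(rev(back), seed_f)

  # Demix the ridge-bin readouts: with both ridge frequencies known, the
  # complex values at the two ridge bins are a linear mixture of the two
  # component amplitudes through the (known) window transform, so the
  # mutual sidelobe leakage -- which otherwise dominates the channel in
  # which a mode is weak -- can be removed exactly by solving a 2x2 system
  # per channel and frame.
  kw <- kaiser_window(rs1$n_win, rs1$window$beta, rs1$fs)
  nfd <- 2^ceiling(log2(rs1$n_win)) * 16L
  Wsp <- stats::fft(c(kw$h, rep(0, nfd - rs1$n_win)))
  W0 <- Wsp[1]
  wlook <- function(df_hz) {
    # window transform at a (possibly negative) frequency offset
    k <- df_hz * nfd / rs1$fs
    neg <- k < 0
    k <- abs(k)
    k0 <- pmin(floor(k), nfd / 2 - 2)
    fr <- k - k0
    v <- Wsp[k0 + 1] * (1 - fr) + Wsp[k0 + 2] * fr
    v[neg] <- Conj(v[neg])
    v / W0
  }
  both <- which(valid[1, ] & valid[2, ])
  for (ti in both) {
    fr <- omega[, ti] / (2 * pi)
    bins <- vapply(fr, function(fx) which.min(abs(rs1$f - fx)), integer(1))
    if (bins[1] == bins[2]) next
    G <- matrix(0i, 2, 2)
    for (i in 1:2) for (j in 1:2) G[i, j] <- wlook(rs1$f[bins[i]] - fr[j])
    if (Mod(G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]) < 1e-3) next
    for (ch in seq_len(nch)) {
      s <- vapply(bins, function(b) rs_list[[ch]]$S[b, ti], complex(1))
      a <- solve(G, s)
      Sc[, ch, ti] <- a
      A[, ch, ti] <- 2 * Mod(a) / rs1$sum_h
    }
  }
  # enforce ascending-frequency mode ordering
  med <- apply(omega, 1, stats::median, na.rm = TRUE)
  ord <- order(med)
  omega <- omega[ord, , drop = FALSE]
  A <- A[ord, , , drop = FALSE]
  Sc <- Sc[ord, , , drop = FALSE]
  E_rdg <- E_rdg[ord, , drop = FALSE]
  valid <- valid[ord, , drop = FALSE]
  miss <- rowMeans(!valid[, active, drop = FALSE])
  tr <- structure(list(t = rs1$t, omega = omega, A = A, Sc = Sc,
                       energy = E_rdg, valid = valid,
                       hop_s = rs1$window$hop, t_onset = t_onset,
                       n_channels = nch),
                  class = "modal_track")
  # a track is untrustworthy when it keeps dropping out, when its ridge
  # energy sits at the numerical-debris floor relative to the strongest
  # track, or when its frequency wanders frame to frame (a genuine ridge is
  # steady to a fraction of a bin; debris scatters across the gate)
  erel <- apply(E_rdg, 1, stats::median, na.rm = TRUE)
  weak <- is.na(erel) | erel < 1e-5 * max(erel, na.rm = TRUE)
  jitter <- vapply(seq_len(n_modes), function(j) {
    w <- omega[j, valid[j, ]]
    if (length(w) < 31) return(Inf)
    stats::median(abs(w - stats::runmed(w, 31))) * 1.4826
  }, numeric(1))
  attr(tr, "low_confidence") <- any(miss > 0.2) || any(weak) ||
    any(jitter > 0.8)
  tr
}

# linear interpolation over NA gaps, constant extrapolation
fill_gaps <- function(t, x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) return(x)
  stats::approx(t[ok], x[ok], xout = t, rule = 2)$y
}

fill_gaps_cplx <- function(t, z) {
  complex(real = fill_gaps(t, Re(z)), imaginary = fill_gaps(t, Im(z)))
}

#' Smooth modal tracks with a Savitzky-Golay filter
#'
#' Third-order Savitzky-Golay smoothing over `sg_window` seconds applied to
#' the instantaneous frequencies and (in the log domain) amplitudes. Gaps are
#' linearly interpolated before smoothing, so the result is continuous over
#' the valid span of each track.
#'
#' @param tracks a `modal_track` from [extract_ridges()]
#' @param sg_order polynomial order
#' @param sg_window filter window (s)
#' @return a smoothed `modal_track`
#' @export
smooth_tracks <- function(tracks, sg_order = 3, sg_window = 0.25) {
  stopifnot(inherits(tracks, "modal_track"))
  dt <- tracks$hop_s
  n <- round(sg_window / dt)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, sg_order + 2 + (sg_order %% 2 == 1))
  if (n %% 2 == 0) n <- n + 1
  span <- which(colSums(tracks$valid) > 0)
  if (!length(span)) stop("no valid track samples to smooth")
  idx <- min(span):max(span)
  if (length(idx) < n)
    stop("Savitzky-Golay window exceeds the valid track length")
  for (j in seq_len(nrow(tracks$omega))) {
    w <- fill_gaps(tracks$t[idx], tracks$omega[j, idx])
    tracks$omega[j, idx] <- signal::sgolayfilt(w, p = sg_order, n = n)
    for (ch in seq_len(tracks$n_channels)) {
      a <- fill_gaps(tracks$t[idx], tracks$A[j, ch, idx])
      a <- pmax(a, .Machine$double.xmin)
      tracks$A[j, ch, idx] <- exp(signal::sgolayfilt(log(a), p = sg_order, n = n))
    }
  }
  tracks$smoothed <- TRUE
  tracks
}

# Decay-adjusted ridge demixing refinement.
# A mode decaying at rate sigma loses a factor exp(-sigma*T_win) within one
# analysis window, so the stationary window transform misestimates its
# sidelobe at the other ridge. Given decay-rate estimates, the two-component
# mixture at the two ridge bins is re-solved with window transforms
# evaluated at the complex frequencies (omega_j - i sigma_j); amplitudes are
# referred to the window centre.
demix_tracks <- function(tracks, rs_list, sigma, t_free = tracks$t_onset) {
  if (inherits(rs_list, "rspec")) rs_list <- list(rs_list)
  rs1 <- rs_list[[1]]
  nch <- length(rs_list)
  kw <- kaiser_window(rs1$n_win, rs1$window$beta, rs1$fs)
  tau <- (seq_len(rs1$n_win) - 1) / rs1$fs
  half_shift <- (rs1$n_win - 1) / (2 * rs1$fs)
  both <- which(tracks$valid[1, ] & tracks$valid[2, ])
  t_on <- t_free
  for (ti in both) {
    fr <- tracks$omega[, ti] / (2 * pi)
    sg <- sigma[, ti]
    if (any(!is.finite(fr)) || any(!is.finite(sg))) next
    sg <- pmax(sg, 0)
    bins <- vapply(fr, function(fx) which.min(abs(rs1$f - fx)), integer(1))
    if (bins[1] == bins[2]) next
    # the free oscillation exists only after the onset: frames whose window
    # straddles it see a truncated component, so the window transform is
    # summed over the post-onset support only
    fstart <- rs1$t[ti] - half_shift
    hw <- kw$h
    if (!is.null(t_on) && fstart < t_on) hw[tau < (t_on - fstart)] <- 0
    if (!any(hw > 0)) next
    G <- matrix(0i, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      z <- -(sg[j] + 2i * pi * (rs1$f[bins[i]] - fr[j]))
      G[i, j] <- sum(hw * exp(z * tau))
    }
    if (Mod(G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]) <
        1e-3 * Mod(G[1, 1]) * Mod(G[2, 2])) next
    for (ch in seq_len(nch)) {
      s <- vapply(bins, function(b) rs_list[[ch]]$S[b, ti], complex(1))
      a <- solve(G, s)
      tracks$Sc[, ch, ti] <- a
      tracks$A[, ch, ti] <- 2 * Mod(a) * exp(-sg * half_shift)
    }
  }
  # demixed reassignment of the ridge frequency: subtract the other
  # component's predicted contribution from the h- and dh-window transforms
  # at the ridge bin, then apply the phase-derivative (reassignment)
  # frequency estimate to the cleaned values. This removes the
  # beat-frequency ripple that two-tone interference imprints on the ridge.
  has_dh <- all(vapply(rs_list, function(r) !is.null(r$S_dh), logical(1)))
  if (has_dh) {
    wc <- function(wvec, delta_hz, sig, live)
      sum(wvec[live] * exp(-(sig + 2i * pi * delta_hz) * tau[live]))
    # local chirp rate of each track (rad/s^2), for readout-bias correction
    n_sl <- round(0.25 / tracks$hop_s); if (n_sl %% 2 == 0) n_sl <- n_sl + 1
    alpha <- matrix(0, 2, length(tracks$t))
    for (j in 1:2) {
      w_fill <- fill_gaps(tracks$t, tracks$omega[j, ])
      if (sum(is.finite(w_fill)) > n_sl)
        alpha[j, ] <- signal::sgolayfilt(w_fill, p = 3, n = n_sl, m = 1,
                                         ts = tracks$hop_s)
    }
    tau_c <- tau - half_shift
    for (ti in both) {
      fr <- tracks$omega[, ti] / (2 * pi)
      sg <- pmax(sigma[, ti], 0)
      if (any(!is.finite(fr)) || any(!is.finite(sg))) next
      bins <- vapply(fr, function(fx) which.min(abs(rs1$f - fx)), integer(1))
      if (bins[1] == bins[2]) next
      fstart <- rs1$t[ti] - half_shift
      live <- if (!is.null(t_on) && fstart < t_on) tau >= (t_on - fstart)
              else rep(TRUE, length(tau))
      for (j in 1:2) {
        k <- 3 - j
        dom <- which.max(Mod(tracks$Sc[j, , ti]))
        ak <- tracks$Sc[k, dom, ti]
        if (!is.finite(Mod(ak))) next
        dkj <- rs1$f[bins[j]] - fr[k]
        sh <- rs_list[[dom]]$S[bins[j], ti] - ak * wc(kw$h, dkj, sg[k], live)
        sdh <- rs_list[[dom]]$S_dh[bins[j], ti] - ak * wc(kw$dh, dkj, sg[k], live)
        if (Mod(sh) == 0) next
        w_new <- 2 * pi * rs1$f[bins[j]] - Im(sdh / sh)
        # subtract the model-implied readout bias: for a decaying, linearly
        # chirping component the h/dh estimate does not read the frequency
        # at the frame centre; the offset is computable from the same sums
        wj <- tracks$omega[j, ti]
        phs <- (wj - 2 * pi * rs1$f[bins[j]]) * tau_c +
          alpha[j, ti] * tau_c^2 / 2
        mdl <- exp(complex(real = -sg[j] * tau_c, imaginary = phs))[live]
        mh <- sum(kw$h[live] * mdl); mdh <- sum(kw$dh[live] * mdl)
        if (Mod(mh) > 0) {
          bias <- (2 * pi * rs1$f[bins[j]] - Im(mdh / mh)) - wj
          # large predicted offsets (heavily truncated window, edge-noisy
          # chirp-rate estimate) are unreliable
          if (is.finite(bias) && abs(bias) < 0.05 * wj) w_new <- w_new - bias
        }
        if (is.finite(w_new) && abs(w_new - tracks$omega[j, ti]) < 2 * pi)
          tracks$omega[j, ti] <- w_new
      }
    }
  }
  tracks
}

#' Tabulate a modal track
#' @param x a `modal_track`
#' @param row.names,optional,... passed on conventions of [as.data.frame()]
#' @return data frame with columns `t`, `w_d1`, `w_d2`, per-channel
#'   amplitudes and validity flags
#' @export
as.data.frame.modal_track <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(t = x$t)
  for (j in seq_len(nrow(x$omega))) df[[paste0("w_d", j)]] <- x$omega[j, ]
  for (j in seq_len(nrow(x$omega)))
    for (ch in seq_len(x$n_channels))
      df[[paste0("A", j, "_q", ch)]] <- x$A[j, ch, ]
  for (j in seq_len(nrow(x$omega))) df[[paste0("valid", j)]] <- x$valid[j, ]
  df
}
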