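test_that("quadratic pencil eigenvalues match the scalar closed form", {
  m <- 0.05; c0 <- 0.3; k <- 30
  ev <- quadratic_eigen(diag(2) * m, diag(2) * c0, diag(2) * k)
  wn <- sqrt(k / m); z <- c0 / (2 * sqrt(k * m))
  expect_equal(Im(ev[1]), wn * sqrt(1 - z^2), tolerance = 1e-10)
  expect_equal(Re(ev[1]), -z * wn, tolerance = 1e-10)
})

two_tone_fixture <- function(psi2 = 0) {
  fs <- 400
  tt <- seq(0, 10, by = 1 / fs)
  A1 <- exp(-0.8 * tt); A2 <- exp(-1.2 * tt)
  m1 <- A1 * cos(2 * pi * 4 * tt)
  m2 <- A2 * cos(2 * pi * 9 * tt)
  m2s <- A2 * cos(2 * pi * 9 * tt - psi2)
  x <- rbind(m1 + 0.5 * m2, 0.8 * m1 + 1.0 * m2s)
  rs <- lapply(1:2, function(ch) reassign(x[ch, ], fs))
  tr <- smooth_tracks(extract_ridges(rs, 2, t_onset = 0))
  list(fs = fs, t = tt, x = x, m1 = m1, m2 = m2, m2s = m2s, tracks = tr)
}

test_that("mode separation recovers the constituents of a two-tone mixture", {
  fx <- two_tone_fixture()
  sep <- separate_modes(fx$x, fx$fs, fx$tracks)
  i <- which(fx$t > 1 & fx$t < 6)
  expect_gt(stats::cor(sep$components[1, 1, i], fx$m1[i]), 0.99)
  expect_gt(stats::cor(sep$components[1, 2, i], fx$m1[i]), 0.99)
  expect_gt(stats::cor(sep$components[2, 1, i], fx$m2[i]), 0.99)
  expect_gt(stats::cor(sep$components[2, 2, i], fx$m2[i]), 0.99)
  # additivity: the two components rebuild the band-limited signal
  rebuilt <- sep$components[1, 1, i] + sep$components[2, 1, i]
  expect_lt(sqrt(mean((rebuilt - fx$x[1, i])^2)) / sqrt(mean(fx$x[1, i]^2)), 0.02)
})

test_that("a single-mode signal leaves the second band empty", {
  fs <- 400
  tt <- seq(0, 8, by = 1 / fs)
  m1 <- exp(-0.5 * tt) * cos(2 * pi * 4 * tt)
  x <- rbind(m1, 0.6 * m1)
  # hand-built tracks with a fictitious high mode so the split is defined
  nt0 <- length(seq(0, 8 - 0.75, by = 0.0025)) + 1
  rs <- lapply(1:2, function(ch) reassign(x[ch, ], fs))
  tr <- extract_ridges(rs, 2, t_onset = 0)
  tr$omega[1, ] <- 2 * pi * 4; tr$omega[2, ] <- 2 * pi * 9
  tr$valid[] <- TRUE
  sep <- separate_modes(x, fs, tr)
  i <- which(tt > 1 & tt < 6)
  r1 <- sqrt(mean(sep$components[1, 1, i]^2))
  r2 <- sqrt(mean(sep$components[2, 1, i]^2))
  expect_lt(r2, 0.01 * r1)
})

test_that("phase lag is recovered from the component cross-correlation", {
  # pure two-channel tone with an imposed 0.3 rad shift: sub-0.01 recovery
  fs <- 400
  tt <- seq(0, 8, by = 1 / fs)
  x1 <- cos(2 * pi * 9 * tt)
  x2 <- 0.7 * cos(2 * pi * 9 * tt - 0.3)
  pl0 <- estimate_phase_lag(x1, x2, tt, rep(2 * pi * 9, length(tt)), fs,
                            interval = c(0.5, 5))
  expect_lt(abs(pl0$psi - 0.3), 0.01)
  expect_equal(pl0$sign, 1)
  # a decaying envelope skews the correlation peak by about atan(sigma/omega)
  Ae <- exp(-1.0 * tt)
  pl_d <- estimate_phase_lag(Ae * x1, Ae * x2, tt,
                             rep(2 * pi * 9, length(tt)), fs,
                             interval = c(0.5, 5))
  expect_lt(abs(pl_d$psi - 0.3), 0.01 + atan(1 / (2 * pi * 9)))
  # anti-phase pair (no extra shift): lag near zero, negative polarity
  pl_neg <- estimate_phase_lag(x1, -0.7 * x1, tt, rep(2 * pi * 9, length(tt)),
                               fs, interval = c(0.5, 5))
  expect_lt(abs(pl_neg$psi), 0.05)
  expect_equal(pl_neg$sign, -1)
  # band-separated two-tone mixture: mild leakage, still within 0.03
  fx <- two_tone_fixture(psi2 = 0.3)
  sep <- separate_modes(fx$x, fx$fs, fx$tracks)
  w2 <- stats::approx(fx$tracks$t, fx$tracks$omega[2, ], xout = fx$t, rule = 2)$y
  pl <- estimate_phase_lag(sep$components[2, 1, ], sep$components[2, 2, ],
                           fx$t, w2, fx$fs, interval = c(1, 5))
  expect_lt(abs(pl$psi - 0.3), 0.03)
  expect_equal(pl$sign, 1)
  w1 <- stats::approx(fx$tracks$t, fx$tracks$omega[1, ], xout = fx$t, rule = 2)$y
  pl1 <- estimate_phase_lag(sep$components[1, 1, ], sep$components[1, 2, ],
                            fx$t, w1, fx$fs, interval = c(1, 5))
  expect_lt(abs(pl1$psi), 0.05)
})

test_that("synchronization removes an imposed lag and is a no-op at zero", {
  fx <- two_tone_fixture(psi2 = 0.3)
  sep <- separate_modes(fx$x, fx$fs, fx$tracks)
  sep0 <- synchronize_modes(sep, c(0, 0), fx$tracks, fx$fs)
  expect_identical(sep0$components, sep$components)
  sync <- synchronize_modes(sep, c(0, 0.3), fx$tracks, fx$fs)
  w2 <- stats::approx(fx$tracks$t, fx$tracks$omega[2, ], xout = fx$t, rule = 2)$y
  pl <- estimate_phase_lag(sync$components[2, 1, ], sync$components[2, 2, ],
                           fx$t, w2, fx$fs, interval = c(1, 5))
  expect_lt(abs(pl$psi), 0.02)
})

test_that("free-vibration relations satisfy the stationary-limit identities", {
  nt <- 2000
  t <- (seq_len(nt) - 1) * 0.0025
  mk <- function(Aexp, wd) {
    A <- array(NA_real_, c(2, 2, nt))
    A[1, 1, ] <- Aexp; A[1, 2, ] <- 0.5 * Aexp
    A[2, 1, ] <- Aexp; A[2, 2, ] <- 0.3 * Aexp
    structure(list(t = t, omega = rbind(rep(wd, nt), rep(3 * wd, nt)),
                   A = A, Sc = NULL, valid = matrix(TRUE, 2, nt),
                   hop_s = 0.0025, t_onset = 0, n_channels = 2),
              class = "modal_track")
  }
  # constant amplitude: undamped limit
  mp <- modal_parameters(mk(rep(1, nt), 20))
  inner <- 200:(nt - 200)
  expect_equal(mp$omega_n[1, inner], rep(20, length(inner)), tolerance = 1e-6)
  expect_lt(max(abs(mp$zeta[1, inner])), 1e-6)
  # exponential decay: omega_n^2 = omega_d^2 + sigma^2, zeta = sigma / omega_n
  sg <- 2.5
  mp <- modal_parameters(mk(exp(-sg * t), 20))
  expect_equal(mp$sigma[1, inner], rep(sg, length(inner)), tolerance = 1e-4)
  expect_equal(mp$omega_n[1, inner], rep(sqrt(400 + sg^2), length(inner)),
               tolerance = 1e-4)
  expect_equal(mp$zeta[1, inner], rep(sg / sqrt(400 + sg^2), length(inner)),
               tolerance = 1e-4)
})

test_that("matrix reconstruction inverts the analytic decomposition exactly", {
  K <- matrix(c(30, 11, 11, 40), 2, 2)
  C <- matrix(c(0.5, 0.12, 0.12, 0.3), 2, 2)
  M <- inertia_matrix(fx_params(), c(0, 1.9))
  ns <- normalize_system(M)
  Kt <- ns$M_half_inv %*% K %*% ns$M_half_inv
  Ct <- ns$M_half_inv %*% C %*% ns$M_half_inv
  eK <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  ord <- order(eK$values)
  U1 <- eK$vectors[, ord]
  U1 <- sweep(U1, 2, U1[1, ], "/")
  wn <- sqrt(eK$values[ord])
  # project the damping on the stiffness eigenvectors (classical part)
  Cm <- solve(U1) %*% Ct %*% U1
  zeta <- diag(Cm) / (2 * wn)
  Ct_cl <- U1 %*% diag(2 * zeta * wn) %*% solve(U1)
  T_ <- 5
  U <- array(U1, c(2, 2, T_))
  est <- reconstruct_matrices(U, matrix(wn, 2, T_), matrix(zeta, 2, T_),
                              ns$M_half, t = seq_len(T_), symmetric = FALSE)
  for (i in seq_len(T_)) {
    expect_equal(est$K_hat[, , i], K, tolerance = 1e-8)
    expect_equal(est$C_hat[, , i], ns$M_half %*% Ct_cl %*% ns$M_half,
                 tolerance = 1e-8)
  }
  # symmetric mode returns exactly symmetric matrices
  ests <- reconstruct_matrices(U, matrix(wn, 2, T_), matrix(zeta, 2, T_),
                               ns$M_half, symmetric = TRUE)
  expect_identical(ests$K_hat[1, 2, 1], ests$K_hat[2, 1, 1])
  # ill-conditioned eigenvectors are masked
  Ubad <- U; Ubad[, 2, ] <- Ubad[, 1, ] * (1 + 1e-6)
  estb <- reconstruct_matrices(Ubad, matrix(wn, 2, T_), matrix(zeta, 2, T_),
                               ns$M_half)
  expect_false(any(estb$mask))
})

test_that("amplitude scale invariance: a common factor leaves the solution unchanged", {
  est <- fx_posture_estimate()
  tr <- est$tracks
  tr2 <- tr
  tr2$A <- tr$A * 7.3
  tr2$Sc <- tr$Sc * 7.3
  e1 <- estimate_eigenvectors(tr)
  e2 <- estimate_eigenvectors(tr2)
  i <- which(e1$mask[1, ] & e2$mask[1, ])
  expect_equal(e1$U[, , i], e2$U[, , i], tolerance = 1e-10)
  m1 <- modal_parameters(tr)
  m2 <- modal_parameters(tr2)
  ok <- is.finite(m1$omega_n)
  expect_equal(m1$omega_n[ok], m2$omega_n[ok], tolerance = 1e-10)
  expect_equal(m1$zeta[ok], m2$zeta[ok], tolerance = 1e-10)
})

test_that("posture pipeline recovers the modal quantities of the pencil truth", {
  est <- fx_posture_estimate()
  rec <- fx_posture_record()
  ev <- fx_qep_truth(rec$model, rec$q_ref[, 1])
  sel <- which(est$mask & est$t > 3 & est$t < 4.5)
  for (j in 1:2) {
    wd_med <- stats::median(est$tracks$omega[j, sel])
    expect_equal(wd_med, Im(ev[j]), tolerance = 0.02 * Im(ev[j]))
    # modal stiffness within 2%, decay (damping) within 10%
    wn_med <- stats::median(est$modal$omega_n[j, sel])
    wn_true <- Mod(ev[j])
    expect_equal(wn_med^2, wn_true^2, tolerance = 0.02 * wn_true^2)
    sg_med <- stats::median(est$modal$sigma[j, sel])
    expect_equal(sg_med, -Re(ev[j]), tolerance = 0.10 * abs(Re(ev[j])))
  }
})

test_that("classically damped posture shows near-zero mode phase lags", {
  est <- fx_posture_estimate()
  expect_lt(max(abs(est$psi)), 0.02 + 0.02)  # estimate near the small true lag
})

test_that("non-parametric force of a linear field is a line with the modal slope", {
  est <- fx_posture_estimate()
  rec <- fx_posture_record()
  npf <- nonparametric_force(est$tracks, est$modal)
  ev <- fx_qep_truth(rec$model, rec$q_ref[, 1])
  for (j in 1:2) {
    d <- npf[[j]]
    d <- d[d$t > 3 & d$t < 4.5, ]
    fit <- stats::lm(force ~ displacement - 1, data = d)
    slope <- stats::coef(fit)[[1]]
    expect_equal(slope, Mod(ev[j])^2, tolerance = 0.05 * Mod(ev[j])^2)
    # linear: cubic augmentation barely improves the fit
    cub <- stats::lm(force ~ displacement + I(displacement^3) - 1, data = d)
    expect_gt(sum(stats::resid(cub)^2) / sum(stats::resid(fit)^2), 0.2)
  }
})
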