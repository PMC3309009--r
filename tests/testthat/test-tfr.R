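test_that("STFT grid matches the window specification", {
  fs <- 4000
  x <- sin(2 * pi * 5 * seq(0, 3, by = 1 / fs))
  sp <- stft(x, fs)
  # hop of 2.5 ms; base frequency resolution 1/duration
  expect_equal(diff(sp$t)[1], 0.0025)
  expect_equal(fs / sp$n_win, 1 / 0.75, tolerance = 1e-3)
  # all-zero signal
  expect_equal(max(stft(numeric(8000), fs)$energy), 0)
  # pure tone: frame-wise magnitude peak at the tone within one base bin
  pk <- sp$f[apply(abs(sp$S), 2, which.max)]
  expect_true(all(abs(pk - 5) <= 1 / 0.75))
  expect_lt(stats::sd(pk), 0.2)
  expect_error(stft(numeric(100), fs), "window longer")
})

test_that("plain STFT satisfies Parseval frame by frame", {
  fs <- 400
  set.seed(8)
  x <- stats::rnorm(3000)
  sp <- stft(x, fs, fmax = Inf)
  kw <- armtf:::kaiser_window(sp$n_win, sp$window$beta, fs)
  for (ti in c(3, 10, 20)) {
    start <- 1 + (ti - 1) * sp$hop
    xw <- x[start:(start + sp$n_win - 1)] * kw$h
    # one-sided spectrum stored: double the interior bins
    w <- rep(2, length(sp$f)); w[1] <- 1
    if (sp$nfft %% 2 == 0 && length(sp$f) == sp$nfft / 2 + 1) w[length(w)] <- 1
    lhs <- sum(w * abs(sp$S[, ti])^2) / sp$nfft
    expect_equal(lhs, sum(xw^2), tolerance = 1e-6)
  }
})

test_that("reassignment sharpens tones and chirps beyond the bin resolution", {
  fs <- 400
  tt <- seq(0, 10, by = 1 / fs)
  rs <- reassign(cos(2 * pi * 8 * tt), fs)
  mid <- which(rs$t > 1 & rs$t < 9)
  fr <- vapply(mid, function(i) rs$fhat[which.max(abs(rs$S[, i])), i], numeric(1))
  expect_lt(max(abs(fr - 8)), 0.05)
  # linear chirp 2 -> 12 Hz over 10 s: ridge tracks the analytic law
  x <- cos(2 * pi * (2 * tt + 0.5 * tt^2))
  rs <- reassign(x, fs)
  mid <- which(rs$t > 1 & rs$t < 9)
  err_rs <- vapply(mid, function(i) {
    pk <- which.max(abs(rs$S[, i]))
    rs$fhat[pk, i] - (2 + 1 * rs$t[i])
  }, numeric(1))
  err_bin <- vapply(mid, function(i) {
    pk <- which.max(abs(rs$S[, i]))
    rs$f[pk] - (2 + 1 * rs$t[i])
  }, numeric(1))
  expect_lt(stats::median(abs(err_rs), na.rm = TRUE), 0.2)
  expect_gt(stats::median(abs(err_bin)) + 0.01, stats::median(abs(err_rs), na.rm = TRUE))
  # coordinates never leave the record span or the Nyquist band
  expect_true(all(rs$that >= 0 & rs$that <= max(tt), na.rm = TRUE))
  expect_true(all(rs$fhat >= 0 & rs$fhat <= fs / 2, na.rm = TRUE))
})

test_that("an isolated impulse reassigns energy toward its instant", {
  fs <- 400
  x <- numeric(4001); x[2001] <- 1
  rs <- reassign(x, fs, fmax = 50)
  t0 <- 2000 / fs
  near <- which(abs(rs$t - t0) < 0.3 & abs(rs$t - t0) > 0.05)
  conc <- abs(rs$that[, near] - t0)
  raw <- abs(matrix(rs$t[near], nrow(conc), length(near), byrow = TRUE) - t0)
  expect_lt(stats::median(conc, na.rm = TRUE), stats::median(raw) / 5)
})

test_that("movement segregation attenuates the slow band and keeps the modes", {
  fs <- 400
  tt <- seq(0, 20, by = 1 / fs)
  x <- 1.0 * sin(2 * pi * 0.2 * tt) + 0.05 * sin(2 * pi * 6 * tt)
  rs <- reassign(x, fs)
  out <- segregate_movement(rs, t_onset = 2, cutoff_hz = 1.2)
  mid <- which(out$t > 5 & out$t < 15)
  band <- function(sp, f0) {
    bins <- which(abs(sp$f - f0) < 0.5)
    mean(sqrt(colSums(abs(sp$S[bins, mid, drop = FALSE])^2)))
  }
  expect_lt(20 * log10(band(out, 0.2) / band(rs, 0.2)), -20)
  expect_lt(abs(20 * log10(band(out, 6) / band(rs, 6))), 1)
})

test_that("ridge extraction tracks two decaying tones and orders them", {
  fs <- 400
  tt <- seq(0, 8, by = 1 / fs)
  on <- tt >= 1
  x1 <- exp(-0.8 * pmax(tt - 1, 0)) * cos(2 * pi * 4 * tt) * on
  x2 <- exp(-1.1 * pmax(tt - 1, 0)) * cos(2 * pi * 9 * tt + 0.4) * on
  x <- rbind(x1 + 0.4 * x2, 0.5 * x1 + x2)
  rs <- lapply(1:2, function(ch) reassign(x[ch, ], fs))
  tr <- smooth_tracks(extract_ridges(rs, n_modes = 2, t_onset = 1))
  sel <- tr$t > 1.6 & tr$t < 5
  expect_lt(max(abs(tr$omega[1, sel] / (2 * pi) - 4), na.rm = TRUE), 0.2)
  expect_lt(max(abs(tr$omega[2, sel] / (2 * pi) - 9), na.rm = TRUE), 0.2)
  expect_true(all(tr$omega[1, sel] < tr$omega[2, sel], na.rm = TRUE))
  expect_false(isTRUE(attr(tr, "low_confidence")))
  # single-mode signal with two requested tracks: low confidence flagged
  y <- rbind(x1, 0.5 * x1)
  rs1 <- lapply(1:2, function(ch) reassign(y[ch, ], fs))
  tr1 <- extract_ridges(rs1, n_modes = 2, t_onset = 1)
  expect_true(attr(tr1, "low_confidence"))
})

test_that("Savitzky-Golay smoothing of tracks denoises without bias and passes cubics", {
  fs_tr <- 400
  nt <- 1200
  t <- (seq_len(nt) - 1) * 0.0025
  mk_tracks <- function(w1) {
    structure(list(t = t, omega = rbind(w1, w1 * 3),
                   A = array(rep(1e-3, 2 * 2 * nt), c(2, 2, nt)),
                   Sc = NULL,
                   valid = matrix(TRUE, 2, nt), hop_s = 0.0025,
                   t_onset = 0, n_channels = 2), class = "modal_track")
  }
  set.seed(9)
  noisy <- 2 * pi * (5 + stats::rnorm(nt, 0, 0.05))
  sm <- smooth_tracks(mk_tracks(noisy))
  inner <- 100:(nt - 100)
  expect_lt(stats::sd(sm$omega[1, inner]) * 3, stats::sd(noisy[inner]))
  expect_lt(abs(mean(sm$omega[1, inner]) / (2 * pi) - 5), 0.02)
  # an exact cubic is invariant under 3rd-order SG smoothing
  cub <- 30 + 2 * t + 0.5 * t^2 - 0.1 * t^3
  smc <- smooth_tracks(mk_tracks(cub))
  expect_equal(smc$omega[1, inner], cub[inner], tolerance = 1e-9)
  # window longer than the valid track errors out
  short <- mk_tracks(noisy)
  short$valid[, 30:nt] <- FALSE
  expect_error(smooth_tracks(short, sg_window = 0.25), "window exceeds")
})

test_that("modal tracks tabulate with the documented columns", {
  tr <- fx_posture_estimate()$tracks
  df <- as.data.frame(tr)
  expect_true(all(c("t", "w_d1", "w_d2", "A1_q1", "A2_q2", "valid1", "valid2")
                  %in% names(df)))
})
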