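stationary_force_trials <- function() {
  if (is.null(.fx$force_trials)) {
    traj <- fx_posture_traj()
    model <- kv_reference()
    .fx$force_trials <- lapply(1:8, function(d) simulate_trial(
      model, traj,
      perturbation_spec("force_pulse", direction = octant_direction(d),
                        t_onset = 2.5),
      t_stop = 2.8))
  }
  .fx$force_trials
}

stationary_servo_trials <- function() {
  if (is.null(.fx$servo_trials)) {
    traj <- fx_posture_traj()
    model <- kv_reference()
    .fx$servo_trials <- lapply(1:8, function(d) servo_response(
      model, traj,
      perturbation_spec("servo_displacement", direction = octant_direction(d),
                        t_onset = 2.5),
      t_stop = 2.9))
  }
  .fx$servo_trials
}

test_that("force-pulse full regression recovers the stationary system", {
  model <- kv_reference()
  fe <- force_full_regression(stationary_force_trials(), 2.5)
  expect_equal(fe$K_hat, model$K0, tolerance = 5e-3)
  expect_equal(fe$C_hat, model$C0, tolerance = 5e-2)
  expect_equal(fe$M_hat, inertia_matrix(fx_params(), fx_posture_traj()$q[, 1]),
               tolerance = 5e-3)
  expect_equal(fe$n_perturbations, 8)
  expect_error(force_full_regression(stationary_force_trials()[1:4], 2.5),
               "at least 8")
})

test_that("servo perturbation reproduces the 8 mm ramp-plateau-ramp profile", {
  rec <- stationary_servo_trials()[[3]]
  amp <- armtf:::servo_profile(rec$perturbation, rec$t)
  expect_equal(max(amp), 0.008)
  expect_lt(abs(sum(amp >= 0.008 - 1e-12) / rec$fs - 0.1), 2 / rec$fs)
  expect_lt(abs(sum(amp > 0) / rec$fs - 0.3), 2 / rec$fs)
})

test_that("displacement regressions are exact on the stationary rigid-servo case", {
  model <- kv_reference()
  de <- displacement_full_regression(stationary_servo_trials(), 2.5)
  expect_equal(de$K_hat, model$K0, tolerance = 1e-6)
  se <- steady_state_regression(stationary_servo_trials(), 2.5)
  expect_equal(se$K_hat, model$K0, tolerance = 1e-6)
  expect_null(se$C_hat)
  # the three estimators agree mutually within 1%
  fe <- force_full_regression(stationary_force_trials(), 2.5)
  expect_equal(max(abs(fe$K_hat - de$K_hat)) / max(abs(model$K0)) , 0, tolerance = 0.01)
  expect_equal(max(abs(se$K_hat - de$K_hat)) / max(abs(model$K0)) , 0, tolerance = 0.01)
})

test_that("mid-movement steady-state stiffness picks up a dynamic asymmetry", {
  model <- kv_reference()
  traj <- fx_reach_traj()
  recs <- lapply(1:8, function(d) servo_response(
    model, traj,
    perturbation_spec("servo_displacement", direction = octant_direction(d),
                      t_onset = 2.2),
    t_stop = 2.6))
  se <- steady_state_regression(recs, 2.2)
  asym_dyn <- abs(se$K_hat[1, 2] - se$K_hat[2, 1])
  se0 <- steady_state_regression(stationary_servo_trials(), 2.5)
  asym_stat <- abs(se0$K_hat[1, 2] - se0$K_hat[2, 1])
  expect_gt(asym_dyn, 10 * max(asym_stat, 1e-9))
})

test_that("time-varying stiffness: the pulse regression reports the window average", {
  model <- kv_reference(gK = gain_profile("sharp"))
  traj <- fx_posture_traj()
  recs <- lapply(1:8, function(d) simulate_trial(
    model, traj,
    perturbation_spec("force_pulse", direction = octant_direction(d),
                      t_onset = 2.5), t_stop = 2.8))
  fe <- force_full_regression(recs, 2.5)
  g <- gain(model$gK, seq(2.5, 2.7, by = 1e-3))
  g_window <- mean(g)
  # recovered k22 lies between the window extremes, near the window mean
  expect_gt(fe$K_hat[2, 2], min(g) * model$K0[2, 2] * 0.99)
  expect_lt(fe$K_hat[2, 2], max(g) * model$K0[2, 2] * 1.01)
  expect_equal(fe$K_hat[2, 2], g_window * model$K0[2, 2],
               tolerance = 0.5 * (max(g) - min(g)) * model$K0[2, 2])
})

test_that("cubic Hermite profile interpolates the punctual estimates", {
  pts <- lapply(1:5, function(i) armtf:::punctual_estimate(
    t_star = 2 + 0.5 * i,
    K_hat = matrix(c(10 + i, 2, 2, 20 + 2 * i), 2, 2),
    C_hat = matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2) * i,
    method = "disp_full", n_perturbations = 8))
  prof <- hermite_profile(pts)
  ts <- vapply(pts, function(p) p$t_star, numeric(1))
  at_knots <- prof(ts)
  for (i in 1:5) {
    expect_equal(at_knots$K[, , i], pts[[i]]$K_hat, tolerance = 1e-12)
    expect_equal(at_knots$C[, , i], pts[[i]]$C_hat, tolerance = 1e-12)
  }
  # linear knots reproduce the line between them (k11 knots are 11..15)
  tq <- seq(2.5, 4.5, by = 0.01)
  lin <- prof(tq)$K[1, 1, ]
  expect_equal(lin, 11 + (tq - 2.5) * 2, tolerance = 1e-9)
  expect_error(hermite_profile(pts[1]), "at least two")
  pts2 <- pts; pts2[[2]]$t_star <- pts2[[1]]$t_star
  expect_error(hermite_profile(pts2), "strictly increasing")
})

test_that("percentage RMS error behaves as a scale-free profile metric", {
  t <- seq(0, 1, by = 0.01)
  truth <- rep(4, length(t))
  expect_equal(percent_rmse(truth, truth, t), 0)
  expect_equal(percent_rmse(1.1 * truth, truth, t), 10, tolerance = 1e-10)
  expect_error(percent_rmse(truth, 0 * truth, t), "zero RMS")
})

test_that("the experiment runner is deterministic and follows the protocol", {
  cfg <- list(methods = "disp_steady", k_profiles = "sigmoid",
              c_profiles = "constant", conditions = "posture",
              t_stars = c(2.5, 3.0, 3.5), seed = 99L)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$report, r2$report)
  expect_null(r1$failures)
  expect_true(all(c("method", "k_profile", "interval", "coefficient",
                    "rmse_pct") %in% names(r1$report)))
  expect_setequal(unique(r1$report$interval), c("full", "early"))
  # stiffness-only method reports no damping rows
  expect_false(any(grepl("^c", r1$report$coefficient)))
})
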