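test_that("z-drift commutes with Iz and dephases I- by the analytic phase", {
  ge <- gradient_event("half_sine", 1e-3, 1, 2.5e-5)
  # [Hz, Iz] = 0: overlap stays 1 at every time point
  tr <- propagate(sys_h, "z", gradient = ge, drift_T = 2.5e-5)
  expect_true(all(abs(tr$overlap - 1) < 1e-12))
  # I-: final overlap = cos(phase), phase = gamma*A*integral of profile.
  # The propagator is exact for the midpoint-sampled profile...
  n <- 250; dt <- 1e-3 / n
  t_mid <- (seq_len(n) - 0.5) * dt
  phase_mid <- 2.675e8 * 2.5e-5 * sum(sin(pi * t_mid / 1e-3)) * dt
  tr2 <- propagate(sys_h, "-", gradient = ge, drift_T = 2.5e-5)
  expect_equal(acos(tr2$final), acos(cos(phase_mid)), tolerance = 1e-8)
  # ...and converges to the analytic integral 2*tau/pi at O(dt^2)
  phase_true <- 2.675e8 * 2.5e-5 * (2e-3 / pi)
  err1 <- abs(acos(tr2$final) - (2 * pi - phase_true))
  tr3 <- propagate(sys_h, "-", gradient = ge, drift_T = 2.5e-5,
                   slice_dt = 2e-6)
  err2 <- abs(acos(tr3$final) - (2 * pi - phase_true))
  expect_lt(err2, err1 / 3.5)   # halved slice width: error / ~4
})

test_that("propagators are unitary and norm is conserved", {
  p <- random_pulse(seed = 3)
  res <- clocr:::window_propagate(sys_h, p, gradient_event(),
                                  drift_T = 1.8e-5, b1_scale = 1.1,
                                  offset_hz = 900, keep_steps = TRUE)
  U <- res$U
  expect_lt(max(abs(Conj(t(U)) %*% U - diag(2))), 1e-10)
  rho0 <- build_operator("-", sys_h)
  for (k in c(1, 10, 40)) {
    Uk <- res$steps[, , k]
    rho <- Uk %*% rho0 %*% Conj(t(Uk))
    expect_equal(Re(sum(Conj(rho) * rho)), Re(sum(Conj(rho0) * rho0)),
                 tolerance = 1e-10)
  }
})

test_that("ensemble signal reproduces the closed-form sinc limit", {
  ge <- gradient_event("half_sine", 1e-3, 1, 2.5e-5)
  # zero gradient
  spec0 <- ensemble_spec(n_voxels = 8, drift_max = 0)
  expect_equal(ensemble_signal(sys_h, "-", spec0, gradient = ge), 1)
  # 64-voxel linear gradient vs sin(k)/k
  spec <- ensemble_spec(n_voxels = 64, drift_max = 2.5e-5)
  sig <- ensemble_signal(sys_h, "-", spec, gradient = ge)
  k <- 2.675e8 * 2.5e-5 * (2e-3 / pi)
  expect_equal(sig, sin(k) / k, tolerance = 0.01)
  # error shrinks ~ 1/n^2
  spec16 <- ensemble_spec(n_voxels = 16, drift_max = 2.5e-5)
  e16 <- abs(ensemble_signal(sys_h, "-", spec16, gradient = ge) -
             sin(k) / k)
  e64 <- abs(sig - sin(k) / k)
  expect_lt(e64, e16 / 8)
  # two opposite-sign members: purely real mean by symmetry
  spec2 <- ensemble_spec(drift_amplitudes = c(-1e-5, 1e-5))
  m1 <- propagate(sys_h, "-", gradient = ge, drift_T = 1e-5)$final
  m2 <- propagate(sys_h, "-", gradient = ge, drift_T = -1e-5)$final
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_error(ensemble_signal(sys_h, "-", list(members = data.frame()),
                               gradient = ge), "empty")
})

test_that("cyclicity defect is 0 for identity, 1 for a hard pi pulse", {
  zp <- zero_pulse("1H", 50, 4e-6)
  expect_equal(cyclicity_defect(zp), 0)
  # constant x amplitude completing a pi rotation: Tr U = 0
  amp <- 1 / (2 * 50 * 4e-6)   # half rotation over the window
  pp <- control_pulse("1H", rep(amp, 50), rep(0, 50), 4e-6, amp * 1.01)
  expect_equal(cyclicity_defect(pp), 1, tolerance = 1e-9)
  # a full 2*pi rotation is cyclic again
  p2 <- control_pulse("1H", rep(2 * amp, 50), rep(0, 50), 4e-6,
                      2.1 * amp)
  expect_equal(cyclicity_defect(p2), 0, tolerance = 1e-9)
})

test_that("trajectories average members and export to CSV", {
  ge <- gradient_event("half_sine", 0.2e-3, 1, 2.5e-5)
  spec <- ensemble_spec(n_voxels = 6)
  tr <- locking_trajectory(sys_h, "-", gradient = ge, spec = spec,
                           slice_dt = 10e-6)
  expect_equal(tr$mean, rowMeans(tr$members))
  expect_equal(ncol(tr$members), 6)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_equal(df$mean, tr$mean, tolerance = 1e-12)
  expect_equal(ncol(df), 8)  # time + 6 members + mean
})

test_that("misaligned locking pulse and gradient is a validation error", {
  p <- zero_pulse("1H", 100, 4e-6)           # 0.4 ms pulse
  ge <- gradient_event("half_sine", 1e-3)    # 1 ms gradient
  expect_error(propagate(sys_h, "-", p, ge, drift_T = 1e-5),
               "time-aligned")
})
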