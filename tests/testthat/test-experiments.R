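test_that("pathway phases: selection ratios refocus, spillover does not", {
  # spin 1 = I = 1H (weight 4), spin 2 = S = 13C (weight 1)
  expect_equal(pathway_phase(pathway_spec(c("1+", "-1"), c(4, 1)),
                             sys_hc), 0)
  expect_equal(pathway_phase(pathway_spec(c("1-", "-1"), c(4, -1)),
                             sys_hc), 0)
  expect_equal(pathway_phase(pathway_spec(c("1+", "1+", "+1"),
                                          c(2, 2, -1)), sys_hc), 0)
  # an added 2:2:1 coupled train dephases the 2:2:-1 pathway
  s <- 0.3
  resid <- pathway_phase(pathway_spec(c("1+", "1+", "+1"), s * c(2, 2, 1)),
                         sys_hc)
  expect_equal(resid, 8 * s)
  # exact-gamma mode reports a small nonzero residual for 4:1
  ex <- pathway_phase(pathway_spec(c("1+", "-1"), c(4, 1)), sys_hc,
                      "exact")
  expect_gt(abs(ex), 0)
  expect_lt(abs(ex), 0.2)
  expect_error(pathway_spec(c("1+"), c(4, 1)), "ratios")
})

test_that("pgse attenuation matches scalar arithmetic and is monotone", {
  expect_equal(pgse_attenuation(0, 1e-3, 7e-3, 1.9e-9), 1)
  # frozen scalar oracle: paper constants, G = Gmax
  expect_equal(pgse_attenuation(1.0306, 1e-3, 7e-3, 1.9e-9),
               0.4204505, tolerance = 1e-6)
  g <- seq(0, 1, 0.1)
  a <- pgse_attenuation(g * 1.0306, 1e-3, 7e-3, 1.9e-9)
  expect_true(all(diff(a) < 0))
  expect_true(all(diff(pgse_attenuation(0.5, 1e-3, 7e-3,
                                        c(1, 2, 3) * 1e-9)) < 0))
  expect_error(pgse_attenuation(1, 2e-3, 1e-3, 1e-9), "Delta")
})

test_that("spillover signal matches the closed-form sinc oracle", {
  expect_equal(spillover_signal(0, 1.9e-3, 1.0306), 1)
  # frozen scalar oracle: k = 1.5321, ratio = 0.6522
  expect_equal(spillover_signal(1, 1.9e-3, 1.0306), 0.6522014,
               tolerance = 1e-6)
  # continuity at g -> 0+
  expect_equal(spillover_signal(1e-9, 1.9e-3, 1.0306), 1,
               tolerance = 1e-9)
})

test_that("synthetic pgse fit recovers Gmax; noiseless fit is exact", {
  p <- list(Gmax = 1.0306, delta = 1e-3, Delta = 7e-3, D = 1.9e-9)
  clean <- generate_calibration_fixture("pgse", p, noise_sigma = 0,
                                        seed = 1)
  f0 <- fit_pgse(clean, D = 1.9e-9)
  expect_equal(f0$estimate, 1.0306, tolerance = 1e-8)
  noisy <- generate_calibration_fixture("pgse", p, noise_sigma = 0.01,
                                        seed = 11)
  f1 <- fit_pgse(noisy, D = 1.9e-9)
  expect_lt(abs(f1$estimate - 1.0306) / 1.0306, 0.02)
  expect_true(f1$ci[1] < f1$ci[2])
  # fitting D instead with known Gmax
  f2 <- fit_pgse(clean, Gmax = 1.0306)
  expect_equal(f2$estimate, 1.9e-9, tolerance = 1e-8)
  expect_error(fit_pgse(clean), "exactly one")
  expect_error(fit_pgse(calibration_curve(rep(0.5, 5), rep(1, 5)),
                        D = 1e-9), "degenerate")
})

test_that("synthetic spillover fit recovers RG; noiseless fit is exact", {
  p <- list(RG = 1.9e-3, Gmax = 1.0306)
  clean <- generate_calibration_fixture("spillover", p, noise_sigma = 0,
                                        seed = 1)
  f0 <- fit_spillover(clean, Gmax = 1.0306)
  expect_equal(f0$estimate, 1.9e-3, tolerance = 1e-5)
  noisy <- generate_calibration_fixture("spillover", p,
                                        noise_sigma = 0.01, seed = 5)
  f1 <- fit_spillover(noisy, Gmax = 1.0306)
  expect_lt(abs(f1$estimate - 1.9e-3) / 1.9e-3, 0.05)
})

test_that("fixture generation is deterministic given the seed", {
  p <- list(RG = 1.9e-3, Gmax = 1.0306)
  a <- generate_calibration_fixture("spillover", p, 0.01, seed = 7)
  b <- generate_calibration_fixture("spillover", p, 0.01, seed = 7)
  expect_identical(a$intensity, b$intensity)
  c2 <- generate_calibration_fixture("spillover", p, 0.01, seed = 8)
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("calibration curve CSV round-trips", {
  p <- list(Gmax = 1.0306, delta = 1e-3, Delta = 7e-3, D = 1.9e-9)
  path <- tempfile(fileext = ".csv")
  cv <- generate_calibration_fixture("pgse", p, 0.01, seed = 3,
                                     path = path)
  back <- read_calibration_csv(path)
  expect_equal(back$g, cv$g)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-12)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(man$seed, 3)
  expect_equal(man$params$Gmax, 1.0306)
})

test_that("reference PGSE is a perfect echo; balanced coupling is inert", {
  spec <- ensemble_spec(n_voxels = 16)
  ref <- simulate_sequence(pgse_program(g = 0.1), sys_h, spec,
                           "reference")
  expect_equal(ref$relative, 1)
  # no-gradient simulation equals the refocused one (refocusing theorem)
  nog <- simulate_sequence(pgse_program(g = 0), sys_h, spec, "reference")
  expect_equal(ref$raw, nog$raw, tolerance = 1e-6)
  # balanced coupled pair refocuses itself: no loss even without locking
  bal <- simulate_sequence(pgse_program(g_c = 0.8, balanced = TRUE),
                           sys_h, spec, "coupled")
  expect_equal(bal$relative, 1, tolerance = 1e-9)
})

test_that("unbalanced coupled PGSE decays as the closed-form sinc", {
  spec <- ensemble_spec(n_voxels = 64)
  gam <- 2.675e8
  for (gc in c(0.3, 0.6, 0.95)) {
    sim <- simulate_sequence(pgse_program(g_c = gc), sys_h, spec,
                             "coupled")
    # net spillover moment: bipolar pair hits I+ then I- with opposite
    # sign -> effective edge phase doubled
    k_edge <- gam * 2.5e-5 * (2e-3 / pi)
    x <- 2 * k_edge * gc
    expect_equal(sim$relative, sin(x) / x, tolerance = 0.01, info = gc)
  }
})

test_that("hsqc reference sequences transfer and refocus exactly", {
  spec <- ensemble_spec(n_voxels = 32)
  for (ratio in list(c(4, 1), c(2, 2, -1))) {
    prog <- hsqc_program(sys_hc, ratio)
    ref <- simulate_sequence(prog, sys_hc, spec, "reference")
    nog <- simulate_sequence(hsqc_program(sys_hc, ratio * 0), sys_hc,
                             spec, "reference")
    # gradient-selected signal is half of the ungated transfer
    # (echo/antiecho split) and refocuses exactly
    expect_equal(abs(ref$raw / nog$raw), 0.5, tolerance = 1e-6)
    expect_gt(abs(ref$raw), 0.1)
  }
})
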