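# Sequence-level simulators and calibration fits: coherence-pathway
# bookkeeping, PGSE diffusion attenuation, sinc spillover, and
# gradient-selected HSQC/HMQC with optional locking blocks.

# ---------------------------------------------------------------------------
# coherence pathway bookkeeping

#' Specify a coherence transfer pathway against a gradient train
#'
#' @param labels character vector: the coherence label present during each
#'   gradient pulse (e.g. `c("1+", "-1")` for the S+ -> I- pathway of a
#'   two-spin 1H-13C system, spin 1 = I = 1H).
#' @param ratios signed relative gradient amplitudes, one per gradient.
#' @export
pathway_spec <- function(labels, ratios) {
  if (length(labels) != length(ratios))
    stop("pathway has ", length(labels), " coherences but ",
         length(ratios), " gradient ratios")
  structure(list(labels = labels, ratios = ratios), class = "pathway_spec")
}

# per-spin gradient weights: gamma ratio relative to the smallest |gamma|
.gamma_ratios <- function(system, gamma_convention) {
  r <- system$gamma / min(abs(system$gamma))
  if (gamma_convention == "nominal4") r <- round(r)
  r
}

#' Net gradient phase of a coherence pathway
#'
#' A pathway is refocused only if the net effect of all gradient pulses is
#' zero: returns \eqn{\sum_i (\sum_s p_s \gamma_s) G_i} in units of the
#' smallest gyromagnetic ratio times the unit gradient moment.  The
#' `nominal4` convention rounds gamma ratios (so 1H/13C = 4 exactly, the
#' assumption behind 4:1 and 2:2:-1 gradient ratios); `exact` reports the
#' small residual instead.
#'
#' @param pathway a [pathway_spec()].
#' @param system a [spin_system()].
#' @param gamma_convention `"nominal4"` or `"exact"`.
#' @return dimensionless net phase factor; 0 means refocused.
#' @export
pathway_phase <- function(pathway, system,
                          gamma_convention = c("nominal4", "exact")) {
  gamma_convention <- match.arg(gamma_convention)
  r <- .gamma_ratios(system, gamma_convention)
  contrib <- vapply(seq_along(pathway$labels), function(i) {
    p <- coherence_orders(pathway$labels[i])
    sum(p * r) * pathway$ratios[i]
  }, 0)
  sum(contrib)
}

# ---------------------------------------------------------------------------
# closed-form calibration models

#' PGSE diffusion attenuation (Stejskal-Tanner form)
#'
#' \eqn{I_g/I_0 = \exp[-\gamma^2\delta^2 G^2(\Delta-\delta) D]}.
#'
#' @param G gradient amplitude, T/m.
#' @param delta gradient pulse length, s.
#' @param Delta interval between the two gradient pulses, s (> delta).
#' @param D diffusion constant, m^2/s.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @export
pgse_attenuation <- function(G, delta, Delta, D, gamma = GAMMA_1H) {
  stopifnot(delta > 0, Delta > delta, D > 0)
  exp(-(gamma^2 * delta^2 * G^2 * (Delta - delta)) * D)
}

#' Sinc spillover attenuation of a pulse-acquire signal
#'
#' A linear stray field across the detection zone dephases the signal as
#' \eqn{I_g/I_0 = \sin(kg)/(kg)} with
#' \eqn{k = (l/2)\,\gamma\,R_G G_{max} \int g(t)dt}, continuously extended
#' to 1 at g = 0.
#'
#' @param g coupling-gradient amplitude as a fraction of maximum.
#' @param RG gradient spillover ratio (dimensionless).
#' @param Gmax maximum gradient, T/m.
#' @param l detection-zone length, m.
#' @param g_integral time integral of the gradient shape, s.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @export
spillover_signal <- function(g, RG, Gmax, l = 6.5e-3, g_integral = 0.9e-3,
                             gamma = GAMMA_1H) {
  k <- (l / 2) * gamma * RG * Gmax * g_integral
  x <- k * g
  ifelse(abs(x) < 1e-12, 1, sin(x) / x)
}

#' Calibration curve container
#'
#' Pairs of (gradient amplitude, signal intensity).  Amplitudes given in
#' percent are normalized to fractions.
#'
#' @param g gradient amplitudes (fraction of maximum, or percent).
#' @param intensity signal intensities (arbitrary units).
#' @param sigma relative noise level used to generate the curve, if known.
#' @export
calibration_curve <- function(g, intensity, sigma = NA_real_) {
  stopifnot(length(g) == length(intensity), all(is.finite(intensity)))
  if (max(g) > 1.5) g <- g / 100
  if (any(g < 0 | g > 1)) stop("g must lie in [0, 1] after normalization")
  structure(list(g = as.numeric(g), intensity = as.numeric(intensity),
                 sigma = sigma),
            class = "calibration_curve")
}

#' Read / write calibration curves as two-column CSV
#' @param path file path.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  calibration_curve(df[[1]], df[[2]])
}

#' @rdname read_calibration_csv
#' @param curve a [calibration_curve()].
#' @export
write_calibration_csv <- function(curve, path) {
  write.csv(data.frame(g = curve$g, intensity = curve$intensity), path,
            row.names = FALSE)
  invisible(path)
}

# residual-resampling bootstrap CI for a scalar estimator
.boot_ci <- function(fitted, resid, refit, n_boot, seed, level = 0.95) {
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(b) {
    y <- fitted + sample(resid, length(resid), replace = TRUE)
    refit(y)
  }, 0)
  est <- est[is.finite(est)]
  quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' Fit the PGSE attenuation curve for Gmax or D
#'
#' Least-squares fit of the diffusion attenuation model with
#' `G = g * Gmax` on the log scale (multiplicative noise is homoscedastic
#' there): `log I = log s - c g^2`, from which the single unknown among
#' `Gmax` and `D` follows.  A residual-resampling bootstrap provides the
#' confidence interval.
#'
#' @param curve a [calibration_curve()] of (g, intensity).
#' @param delta,Delta,gamma known sequence constants (see
#'   [pgse_attenuation()]).
#' @param D,Gmax exactly one must be NULL (the parameter to fit); the
#'   other is the known value (D in m^2/s, Gmax in T/m).
#' @param n_boot bootstrap replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return list with `estimate`, `ci` (95 \%), `parameter` name, `c`
#'   (fitted decay coefficient).
#' @export
fit_pgse <- function(curve, delta = 1e-3, Delta = 7e-3, gamma = GAMMA_1H,
                     D = NULL, Gmax = NULL, n_boot = 199, seed = 1) {
  if (length(curve$g) < 4) stop("need at least 4 points")
  if (sd(curve$g) == 0) stop("degenerate curve: all g equal")
  if (is.null(D) == is.null(Gmax))
    stop("exactly one of D, Gmax must be NULL (the unknown)")
  if (any(curve$intensity <= 0))
    stop("non-positive intensities cannot be fit on the log scale")
  x <- curve$g^2
  ly <- log(curve$intensity)
  solve_c <- function(ly) {
    fit <- stats::lm.fit(cbind(1, -x), ly)
    max(fit$coefficients[2], 0)
  }
  cc <- solve_c(ly)
  to_param <- function(cc) {
    if (is.null(Gmax)) sqrt(cc / (gamma^2 * delta^2 * (Delta - delta) * D))
    else cc / (gamma^2 * delta^2 * (Delta - delta) * Gmax^2)
  }
  fit0 <- stats::lm.fit(cbind(1, -x), ly)
  ci <- .boot_ci(cbind(1, -x) %*% fit0$coefficients, fit0$residuals,
                 function(y) to_param(solve_c(y)), n_boot, seed)
  list(estimate = to_param(cc), ci = ci,
       parameter = if (is.null(Gmax)) "Gmax" else "D", c = cc)
}

#' Fit the sinc spillover curve for the spillover ratio RG
#'
#' Nonlinear least squares of `I = s * sinc(k g)` on the linear scale,
#' with a grid-initialized `k`; `RG = k / ((l/2) gamma Gmax g_integral)`.
#'
#' @inheritParams fit_pgse
#' @param Gmax maximum gradient, T/m (known).
#' @param l,g_integral,gamma model constants (see [spillover_signal()]).
#' @return list with `estimate` (RG), `ci`, `k`.
#' @export
fit_spillover <- function(curve, Gmax, l = 6.5e-3, g_integral = 0.9e-3,
                          gamma = GAMMA_1H, n_boot = 199, seed = 1) {
  if (length(curve$g) < 4) stop("need at least 4 points")
  if (sd(curve$g) == 0) stop("degenerate curve: all g equal")
  g <- curve$g; y <- curve$intensity
  msinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  sse <- function(k, y) {
    f <- msinc(k * g)
    s <- sum(f * y) / sum(f * f)
    sum((y - s * f)^2)
  }
  solve_k <- function(y) {
    ks <- seq(0.05, pi / max(g), length.out = 200)
    k0 <- ks[which.min(vapply(ks, sse, 0, y = y))]
    stats::optimize(sse, c(max(k0 - 0.2, 1e-3), k0 + 0.2), y = y)$minimum
  }
  k <- solve_k(y)
  fhat <- msinc(k * g)
  s <- sum(fhat * y) / sum(fhat * fhat)
  denom <- (l / 2) * gamma * Gmax * g_integral
  ci <- .boot_ci(s * fhat, y - s * fhat, function(yy) solve_k(yy) / denom,
                 n_boot, seed)
  list(estimate = k / denom, ci = ci, k = k)
}

# ---------------------------------------------------------------------------
# sequence programs

ev_pulse <- function(channel, angle_deg, phase_deg = 0) {
  list(type = "pulse", channel = channel, angle = angle_deg * pi / 180,
       phase = phase_deg * pi / 180)
}

ev_delay <- function(duration) list(type = "delay", duration = duration)

# role "primary": ideal pathway-selection gradient; phase across the zone =
#   2*pi*cycles*amplitude per unit gamma ratio (integer `cycles` makes the
#   discrete voxel average of dephased pathways exactly zero).
# role "coupled": spillover gradient characterized by drift_scale (Tesla of
#   peak B0 drift at the zone edge per unit amplitude); may carry locking
#   pulses time-aligned with it.
ev_grad <- function(role, amplitude, cycles = 1, drift_scale = 2.5e-5,
                    duration = 1e-3, shape = "half_sine", cloc = NULL) {
  list(type = "grad", role = role, amplitude = amplitude, cycles = cycles,
       drift_scale = drift_scale,
       event = gradient_event(shape, duration = duration,
                              drift_scale = drift_scale),
       cloc = cloc)
}

#' Assemble a sequence program
#'
#' An ordered list of hard pulses (ideal rotations), delays (offset + weak
#' J evolution), primary pathway-selection gradients and coupled
#' (spillover) gradients with optional time-aligned locking pulses.
#' Gradient windows are treated as embedded in refocused echoes: neither J
#' nor offsets evolve inside them, and locking windows are excluded from
#' the J-evolution delay bookkeeping.
#'
#' @param events list of events built by the sequence builders.
#' @param initial initial coherence label (e.g. `"z1"`).
#' @param acquire acquisition target coherence label (e.g. `"-1"`).
#' @export
sequence_program <- function(events, initial, acquire) {
  structure(list(events = events, initial = initial, acquire = acquire),
            class = "sequence_program")
}

#' PGSE sequence with an unbalanced coupled-gradient pair
#'
#' 90 - G - GC1 - 180 - GC2 - G - acquire, a spin echo whose primary
#' gradients G balance while the coupled pair GC (spillover from a
#' neighboring detector, swept in amplitude) does not: with the default
#' bipolar coupled pair the echo pathway (I+ before the inversion pulse,
#' I- after) accumulates net spillover phase and decays as a sinc.
#' Locking pulses aligned with each GC block protect I+ during the first
#' spillover period and I- during the second.
#'
#' @param g primary gradient amplitude (fraction), fixed at 10 \% by
#'   default.
#' @param g_c coupled-gradient amplitude (fraction of its maximum).
#' @param cycles primary-gradient dephasing cycles across the zone per
#'   unit amplitude.
#' @param drift_scale peak coupled B0 drift (T) at the zone edge for
#'   g_c = 1.
#' @param balanced if TRUE the coupled pair has equal polarity and
#'   refocuses itself (no net spillover).
#' @param cloc a 1H [control_pulse()] to align with both coupled blocks,
#'   or NULL.
#' @param duration gradient pulse length, s.
#' @export
pgse_program <- function(g = 0.1, g_c = 0, cycles = 10,
                         drift_scale = 2.5e-5, balanced = FALSE,
                         cloc = NULL, duration = 1e-3) {
  sgn2 <- if (balanced) 1 else -1
  cl <- if (is.null(cloc)) NULL else list("1H" = cloc)
  sequence_program(list(
    ev_pulse("1H", 90, 90),
    ev_grad("primary", g, cycles = cycles, duration = duration),
    ev_grad("coupled", g_c, drift_scale = drift_scale,
            duration = duration, cloc = cl),
    ev_pulse("1H", 180, 0),
    ev_grad("coupled", sgn2 * g_c, drift_scale = drift_scale,
            duration = duration, cloc = cl),
    ev_grad("primary", g, cycles = cycles, duration = duration)
  ), initial = "z", acquire = "-")
}

#' Gradient-selected HSQC program with coupled gradients
#'
#' Two variants on a 1H-13C pair (spin 1 = I = 1H, spin 2 = S = 13C),
#' distinguished by the primary gradient ratio:
#' a two-gradient `4:1` (or `4:-1`) sequence selecting S+ -> I-
#' (S- -> I-), and a three-gradient `2:2:-1` sequence selecting
#' S+ -> S+ -> I+ -> I-.  Coupled gradients (one per primary gradient,
#' shifted by one gradient length) model spillover from a parallel
#' detector running its own ratio; locking pulses ride on the coupled
#' blocks: 13C pulses while S coherence is transverse, a 1H pulse during
#' the last block.  All INEPT delays use Delta = 1/(4J).
#'
#' @param system a two-spin [spin_system()] with nonzero J.
#' @param ratio primary gradient ratio, length 2 or 3.
#' @param coupled_ratio coupled gradient ratio (same length), or NULL for
#'   no spillover.
#' @param cycles dephasing cycles per unit primary amplitude.
#' @param drift_scale peak coupled B0 drift (T) at the zone edge per unit
#'   coupled amplitude.
#' @param cloc named list of locking pulses (`"1H"`, `"13C"`), or NULL.
#' @param duration gradient length, s.
#' @export
hsqc_program <- function(system, ratio = c(4, 1), coupled_ratio = NULL,
                         cycles = 1, drift_scale = 2.5e-5 / 4,
                         cloc = NULL, duration = 1e-3) {
  J <- system$j_hz[1, 2]
  if (J == 0) stop("HSQC requires a coupled two-spin system")
  tau_j <- 1 / (2 * J)                      # 2 * Delta with Delta = 1/(4J)
  stopifnot(length(ratio) %in% c(2L, 3L))
  if (!is.null(coupled_ratio) && length(coupled_ratio) != length(ratio))
    stop("coupled_ratio must match the primary gradient count")
  cl_ch <- if (length(ratio) == 2L) c("13C", "1H") else
    c("13C", "13C", "1H")
  gc_ev <- function(i) {
    if (is.null(coupled_ratio)) return(NULL)
    pl <- if (!is.null(cloc) && cl_ch[i] %in% names(cloc))
      cloc[cl_ch[i]] else NULL
    ev_grad("coupled", coupled_ratio[i], drift_scale = drift_scale,
            duration = duration, cloc = pl)
  }
  ev <- list(
    ev_pulse("1H", 90, 0),           # Iz -> -Iy
    ev_delay(tau_j),                 # -> 2IxSz
    ev_pulse("1H", 90, 90),
    ev_pulse("13C", 90, 0)           # -> antiphase S coherence
  )
  add <- function(ev, x) if (is.null(x)) ev else c(ev, list(x))
  if (length(ratio) == 2L) {
    ev <- add(c(ev, list(ev_grad("primary", ratio[1], cycles = cycles,
                                 duration = duration))), gc_ev(1))
    ev <- c(ev, list(ev_pulse("13C", 90, 0), ev_pulse("1H", 90, 0),
                     ev_delay(tau_j)))
    ev <- add(c(ev, list(ev_grad("primary", ratio[2], cycles = cycles,
                                 duration = duration))), gc_ev(2))
  } else {
    ev <- add(c(ev, list(ev_grad("primary", ratio[1], cycles = cycles,
                                 duration = duration))), gc_ev(1))
    ev <- add(c(ev, list(ev_grad("primary", ratio[2], cycles = cycles,
                                 duration = duration))), gc_ev(2))
    ev <- c(ev, list(ev_pulse("13C", 90, 0), ev_pulse("1H", 90, 0),
                     ev_delay(tau_j / 2)))
    ev <- add(c(ev, list(ev_grad("primary", ratio[3], cycles = cycles,
                                 duration = duration))), gc_ev(3))
    ev <- c(ev, list(ev_pulse("1H", 180, 0), ev_pulse("13C", 180, 0),
                     ev_delay(tau_j / 2)))
  }
  sequence_program(ev, initial = "z1", acquire = "-1")
}

#' HMQC program with double-quantum locking (simulation only)
#'
#' 1H90 - 1/(2J) - 13C90 - g1 - 1H180 - 13C90 - 1/(2J) - g2 - acquire
#' I-.  The first gradient falls in the multiple-quantum period; the
#' proton 180 in its middle converts I+S+ into the detectable branch, so
#' the `4:5` gradient ratio refocuses exactly the double-quantum pathway
#' (5*4 - 4*5 = 0 under the nominal gamma ratio) and dephases the
#' zero-quantum one (3*4 - 4*5 = -8).  Protecting the double quantum
#' during a coupled gradient requires locking pulses on both channels
#' simultaneously.
#'
#' @inheritParams hsqc_program
#' @param ratio primary gradient pair, default `c(4, 5)`.
#' @export
hmqc_program <- function(system, ratio = c(4, 5), coupled_ratio = NULL,
                         cycles = 1, drift_scale = 2.5e-5 / 4,
                         cloc = NULL, duration = 1e-3) {
  J <- system$j_hz[1, 2]
  if (J == 0) stop("HMQC requires a coupled two-spin system")
  tau_j <- 1 / (2 * J)
  gc_ev <- function(i, channels) {
    if (is.null(coupled_ratio)) return(NULL)
    pl <- if (!is.null(cloc)) cloc[intersect(channels, names(cloc))] else
      NULL
    if (length(pl) == 0L) pl <- NULL
    ev_grad("coupled", coupled_ratio[i], drift_scale = drift_scale,
            duration = duration, cloc = pl)
  }
  ev <- list(ev_pulse("1H", 90, 0), ev_delay(tau_j),
             ev_pulse("13C", 90, 0))
  add <- function(ev, x) if (is.null(x)) ev else c(ev, list(x))
  ev <- add(c(ev, list(ev_grad("primary", ratio[1], cycles = cycles,
                               duration = duration))),
            gc_ev(1, c("1H", "13C")))
  ev <- c(ev, list(ev_pulse("1H", 180, 0), ev_pulse("13C", 90, 0),
                   ev_delay(tau_j)))
  ev <- add(c(ev, list(ev_grad("primary", ratio[2], cycles = cycles,
                               duration = duration))), gc_ev(2, "1H"))
  sequence_program(ev, initial = "z1", acquire = "-1")
}

# ---------------------------------------------------------------------------
# sequence simulation

#' Simulate a sequence over a voxel ensemble
#'
#' Propagates the initial coherence through the program for every voxel,
#' averages the acquired-coherence overlap, and normalizes to the
#' `reference` scenario (primary gradients only).  Scenarios: `reference`
#' drops the coupled gradients, `coupled` keeps them but strips the
#' locking pulses, `coupled_with_cloc` keeps both.
#'
#' @param program a [sequence_program()].
#' @param system the [spin_system()].
#' @param spec an [ensemble_spec()] in voxel mode (64 voxels by default so
#'   that dephased integer-cycle pathways cancel exactly).
#' @param scenario one of `"reference"`, `"coupled"`,
#'   `"coupled_with_cloc"`.
#' @param gamma_convention gamma-ratio convention for the primary
#'   gradients (see [pathway_phase()]).
#' @return list with `relative` (signal normalized to reference), `raw`,
#'   `reference`.
#' @export
simulate_sequence <- function(program, system,
                              spec = ensemble_spec(n_voxels = 64),
                              scenario = c("reference", "coupled",
                                           "coupled_with_cloc"),
                              gamma_convention = c("nominal4", "exact")) {
  scenario <- match.arg(scenario)
  gamma_convention <- match.arg(gamma_convention)
  raw <- .run_scenario(program, system, spec, scenario, gamma_convention)
  ref <- if (scenario == "reference") raw else
    .run_scenario(program, system, spec, "reference", gamma_convention)
  # raw amplitudes are complex; dividing by the reference cancels the
  # arbitrary receiver phase of the selected pathway
  list(relative = Re(raw / ref), raw = raw, reference = ref)
}

.run_scenario <- function(program, system, spec, scenario,
                          gamma_convention) {
  n <- n_spins(system)
  d <- 2^n
  gr <- .gamma_ratios(system, gamma_convention)
  mz <- lapply(seq_len(n), function(k) Re(diag(.iz_spin(system, k))))
  rho0 <- build_operator(program$initial, system)
  Tm <- build_operator(program$acquire, system)
  # gradient-window system: no offsets, no J (refocused-echo convention)
  sysg <- system
  sysg$offset_hz[] <- 0
  sysg$j_hz[] <- 0

  # member-independent propagators
  Hfree <- offset_hamiltonian(system) +
    (if (n == 2L && system$j_hz[1, 2] != 0) j_coupling(system, "weak") else 0)
  prep <- lapply(program$events, function(e) {
    if (e$type == "pulse") {
      H1 <- rf_hamiltonian(system, e$channel, 1 / (2 * pi), e$phase)
      list(U = expm_herm(H1, e$angle))
    } else if (e$type == "delay") {
      list(U = expm_herm(Hfree, e$duration))
    } else NULL
  })

  mem <- spec$members
  sig <- 0
  for (i in seq_len(nrow(mem))) {
    z <- mem$z_frac[i]
    if (is.na(z)) stop("simulate_sequence needs a voxel-mode ensemble")
    rho <- rho0
    for (j in seq_along(program$events)) {
      e <- program$events[[j]]
      if (e$type %in% c("pulse", "delay")) {
        U <- prep[[j]]$U
      } else if (e$role == "primary") {
        ph <- 2 * pi * e$cycles * e$amplitude * z
        dphase <- Reduce(`+`, lapply(seq_len(n),
                                     function(k) ph * gr[k] * mz[[k]]))
        U <- diag(exp(-1i * dphase), d, d)
      } else {                                   # coupled gradient
        if (scenario == "reference") next
        drift <- e$drift_scale * 2 * z           # peak drift at this voxel
        use_cloc <- scenario == "coupled_with_cloc" && !is.null(e$cloc)
        if (use_cloc) {
          res <- window_propagate(sysg, e$cloc, e$event,
                                  drift_T = drift * e$amplitude,
                                  b1_scale = mem$b1_scale[i],
                                  offset_hz = mem$offset_hz[i],
                                  include_j = FALSE)
          U <- res$U
        } else {
          ph <- drift * e$amplitude * shape_integral(e$event)
          dphase <- Reduce(`+`, lapply(seq_len(n), function(k)
            system$gamma[k] * ph * mz[[k]]))
          U <- diag(exp(-1i * dphase), d, d)
        }
      }
      rho <- U %*% rho %*% Conj(t(U))
    }
    # complex acquired amplitude <T|rho> (receiver phase handled by the
    # reference normalization)
    sig <- sig + sum(Conj(Tm) * rho) / Re(sum(Conj(Tm) * Tm))
  }
  sig / nrow(mem)
}

# ---------------------------------------------------------------------------
# robustness sweeps

#' Robustness sweep of a locking pulse
#'
#' Evaluates the cyclic fidelity (and, where defined, the heteronuclear
#' scale factor chi) along one robustness axis with the other factors at
#' their nominal values.
#'
#' @param pulse a [control_pulse()].
#' @param axis `"bandwidth"` (resonance offset, Hz), `"b1"` (B1 scale) or
#'   `"drift_amplitude"` (half-sine peak drift, Tesla).
#' @param values grid of axis values.
#' @param drift_T nominal drift amplitude used for the off-axis factors.
#' @return data frame (value, fidelity, chi); chi is NA on the drift axis
#'   (the toggling frame depends only on RF and offset).
#' @export
robustness_sweep <- function(pulse, axis = c("bandwidth", "b1",
                                             "drift_amplitude"),
                             values, drift_T = 2.5e-5) {
  axis <- match.arg(axis)
  fid1 <- function(drift, b1, off) {
    spec <- optimization_spec(channel = pulse$channel, target = "cyclic",
                              ensemble = ensemble_spec(
                                drift_amplitudes = drift, b1_scales = b1,
                                offsets_hz = off),
                              nominal_amp_hz = pulse$nominal_amp_hz,
                              duration = pulse$duration,
                              n_slices = pulse$n_slices)
    cloc_fidelity(pulse, spec)$fidelity
  }
  out <- lapply(values, function(v) {
    if (axis == "bandwidth") {
      data.frame(value = v, fidelity = fid1(drift_T, 1, v),
                 chi = toggling_tensor(pulse, offset_hz = v)$chi)
    } else if (axis == "b1") {
      data.frame(value = v, fidelity = fid1(drift_T, v, 0),
                 chi = toggling_tensor(pulse, b1_scale = v)$chi)
    } else {
      data.frame(value = v, fidelity = fid1(v, 1, 0), chi = NA_real_)
    }
  })
  do.call(rbind, out)
}
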