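# Piecewise-constant unitary propagation of states through RF + drift
# windows, and ensemble averaging over voxels / field distortions.
# Time-dependent drift within a slice is evaluated at the slice midpoint.

#' Define a robustness / voxel ensemble
#'
#' Two uses share this container.  In *voxel* mode (default,
#' `drift_amplitudes = NULL`) the detection zone of length `length_m` is
#' segmented into `n_voxels` voxels along z; a linear gradient assigns each
#' voxel center a peak B0 drift `drift_max * 2 * z_frac`, spanning
#' +/- `drift_max` across the zone (12 voxels and 0.25 Gauss by default).
#' In *grid* mode an explicit list of drift amplitudes is crossed with the
#' B1 scales and offsets, which is how optimization design grids are
#' specified.
#'
#' @param n_voxels number of voxel centers (voxel mode).
#' @param drift_max peak B0 drift in Tesla at the zone edge (default
#'   2.5e-5 T = 0.25 Gauss).
#' @param drift_amplitudes optional explicit drift amplitudes (Tesla);
#'   switches to grid mode.
#' @param b1_scales vector of B1 multipliers.
#' @param offsets_hz vector of resonance offsets (Hz).
#' @param length_m detection-zone length (m), default 6.5 mm.
#' @return object of class `ensemble_spec` with a `members` data frame
#'   (columns `drift_T`, `b1_scale`, `offset_hz`, `z_frac`).
#' @export
ensemble_spec <- function(n_voxels = 12, drift_max = 2.5e-5,
                          drift_amplitudes = NULL, b1_scales = 1,
                          offsets_hz = 0, length_m = 6.5e-3) {
  if (is.null(drift_amplitudes)) {
    stopifnot(n_voxels >= 1)
    z <- (seq_len(n_voxels) - 0.5) / n_voxels - 0.5
    base <- data.frame(drift_T = drift_max * 2 * z, z_frac = z)
  } else {
    base <- data.frame(drift_T = drift_amplitudes, z_frac = NA_real_)
  }
  grid <- expand.grid(i = seq_len(nrow(base)), b1_scale = b1_scales,
                      offset_hz = offsets_hz)
  members <- data.frame(drift_T = base$drift_T[grid$i],
                        b1_scale = grid$b1_scale,
                        offset_hz = grid$offset_hz,
                        z_frac = base$z_frac[grid$i])
  structure(list(members = members, drift_max = drift_max,
                 length_m = length_m),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec> ", nrow(x$members), " members; drift span +/-",
      format(x$drift_max * 1e4), " G\n", sep = "")
  invisible(x)
}

# Build operator stack + coefficient matrix for one locking window and call
# the compiled propagator.  `pulses` is a named list channel -> control
# pulse (possibly empty); `gradient` a gradient_event or NULL; `drift_T`
# the signed peak drift (Tesla) this member sees (voxel scaling already
# applied); offsets/b1 from `member` (a field_distortion or a row of an
# ensemble members frame).
window_propagate <- function(system, pulses = list(), gradient = NULL,
                             drift_T = 0, b1_scale = 1, offset_hz = 0,
                             duration = NULL, slice_dt = 4e-6,
                             include_j = TRUE,
                             keep_steps = FALSE, keep_mids = FALSE) {
  pulses <- if (inherits(pulses, "control_pulse")) list(pulses) else pulses
  if (length(pulses)) {
    ns <- vapply(pulses, function(p) p$n_slices, 0)
    dts <- vapply(pulses, function(p) p$slice_dt, 0)
    if (length(unique(ns)) != 1L || length(unique(dts)) != 1L)
      stop("all pulses in one window must share the time grid")
    n_slices <- ns[1]; dt <- dts[1]
    duration <- n_slices * dt
    if (!is.null(gradient) &&
        abs(gradient$duration - duration) > 1e-12)
      stop("shaped pulse is not time-aligned with its gradient")
  } else {
    if (is.null(duration)) {
      if (is.null(gradient)) stop("need a pulse, gradient or duration")
      duration <- gradient$duration
    }
    n_slices <- max(1L, as.integer(ceiling(duration / slice_dt - 1e-9)))
    dt <- duration / n_slices
  }
  n <- n_spins(system)
  d <- 2^n
  t_mid <- (seq_len(n_slices) - 0.5) * dt

  ops <- list()
  coef <- NULL
  # static part: offsets (+ member offset on every spin) and weak J
  Hstat <- offset_hamiltonian(system, offset_hz)
  if (include_j && n == 2L && system$j_hz[1, 2] != 0)
    Hstat <- Hstat + j_coupling(system, "weak")
  ops[[1]] <- Hstat
  coef <- cbind(rep(1, n_slices))
  # gradient drift per spin
  if (!is.null(gradient) && drift_T != 0) {
    prof <- drift_T * gradient$relative_amplitude *
      shape_value(gradient, t_mid)
    for (k in seq_len(n)) {
      ops[[length(ops) + 1L]] <- .iz_spin(system, k)
      coef <- cbind(coef, system$gamma[k] * prof)
    }
  }
  # RF controls
  for (p in pulses) {
    k <- match(p$channel, system$labels)
    if (is.na(k)) stop("pulse channel '", p$channel, "' not in system")
    labx <- rep("1", n); labx[k] <- "x"
    laby <- rep("1", n); laby[k] <- "y"
    ops[[length(ops) + 1L]] <- build_operator(paste(labx, collapse = ""),
                                              system)
    coef <- cbind(coef, 2 * pi * b1_scale * p$x_hz)
    ops[[length(ops) + 1L]] <- build_operator(paste(laby, collapse = ""),
                                              system)
    coef <- cbind(coef, 2 * pi * b1_scale * p$y_hz)
  }
  cube <- array(0i, dim = c(d, d, length(ops)))
  for (j in seq_along(ops)) cube[, , j] <- ops[[j]]
  res <- cpp_slice_propagate(cube, coef, dt, diag(d) + 0i,
                             keep_steps, keep_mids)
  res$time <- seq_len(n_slices) * dt
  res$dt <- dt
  res
}

#' Propagate a coherence through a locking window (one ensemble member)
#'
#' Evolves an initial coherence under shaped RF pulse(s) applied
#' simultaneously with a time-dependent gradient drift, by exact matrix
#' exponentials on a piecewise-constant grid (slice width 4 us by default),
#' and returns the overlap trajectory against a target coherence.
#'
#' @param system a [spin_system()].
#' @param initial,target coherence labels (target defaults to initial).
#' @param pulses a [control_pulse()] or named list of them (may be empty).
#' @param gradient a [gradient_event()] or NULL.
#' @param member a [field_distortion()] describing this member.
#' @param drift_T signed peak B0 drift (Tesla) seen by this member; when
#'   NULL, taken from `member$b0_drift`.
#' @param slice_dt slice width in seconds when no shaped pulse sets the
#'   grid.
#' @param include_j include the weak J coupling of a two-spin system.
#' @return list with `time`, `overlap` (real series) and `final`.
#' @export
propagate <- function(system, initial, pulses = list(), gradient = NULL,
                      member = field_distortion(), target = initial,
                      drift_T = NULL, slice_dt = 4e-6, include_j = TRUE) {
  if (is.null(drift_T)) drift_T <- member$b0_drift
  res <- window_propagate(system, pulses, gradient, drift_T,
                          member$b1_scale, member$offset_hz,
                          slice_dt = slice_dt, include_j = include_j,
                          keep_steps = TRUE)
  rho0 <- build_operator(initial, system)
  Tm <- build_operator(target, system)
  nt <- length(res$time)
  ov <- numeric(nt)
  for (k in seq_len(nt)) {
    U <- res$steps[, , k]
    ov[k] <- overlap(U %*% rho0 %*% Conj(t(U)), Tm)
  }
  list(time = res$time, overlap = ov, final = ov[nt], U = res$U)
}

#' Ensemble locking trajectory
#'
#' Runs [propagate()] for every ensemble member and collects the per-member
#' overlap series and their arithmetic mean, the quantity a detected signal
#' measures when voxel magnetizations sum.
#'
#' @inheritParams propagate
#' @param spec an [ensemble_spec()].
#' @return object of class `cloc_trajectory` with fields `time`, `members`
#'   (matrix time x member), `mean`.
#' @export
locking_trajectory <- function(system, initial, pulses = list(),
                               gradient = NULL, spec = ensemble_spec(),
                               target = initial, slice_dt = 4e-6,
                               include_j = TRUE) {
  mem <- spec$members
  out <- NULL
  tgrid <- NULL
  for (i in seq_len(nrow(mem))) {
    tr <- propagate(system, initial, pulses, gradient,
                    field_distortion(0, mem$b1_scale[i], mem$offset_hz[i]),
                    target = target, drift_T = mem$drift_T[i],
                    slice_dt = slice_dt, include_j = include_j)
    if (is.null(out)) {
      out <- matrix(0, length(tr$time), nrow(mem))
      tgrid <- tr$time
    }
    out[, i] <- tr$overlap
  }
  structure(list(time = tgrid, members = out, mean = rowMeans(out)),
            class = "cloc_trajectory")
}

#' @export
print.cloc_trajectory <- function(x, ...) {
  cat("<cloc_trajectory> ", ncol(x$members), " members, ",
      length(x$time), " time points; final mean overlap ",
      format(signif(x$mean[length(x$mean)], 4)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cloc_trajectory <- function(x, ...) {
  df <- data.frame(time = x$time)
  for (i in seq_len(ncol(x$members)))
    df[[paste0("member_", i)]] <- x$members[, i]
  df$mean <- x$mean
  df
}

#' Write a trajectory as CSV (time, member overlaps, mean)
#' @param x a `cloc_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Ensemble-averaged final overlap
#'
#' Mean final overlap of the initial coherence with a target over all
#' ensemble members.  For a linear gradient over voxels with no RF this
#' converges to the closed-form sinc dephasing as the voxel count grows.
#'
#' @inheritParams locking_trajectory
#' @export
ensemble_signal <- function(system, initial, spec, pulses = list(),
                            gradient = NULL, target = initial,
                            slice_dt = 4e-6, include_j = TRUE) {
  mem <- spec$members
  if (!nrow(mem)) stop("empty ensemble")
  finals <- vapply(seq_len(nrow(mem)), function(i) {
    propagate(system, initial, pulses, gradient,
              field_distortion(0, mem$b1_scale[i], mem$offset_hz[i]),
              target = target, drift_T = mem$drift_T[i],
              slice_dt = slice_dt, include_j = include_j)$final
  }, 0)
  mean(finals)
}

#' Cyclicity defect of a pulse window
#'
#' `1 - |Tr(U)| / 2^n` for the net propagator over the pulse window; zero
#' exactly when U is the identity up to a global phase, the cyclic-
#' propagation design target.
#'
#' @param pulse a [control_pulse()] (or empty list for drift only).
#' @param member a [field_distortion()].
#' @param gradient optional [gradient_event()] supplying the drift shape.
#' @param system optional [spin_system()]; defaults to a single spin on the
#'   pulse channel.
#' @export
cyclicity_defect <- function(pulse, member = field_distortion(),
                             gradient = NULL, system = NULL) {
  if (is.null(system)) {
    ch <- if (inherits(pulse, "control_pulse")) pulse$channel else
      pulse[[1]]$channel
    system <- spin_system(ch)
  }
  res <- window_propagate(system, pulse, gradient, member$b0_drift,
                          member$b1_scale, member$offset_hz)
  d <- nrow(res$U)
  1 - Mod(sum(diag(res$U))) / d
}
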