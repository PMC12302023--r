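# Hamiltonian construction.  All returned matrices are Hermitian and in
# angular-frequency units (rad/s); the rotating-frame sign convention is
# H = +gamma B Iz, fixed globally (offsets enter as +2*pi*offset_hz*Iz).

#' Describe a shaped gradient pulse
#'
#' A gradient event carries the temporal shape of the field pulse, its
#' duration, a signed relative amplitude (fraction of maximum) and the peak
#' equivalent B0 drift it produces at the edge of the detection zone.  The
#' half-sine shape `A sin(pi t / tau)` is the design default for
#' coherence-locking optimization; the trapezoid is characterized only by
#' its time integral (0.9 ms for a 1 ms pulse by default) as used by the
#' sinc spillover model.
#'
#' @param shape `"half_sine"` or `"trapezoid"`.
#' @param duration pulse length tau in seconds (default 1 ms).
#' @param relative_amplitude signed dimensionless fraction of maximum.
#' @param drift_scale peak equivalent B0 drift in Tesla at the reference
#'   (zone-edge) position, for unit relative amplitude.  Default 2.5e-5 T
#'   (0.25 Gauss), the design value for locking pulses.
#' @param time_integral for the trapezoid, `integral g(t) dt` in seconds;
#'   defaults to `0.9 * duration`.
#' @return an object of class `gradient_event`.
#' @export
gradient_event <- function(shape = c("half_sine", "trapezoid"),
                           duration = 1e-3, relative_amplitude = 1,
                           drift_scale = 2.5e-5, time_integral = NULL) {
  shape <- match.arg(shape)
  stopifnot(duration > 0)
  if (is.null(time_integral))
    time_integral <- if (shape == "trapezoid") 0.9 * duration else
      2 * duration / pi
  structure(list(shape = shape, duration = duration,
                 relative_amplitude = relative_amplitude,
                 drift_scale = drift_scale, time_integral = time_integral),
            class = "gradient_event")
}

# dimensionless temporal profile, 1 at the half-sine peak
shape_value <- function(event, t) {
  if (any(t < 0 | t > event$duration))
    stop("t outside [0, duration]")
  switch(event$shape,
         half_sine = sin(pi * t / event$duration),
         trapezoid = rep_len(event$time_integral / event$duration, length(t)))
}

# integral of the dimensionless profile over [0, tau]
shape_integral <- function(event) {
  switch(event$shape,
         half_sine = 2 * event$duration / pi,
         trapezoid = event$time_integral)
}

#' Describe one ensemble member's field distortion
#'
#' @param b0_drift static-equivalent B0 drift in Tesla (the peak of a
#'   time-dependent profile when used with a gradient event).
#' @param b1_scale dimensionless multiplier on the nominal RF amplitude
#'   (must be positive; design ranges are +/-20 \% for 1H, +/-15 \% for
#'   13C).
#' @param offset_hz additional resonance offset in Hz.
#' @export
field_distortion <- function(b0_drift = 0, b1_scale = 1, offset_hz = 0) {
  stopifnot(b1_scale > 0)
  structure(list(b0_drift = b0_drift, b1_scale = b1_scale,
                 offset_hz = offset_hz),
            class = "field_distortion")
}

# Iz on spin k embedded in the full space
.iz_spin <- function(system, k) {
  n <- n_spins(system)
  lab <- rep("1", n)
  lab[k] <- "z"
  build_operator(paste(lab, collapse = ""), system)
}

#' Zeeman drift Hamiltonian
#'
#' \eqn{\sum_k \gamma_k b_0 I_{z,k}} in rad/s.  At `b0 = 1` this is the
#' 1 T Zeeman Hamiltonian that the time-dependent gradient drift rescales.
#'
#' @param system a [spin_system()].
#' @param b0 field drift in Tesla.
#' @return Hermitian complex matrix (rad/s).
#' @export
zeeman_drift <- function(system, b0) {
  stopifnot(is.finite(b0))
  d <- 2^n_spins(system)
  H <- matrix(0i, d, d)
  for (k in seq_len(n_spins(system)))
    H <- H + system$gamma[k] * b0 * .iz_spin(system, k)
  H
}

#' Time-dependent gradient drift Hamiltonian
#'
#' For a half-sine event this is `A sin(pi t / tau)` times the Zeeman
#' drift, with `A = drift_scale * relative_amplitude`.
#'
#' @param event a [gradient_event()].
#' @param t time within `[0, duration]`, seconds.
#' @param system a [spin_system()].
#' @export
gradient_drift <- function(event, t, system) {
  b0 <- event$drift_scale * event$relative_amplitude * shape_value(event, t)
  zeeman_drift(system, b0)
}

#' RF control-field Hamiltonian
#'
#' \eqn{2\pi \nu_1 s_{B1} (\cos\phi\, I_x + \sin\phi\, I_y)} on the named
#' channel only.
#'
#' @param system a [spin_system()].
#' @param channel isotope label of the irradiated spin.
#' @param amp_hz nominal RF amplitude nu1 in Hz (>= 0).
#' @param phase RF phase in radians.
#' @param b1_scale dimensionless B1 scale.
#' @export
rf_hamiltonian <- function(system, channel, amp_hz, phase = 0, b1_scale = 1) {
  stopifnot(amp_hz >= 0)
  k <- match(channel, system$labels)
  if (is.na(k)) stop("unknown channel '", channel, "'")
  n <- n_spins(system)
  labx <- rep("1", n); labx[k] <- "x"
  laby <- rep("1", n); laby[k] <- "y"
  Ix <- build_operator(paste(labx, collapse = ""), system)
  Iy <- build_operator(paste(laby, collapse = ""), system)
  2 * pi * amp_hz * b1_scale * (cos(phase) * Ix + sin(phase) * Iy)
}

#' Heteronuclear scalar-coupling Hamiltonian
#'
#' Weak (secular) regime returns \eqn{2\pi J I_z S_z}; the full isotropic
#' form \eqn{2\pi J (I_xS_x + I_yS_y + I_zS_z)} is available for
#' validation.  The weak form commutes with both `Iz` and `Sz`, so J
#' evolution conserves coherence order.
#'
#' @param system a two-spin [spin_system()].
#' @param regime `"weak"` or `"full"`.
#' @export
j_coupling <- function(system, regime = c("weak", "full")) {
  regime <- match.arg(regime)
  if (n_spins(system) != 2L)
    stop("j_coupling requires a 2-spin system")
  J <- system$j_hz[1, 2]
  if (regime == "weak")
    return(2 * pi * J * build_operator("zz", system))
  2 * pi * J * (build_operator("xx", system) +
                build_operator("yy", system) +
                build_operator("zz", system))
}

# offset Hamiltonian sum_k 2*pi*offset_k Iz_k (rad/s)
offset_hamiltonian <- function(system, extra_offset_hz = 0) {
  d <- 2^n_spins(system)
  H <- matrix(0i, d, d)
  off <- system$offset_hz + rep_len(extra_offset_hz, n_spins(system))
  for (k in seq_len(n_spins(system)))
    H <- H + 2 * pi * off[k] * .iz_spin(system, k)
  H
}

# matrix exponential exp(-i H t) for Hermitian H (R-side convenience)
expm_herm <- function(H, t) {
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  V %*% (exp(-1i * e$values * t) * Conj(t(V)))
}
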