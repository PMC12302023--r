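# Average-Hamiltonian evaluation of residual heteronuclear J coupling
# under locking pulses: toggling-frame tensor c(t) and scale factor
# chi = ||mean c||.  chi = 1 means the coupling is fully retained, chi = 0
# perfect decoupling; couplings are negligible when chi * J * tau << 1.

# toggling-frame coefficients of Iz for one channel: c_k(t) =
# 2 Tr(I_k U^dag(t) Iz U(t)), evaluated at slice midpoints.
.toggle_coeffs <- function(pulse, offset_hz, b1_scale) {
  sys1 <- spin_system(pulse$channel)
  res <- window_propagate(sys1, pulse, gradient = NULL, drift_T = 0,
                          b1_scale = b1_scale, offset_hz = offset_hz,
                          keep_mids = TRUE)
  Iz <- build_operator("z", sys1)
  ops <- list(build_operator("x", sys1), build_operator("y", sys1), Iz)
  n <- length(res$time)
  cc <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    U <- res$mids[, , k]
    A <- Conj(t(U)) %*% Iz %*% U
    for (j in 1:3) cc[k, j] <- 2 * Re(sum(Conj(ops[[j]]) * A))
  }
  cc
}

#' Toggling-frame J-coupling tensor and scale factor chi
#'
#' In the interaction frame of the RF-plus-offset propagator the secular
#' heteronuclear coupling \eqn{2\pi J I_zS_z} becomes time dependent.  With
#' one irradiated channel its coefficients form a unit 3-vector
#' \eqn{c(t)}; with both channels irradiated, a 3x3 tensor
#' \eqn{c_{kl}(t)} (outer product of the two single-channel vectors).  The
#' scale factor is the Euclidean (Frobenius) norm of the time average:
#' \eqn{\chi = \|\bar c\|}.
#'
#' @param pulse a [control_pulse()] on the first channel.
#' @param offset_hz resonance offset of the irradiated spin (Hz).
#' @param b1_scale B1 multiplier for `pulse`.
#' @param pulse2 optional second-channel [control_pulse()] (dual-channel
#'   locking); must share the time grid.
#' @param offset2_hz,b1_scale2 distortion for the second channel.
#' @return object of class `toggle_tensor` with fields `time`, `c`
#'   (n x 3 matrix, or n x 3 x 3 array for dual channel), `cbar`, `chi`.
#' @export
toggling_tensor <- function(pulse, offset_hz = 0, b1_scale = 1,
                            pulse2 = NULL, offset2_hz = 0,
                            b1_scale2 = 1) {
  c1 <- .toggle_coeffs(pulse, offset_hz, b1_scale)
  n <- nrow(c1)
  tgrid <- (seq_len(n) - 0.5) * pulse$slice_dt
  if (is.null(pulse2)) {
    cbar <- colMeans(c1)
    out <- list(time = tgrid, c = c1, cbar = cbar,
                chi = sqrt(sum(cbar^2)))
  } else {
    if (pulse2$n_slices != n || abs(pulse2$slice_dt - pulse$slice_dt) >
        1e-15)
      stop("dual-channel pulses must share the time grid")
    c2 <- .toggle_coeffs(pulse2, offset2_hz, b1_scale2)
    cc <- array(0, dim = c(n, 3, 3))
    for (k in seq_len(n)) cc[k, , ] <- outer(c1[k, ], c2[k, ])
    cbar <- apply(cc, c(2, 3), mean)
    out <- list(time = tgrid, c = cc, cbar = cbar,
                chi = sqrt(sum(cbar^2)))
  }
  structure(out, class = "toggle_tensor")
}

#' @export
print.toggle_tensor <- function(x, ...) {
  cat("<toggle_tensor> chi = ", format(signif(x$chi, 5)), "\n", sep = "")
  invisible(x)
}

#' J-coupling scale factor over an offset x B1 grid
#'
#' Evaluates chi on a grid of resonance offsets and B1 scales, the
#' robustness map used to verify that a locking pulse suppresses
#' heteronuclear J coupling across its design range.
#'
#' @inheritParams toggling_tensor
#' @param offsets_hz vector of offsets (Hz).
#' @param b1_scales vector of B1 multipliers.
#' @param pulse2 optional second-channel pulse; when given, the offset and
#'   B1 grids are applied to both channels in lockstep (nu0 and nu1
#'   aligned).
#' @return object of class `chi_map`: matrix of chi values
#'   (offsets x B1) with the grids attached.
#' @export
chi_map <- function(pulse, offsets_hz, b1_scales, pulse2 = NULL) {
  m <- matrix(0, length(offsets_hz), length(b1_scales),
              dimnames = list(offsets_hz, b1_scales))
  for (i in seq_along(offsets_hz))
    for (j in seq_along(b1_scales))
      m[i, j] <- toggling_tensor(pulse, offsets_hz[i], b1_scales[j],
                                 pulse2, offsets_hz[i],
                                 b1_scales[j])$chi
  structure(list(chi = m, offsets_hz = offsets_hz,
                 b1_scales = b1_scales),
            class = "chi_map")
}

#' @export
print.chi_map <- function(x, ...) {
  cat("<chi_map> ", length(x$offsets_hz), " offsets x ",
      length(x$b1_scales), " B1 scales; max chi = ",
      format(signif(max(x$chi), 4)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.chi_map <- function(x, ...) {
  data.frame(offset_hz = rep(x$offsets_hz, times = length(x$b1_scales)),
             b1_scale = rep(x$b1_scales, each = length(x$offsets_hz)),
             chi = as.vector(x$chi))
}

#' Write a chi map as a CSV grid (offset_hz, b1_scale, chi)
#' @param x a `chi_map`.
#' @param path output file.
#' @export
write_chi_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Is a residual coupling negligible over a locking window?
#'
#' Returns the dimensionless product chi * J * tau (in cycles) and a
#' verdict against a threshold; residual couplings can be ignored while
#' the product is much smaller than one.
#'
#' @param chi_value scale factor in `[0, 1]`.
#' @param j_hz scalar coupling in Hz.
#' @param tau_s locking-window duration in seconds.
#' @param threshold verdict threshold in cycles (default 0.05).
#' @export
negligibility <- function(chi_value, j_hz, tau_s, threshold = 0.05) {
  stopifnot(chi_value >= 0, j_hz >= 0, tau_s >= 0)
  prod <- chi_value * j_hz * tau_s
  list(product = prod, negligible = prod <= threshold,
       threshold = threshold)
}
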