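#' @useDynLib clocr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rnorm runif sd quantile nls coef predict
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

# Gyromagnetic ratios, rad s^-1 T^-1.  The 1H value is the rounded constant
# used throughout the gradient-drift arithmetic in this package.
.GAMMA_TABLE <- c(
  "1H"  =  2.675e8,
  "13C" =  6.728e7,
  "15N" = -2.7126e7,
  "19F" =  2.5181e8,
  "31P" =  1.0839e8
)

#' Proton gyromagnetic ratio
#'
#' The rounded constant \eqn{\gamma_H = 2.675\times 10^8} rad s\eqn{^{-1}}
#' T\eqn{^{-1}} used for all gradient-drift and diffusion arithmetic.
#' @export
GAMMA_1H <- 2.675e8

#' Define a spin system of one or two spins-1/2
#'
#' A spin system carries isotope labels, gyromagnetic ratios, resonance
#' offsets and a symmetric scalar-coupling table.  Only one- and two-spin
#' systems are supported: these cover single-spin coherence locking and the
#' heteronuclear IS pair (e.g. 1H-13C with J = 145 Hz) used in the
#' gradient-selected HSQC/HMQC simulations.
#'
#' @param labels character vector of isotope labels, e.g. `c("1H","13C")`.
#'   Known isotopes ("1H", "13C", "15N", "19F", "31P") get default
#'   gyromagnetic ratios.
#' @param offset_hz resonance offset per spin in Hz (recycled).
#' @param j_hz scalar coupling in Hz: either a single number (the IS
#'   coupling of a two-spin system) or a symmetric matrix with zero
#'   diagonal.
#' @param gamma optional gyromagnetic ratios (rad s^-1 T^-1) overriding the
#'   isotope defaults.
#' @return an object of class `spin_system`.
#' @examples
#' hc <- spin_system(c("1H", "13C"), j_hz = 145)
#' @export
spin_system <- function(labels = "1H", offset_hz = 0, j_hz = 0,
                        gamma = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L || n > 2L)
    stop("spin_system supports 1 or 2 spins, got ", n)
  if (is.null(gamma)) {
    gamma <- unname(.GAMMA_TABLE[labels])
    if (anyNA(gamma))
      stop("unknown isotope(s) ", paste(labels[is.na(gamma)], collapse = ", "),
           "; supply `gamma` explicitly")
  }
  stopifnot(length(gamma) == n)
  offset_hz <- rep_len(as.numeric(offset_hz), n)
  if (is.matrix(j_hz)) {
    stopifnot(nrow(j_hz) == n, ncol(j_hz) == n)
    if (any(diag(j_hz) != 0)) stop("j_hz diagonal must be zero")
    if (!isTRUE(all.equal(j_hz, t(j_hz)))) stop("j_hz must be symmetric")
    J <- j_hz
  } else {
    J <- matrix(0, n, n)
    if (n == 2L) J[1, 2] <- J[2, 1] <- as.numeric(j_hz)[1]
    else if (any(j_hz != 0)) stop("scalar j_hz requires a 2-spin system")
  }
  structure(list(labels = labels, gamma = gamma, offset_hz = offset_hz,
                 j_hz = J),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> ", paste(x$labels, collapse = "-"), "\n", sep = "")
  cat("  gamma [rad/s/T]: ", paste(signif(x$gamma, 5), collapse = ", "), "\n")
  cat("  offset [Hz]:     ", paste(x$offset_hz, collapse = ", "), "\n")
  if (length(x$labels) == 2L)
    cat("  J [Hz]:          ", x$j_hz[1, 2], "\n")
  invisible(x)
}

n_spins <- function(system) length(system$labels)

# single-spin operator matrices under the "+" = x + iy convention
.single_op <- function(sym) {
  switch(sym,
         "1" = diag(2) + 0i,
         "x" = matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i,
         "y" = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
         "z" = diag(c(0.5, -0.5)) + 0i,
         "+" = matrix(c(0, 0, 1, 0), 2, 2) + 0i,
         "-" = matrix(c(0, 1, 0, 0), 2, 2) + 0i,
         stop("unknown operator symbol '", sym, "'"))
}

split_label <- function(label) {
  syms <- strsplit(label, "")[[1]]
  bad <- setdiff(syms, c("1", "x", "y", "z", "+", "-"))
  if (length(bad))
    stop("unknown factor symbol(s) in coherence label: ",
         paste(bad, collapse = ", "))
  syms
}

#' Build a product-operator matrix
#'
#' Turns a coherence label such as `"z"`, `"+"`, or `"-+"` (meaning
#' \eqn{I^- S^+}) into its \eqn{2^n \times 2^n} matrix representation by
#' Kronecker product of single-spin factors.  The raising/lowering
#' convention is \eqn{I^\pm = I_x \pm i I_y}.
#'
#' @param label string with one character per spin from `1 x y z + -`.
#' @param system a [spin_system()]; label arity must match.
#' @return complex matrix.
#' @examples
#' build_operator("+", spin_system("1H"))
#' @export
build_operator <- function(label, system) {
  syms <- split_label(label)
  if (length(syms) != n_spins(system))
    stop("label '", label, "' has ", length(syms), " factor(s) but system has ",
         n_spins(system), " spin(s)")
  op <- .single_op(syms[1])
  if (length(syms) > 1L)
    for (k in 2:length(syms)) op <- kronecker(op, .single_op(syms[k]))
  op
}

#' Coherence order of a product-operator label
#'
#' Sum of per-spin orders: +1 for `+`, -1 for `-`, 0 otherwise.  Gradients
#' imprint phase proportional to this order times the gyromagnetic ratio.
#'
#' @param label coherence label string.
#' @return integer in `[-n, n]`.
#' @examples
#' coherence_order("-+")  # I-S+ is a zero-quantum term
#' @export
coherence_order <- function(label) {
  syms <- split_label(label)
  sum(ifelse(syms == "+", 1L, ifelse(syms == "-", -1L, 0L)))
}

# orders per spin, used by the gradient bookkeeping
coherence_orders <- function(label) {
  syms <- split_label(label)
  ifelse(syms == "+", 1L, ifelse(syms == "-", -1L, 0L))
}

#' Normalized overlap of a state with a target coherence
#'
#' Returns \eqn{\mathrm{Re}\,\mathrm{Tr}(T^\dagger \rho)/\mathrm{Tr}
#' (T^\dagger T)}, so that `overlap(T, T) == 1` for any label and ensemble
#' locking trajectories read as fractions of retained coherence.
#'
#' @param state density-operator-like complex matrix.
#' @param target coherence label string, or a matrix of matching dimension.
#' @param system the [spin_system()] (needed when `target` is a label).
#' @return real scalar.
#' @export
overlap <- function(state, target, system = NULL) {
  Tm <- if (is.character(target)) build_operator(target, system) else target
  if (!all(dim(Tm) == dim(state))) stop("dimension mismatch")
  nrm <- Re(sum(Conj(Tm) * Tm))
  if (nrm <= .Machine$double.eps) stop("zero-norm target")
  Re(sum(Conj(Tm) * state)) / nrm
}
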