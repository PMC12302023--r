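# shared fixtures: spin systems, oracle operator builders, random pulses

sys_h <- spin_system("1H")
sys_hc <- spin_system(c("1H", "13C"), j_hz = 145)

# independent single-spin matrices for Kronecker oracles (built from Pauli
# matrices, not via build_operator)
pauli <- list(
  x = matrix(c(0, 1, 1, 0), 2, 2) / 2 + 0i,
  y = matrix(c(0, 1i, -1i, 0), 2, 2) / 2,
  z = diag(c(1, -1)) / 2 + 0i,
  "1" = diag(2) + 0i
)
pauli[["+"]] <- pauli$x + 1i * pauli$y
pauli[["-"]] <- pauli$x - 1i * pauli$y

kron_oracle <- function(label) {
  syms <- strsplit(label, "")[[1]]
  Reduce(kronecker, lapply(syms, function(s) pauli[[s]]))
}

random_pulse <- function(channel = "1H", n = 40, dt = 25e-6,
                         nominal = 6000, seed = 1) {
  set.seed(seed)
  a <- runif(n, 0, nominal)
  ph <- runif(n, 0, 2 * pi)
  control_pulse(channel, a * cos(ph), a * sin(ph), dt, nominal)
}
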