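Package: clocr
Title: Coherence-Locking Pulse Design and Spin Dynamics for Parallel NMR
Version: 0.1.0
Authors@R:
    person("clocr", "developers", email = "clocr@example.org", role = c("aut", "cre"))
Description: Tools for designing radio-frequency pulses that lock nuclear spin
    coherences against pulsed-field-gradient spillover in parallel NMR probes.
    Provides product-operator spin algebra for one- and two-spin-1/2 systems,
    Hamiltonian construction (Zeeman drift, time-dependent gradient drift, RF
    control, heteronuclear J coupling), piecewise-constant unitary propagation
    with voxel/field-distortion ensembles, GRAPE-style optimal control with
    state-locking and cyclic-propagator targets, average-Hamiltonian evaluation
    of residual heteronuclear J coupling (scale factor chi), sequence-level
    simulators for PGSE and gradient-selected HSQC/HMQC with coherence-pathway
    bookkeeping, calibration-curve fitting (diffusion attenuation and sinc
    spillover models), shaped-pulse file I/O in a JCAMP-DX dialect, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
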