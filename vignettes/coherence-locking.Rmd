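---
title: "Coherence locking against gradient spillover: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence locking against gradient spillover: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Parallel NMR probes put several detectors, each with its own RF and
pulsed-field-gradient coil, into one magnet to raise sample throughput.
Imperfect shielding lets a gradient pulse fired at one detector leak a
stray field into its neighbours ("gradient spillover").  The stray field
is a time-dependent B0 inhomogeneity: transverse coherences at the
neighbouring detector acquire a position-dependent phase, the voxel
average decays, and the neighbour loses signal through no fault of its own
pulse sequence.

`clocr` implements the compensation strategy of locking the endangered
coherences with a shaped RF pulse played *simultaneously* with the
offending gradient.  The pulse is found by optimal control (GRAPE) and is
robust over an ensemble of drift amplitudes, resonance offsets and B1
scales, so one waveform protects the coherence wherever the spins sit in
the detection zone and whatever the gradient amplitude of the neighbour's
sweep happens to be.

## Model and conventions

* **Spin systems.** One or two spins-1/2 (`spin_system()`), expressed in
  the product-operator basis (`build_operator()`); density operators are
  dense 2x2 / 4x4 complex matrices.  Convention: $I^\pm = I_x \pm i I_y$;
  rotating-frame Hamiltonians are written $+\gamma B I_z$ (offsets enter
  as $+2\pi\nu_0 I_z$).  Neither sign choice affects any fidelity, scale
  factor or attenuation reported by the package, so they are fixed
  globally and not configurable.
* **Overlap normalization.** Locking trajectories report
  $\mathrm{Re}\,\mathrm{Tr}(T^\dagger\rho)/\mathrm{Tr}(T^\dagger T)$, so a
  trajectory that starts at the protected coherence starts at exactly 1
  and reads as the fraction of coherence retained.
* **Drift model.** A gradient pulse of duration $\tau$ (1 ms default)
  produces a drift Hamiltonian $A\sin(\pi t/\tau)\,H_{z,1\mathrm{T}}$,
  where $H_{z,1\mathrm{T}}$ is the 1 T Zeeman Hamiltonian.  The peak drift
  $A$ is modeled linear in the voxel position across the 6.5 mm detection
  zone, reaching $\pm A_\max$ at the zone edges ($A_\max = 0.25$ G for the
  design ensemble).  The linear profile is the same assumption behind the
  closed-form sinc attenuation, so the two routes can be cross-checked.
* **J coupling.** Heteronuclear coupling defaults to the secular form
  $2\pi J\,I_zS_z$ ($J = 145$ Hz for the worked IS pair); the full
  isotropic form exists for validation only.  Homonuclear coupling is out
  of scope.

## Pulse design

`optimize_cloc()` ascends the ensemble-mean fidelity of a piecewise-
constant two-quadrature pulse (250 slices of 4 us over 1 ms by default)
with the exact first-order GRAPE gradient, computed per slice with the
Daleckii-Krein (Frechet) derivative of the slice exponential — so the
analytic gradient agrees with finite differences to ~1e-9 relative, and
quasi-Newton (L-BFGS-B) steps are well founded.

Two targets exist:

* `state_lock`: protect one named coherence, reported as
  $(1+\mathrm{Re}\langle T|U\rho_0U^\dagger\rangle)/2 \in [0,1]$;
* `cyclic` (primary): drive the net propagator to the identity up to a
  global phase, which protects *every* coherence of the irradiated spin at
  once.  Reported as the phase-insensitive $|\mathrm{Tr}\,U|/2^n$.

**A landscape subtlety worth recording.**  Optimizing
$|\mathrm{Tr}\,U|/2^n$ directly stalls far from the optimum: different
ensemble members settle on opposite global-phase branches ($U \to +1$ vs
$U \to -1$, both perfect for the phase-insensitive functional), and the
ensemble mean then frustrates the ascent.  The optimizer therefore
internally ascends the phase-locked functional
$\mathrm{Re}\,\mathrm{Tr}(U)/2^n$, which forces all members onto the $+1$
branch; the reported fidelity is still the phase-insensitive one.  On the
default 1H grid this is the difference between stalling near 0.81 and
converging above 0.995.

Tunable parameters (defaults, units, rationale):

| parameter | default | why |
|---|---|---|
| pulse duration | 1 ms | must equal the gradient duration it shadows |
| slices | 250 (4 us) | resolves 6 kHz nutation (~42 slices/rotation) and the half-sine drift |
| 1H amplitude ceiling | 6 kHz | kept low to limit RF coupling between detectors |
| 13C amplitude ceiling | 4 kHz | same reason |
| 1H ensemble | 5 drifts x 5 offsets x 3 B1 | spans +/-0.25 G, 7 kHz bandwidth, +/-20 % B1 |
| 13C ensemble | as above | 6 kHz bandwidth, +/-15 % B1 |
| iterations | 1000/restart | 500 (the first guess for this budget) demonstrably stalls before convergence on the 1H grid; 1000 converges with margin |
| restarts | 3, seeded | landscape has local optima; restarts are cheap |
| tolerance | 1e-8 on fidelity change | L-BFGS `factr` equivalent |
| seed | 20250717 | reproducibility; any seed is accepted |

Amplitude limiting uses a smooth clip: raw per-slice quadratures are
scaled by $u_\max\tanh(r/u_\max)/r$ so the magnitude approaches but never
exceeds the ceiling and the map stays differentiable (a hard projection
would break the quasi-Newton model).  The optimizer works on raw controls
divided by $u_\max$; without this scaling the first iterations take
near-zero steps because the per-Hz gradient entries are ~1e-5.

## Residual heteronuclear coupling (average Hamiltonian)

During a locking pulse the secular coupling $2\pi J I_zS_z$ becomes
time-dependent in the interaction frame of the RF-plus-offset propagator:
$I_z \to \sum_k c_k(t) I_k$ with $\|c(t)\| = 1$.  The first-order
effective coupling is scaled by $\chi = \|\bar c\|$, the norm of the time
average; `toggling_tensor()` evaluates $c$ at slice midpoints (matching
the propagation discretization) and `chi_map()` scans offset x B1 grids.
With both channels irradiated the object is the 3x3 tensor
$c^{(1)}_k c^{(2)}_l$ and "norm" is read as the Frobenius norm — the
natural tensor reduction, and the one that collapses to the Euclidean
norm in the single-channel case.

A coupling is negligible over the window when $\chi J\tau \ll 1$;
`negligibility()` applies a 0.05-cycle threshold by default (at
$\chi = 0.1$, $J = 145$ Hz, $\tau = 1$ ms the product is 0.0145).

The package cross-checks first-order AHT against brute-force two-spin
propagation: for a constant test pulse the effective coupling fitted from
the protected-coherence overlap agrees with $\chi J$ within 10 %.  The
test suite asserts the 10 % bound on $\chi$ over the designed offset x B1
grid for the 1H pulse (the acceptance target); the corresponding bound is
*not* asserted for the 13C channel, whose RF ceiling is lower relative to
its design bandwidth.

## Sequence simulation

`simulate_sequence()` propagates a voxel ensemble through hard pulses
(ideal, zero duration), delays (offset + secular J), primary
pathway-selection gradients, and coupled (spillover) gradients with
optional locking pulses.  Design choices:

* **Integer-cycle primary gradients.**  A primary gradient of unit
  relative amplitude imprints an integer number of phase cycles across the
  zone in units of the smaller gyromagnetic ratio, with the nominal
  $\gamma_H/\gamma_C = 4$ convention (the assumption behind 4:1 and
  2:2:-1 ratio selection).  Over $n$ equally spaced voxels the average of
  $e^{2\pi i m z}$ vanishes *exactly* for integer $m \not\equiv 0 \pmod n$,
  so dephased pathways cancel to machine precision and the refocusing
  theorem holds within 1e-6 at 64 voxels.  An `exact` gamma mode reports
  the small residual phase instead.
* **Refocused-window convention.**  Neither J nor offsets evolve inside
  gradient/locking windows: gradient pulses in real gradient-selected
  sequences sit inside echoes, and locking windows are excluded from the
  J-evolution delay bookkeeping (delays are set to their nominal
  $\Delta = 1/4J$ values).  This keeps the three scenarios — `reference`,
  `coupled`, `coupled_with_cloc` — comparable: they differ only in
  spillover dephasing and locking quality.  J *is* active during locking
  windows in `locking_trajectory()` and in the AHT cross-checks, which is
  where its effect belongs.
* **Coupled-pair polarity in the PGSE test.**  The effective polarity of
  the neighbour's gradient pair relative to the echo depends on timing
  details a simulation must choose: a same-polarity pair straddling the
  inversion pulse self-refocuses and produces no loss at all.  The
  builder therefore uses a bipolar coupled pair, which gives
  the expected sinc-like decay (net moment 2 on the echo pathway) and
  matches the narrative of protecting $I^+$ during the first spillover
  period and $I^-$ during the second.

## Calibration fits and synthetic data

The PGSE attenuation
$\ln(I_g/I_0) = -\gamma^2\delta^2G^2(\Delta-\delta)D$ is fitted on the log
scale (multiplicative noise is homoscedastic there; the noiseless fit is
exact), the sinc spillover model $I_g/I_0 = \sin(kg)/kg$ by
grid-initialized nonlinear least squares on the linear scale.  Both return
residual-resampling bootstrap CIs.

`generate_calibration_fixture()` emulates the calibration measurements
with the stated parameters ($G_{\max} = 1.0306$ T/m; $R_G = 1.9\times
10^{-3}$; $\delta = 1$ ms, $\Delta = 7$ ms, $D = 1.9\times10^{-9}$
m$^2$/s) and 1 % multiplicative Gaussian noise, seed-fixed.  It emulates
the *shape and noise level* of such curves — not probe drift, temperature
effects, RF coupling between detectors, relaxation or the true noise
correlation structure.  A green recovery test therefore establishes that
the estimators are consistent and correctly implemented at realistic
noise, not that the instrument would deliver these numbers.

## Numerical choices

* Slice width 4 us (midpoint rule for time-dependent drift); error is
  O($\Delta t^2$), validated by slice-halving.  Propagators are exact
  matrix exponentials via Hermitian eigendecomposition (unitarity ~1e-14
  per window).
* The propagation phase is exact for the midpoint-sampled drift profile;
  agreement with the continuous half-sine integral is ~3e-5 rad at 250
  slices and improves quadratically — the 1e-8-rad oracle test is
  formulated against the sampled profile.
* $|\mathrm{Tr}\,U| \approx 0$ makes the cyclic-fidelity gradient
  undefined; the gradient contribution of such a member is set to zero
  (measure-zero set, and the optimizer never operates there because it
  ascends the phase-locked functional).
* The sinc fit's $k$ is initialized by a 200-point grid search on
  $(0.05, \pi/g_\max)$ before local refinement, avoiding the secondary
  lobes of the sinc least-squares surface.

## Known limitations

Two coupled spins at most; no relaxation anywhere (the locking windows
are short against typical liquid-state T1/T2, and every quantity reported
here is relaxation-free); no diffusion during gradient windows (diffusion
enters only through the closed-form PGSE model); homonuclear coupling
compensation, RF inter-detector coupling, coil-geometry field simulation
and hardware control are out of scope.  The HSQC simulator is a single IS
pair: per-peak intensities of real multi-spin spectra are outside desk
scale, and only the scenario ordering (coupled $\le$ locked $\le$
reference) is asserted.
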