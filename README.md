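# clocr — coherence locking against gradient spillover in parallel NMR

Parallel NMR probes raise throughput by running several detectors, each
with its own RF and pulsed-field-gradient coil, in one magnet.  Imperfect
shielding makes a gradient pulse at one detector spill a stray field into
its neighbours; the stray field dephases transverse coherences across the
neighbour's detection zone and silently destroys its signal.  `clocr` is a
desk-scale spin-dynamics toolkit for the compensation strategy of
*coherence locking by optimal control*: shaped RF pulses, played
simultaneously with the offending gradient, that return every protected
coherence to itself at the end of the gradient window.

For whom: NMR methods developers and simulation-minded spectroscopists who
want to design such pulses, quantify their residual heteronuclear J
coupling, and rehearse gradient-selected experiments (PGSE, HSQC, HMQC)
under spillover — without hardware.

## The models at the core

* **Spillover dephasing.**  A linear stray field across a detection zone
  of length $l$ attenuates a pulse-acquire signal as
  $I_g/I_0 = \sin(kg)/(kg)$, with
  $k = (l/2)\,\gamma\,R_G G_{\max} \int g(t)\,dt$ — the sinc model used to
  calibrate the spillover ratio $R_G$.
* **Gradient calibration.**  PGSE diffusion attenuation
  $\ln(I_g/I_0) = -\gamma^2\delta^2 G^2(\Delta-\delta)D$ calibrates
  $G_{\max}$.
* **Pulse design.**  GRAPE optimal control with exact analytic gradients
  drives the net propagator of a 1 ms, 250-slice pulse to the identity
  ($U = 1$, "cyclic propagation") over an ensemble of half-sine B0 drifts
  ($\pm0.25$ G), resonance offsets (7 kHz bandwidth for 1H) and B1 scales
  ($\pm20\,\%$), under a 6 kHz amplitude ceiling.
* **Residual coupling.**  Average-Hamiltonian theory: the heteronuclear
  coupling surviving a locking pulse is scaled by
  $\chi = \|\bar c\|$, the norm of the time-averaged toggling-frame
  coupling tensor; couplings are negligible while $\chi J \tau \ll 1$.
* **Pathway bookkeeping.**  Gradient-selected sequences refocus a
  coherence pathway iff $\sum_i (\sum_s p_s\gamma_s) G_i = 0$; spillover
  gradients break the balance, locking pulses restore the signal.

## Worked example

Calibrate the gradient and the spillover ratio from synthetic curves:

```r
library(clocr)
curve <- generate_calibration_fixture(
  "pgse", list(Gmax = 1.0306, delta = 1e-3, Delta = 7e-3, D = 1.9e-9),
  noise_sigma = 0.01, seed = 42)
fit <- fit_pgse(curve, D = 1.9e-9)
sprintf("Gmax = %.2f G/cm  (95%% CI %.2f .. %.2f)",
        fit$estimate * 100, fit$ci[1] * 100, fit$ci[2] * 100)
#> "Gmax = 103.90 G/cm  (95% CI 102.91 .. 104.91)"
spillover_signal(1, RG = 1.9e-3, Gmax = 1.0306)
#> 0.6522014
```

The fitted maximum gradient recovers the generating 103.06 G/cm within the
1 % noise; at full coupling-gradient amplitude the neighbour keeps only
65 % of its signal — the loss the locking pulse is designed to prevent.

Design a 1H locking pulse and check what it leaves of a 145 Hz coupling
(about 1.5 min per restart on one CPU):

```r
design <- optimize_cloc(design_spec("1H", restarts = 1))
design
#> <cloc_design> 1H cyclic: fidelity 0.995307 (worst member 0.966478); converged
grid <- chi_map(design$pulse, seq(-3500, 3500, length.out = 9),
                seq(0.8, 1.2, length.out = 5))
max(grid$chi)
#> 0.05476844
negligibility(max(grid$chi), j_hz = 145, tau_s = 1e-3)$product
#> 0.007941423
```

The pulse is cyclic to 0.995 over the whole design grid, scales the
heteronuclear J coupling down to at most 5.5 % of its value across the
designed offset × B1 range (well under the 10 % design bound), and the
residual coupling-evolution product 0.008 cycles is negligible.  Rehearse
a locked HSQC under spillover:

```r
design_c <- optimize_cloc(design_spec("13C", restarts = 1))
syshc <- spin_system(c("1H", "13C"), j_hz = 145)
prog <- hsqc_program(syshc, ratio = c(4, 1), coupled_ratio = c(4, -1),
                     cloc = list("1H" = design$pulse,
                                 "13C" = design_c$pulse))
simulate_sequence(prog, syshc, ensemble_spec(n_voxels = 64), "coupled")$relative
#> 0.3960656
simulate_sequence(prog, syshc, ensemble_spec(n_voxels = 64), "coupled_with_cloc")$relative
#> 0.9972557
```

Spillover from a neighbour running the 4:-1 anti-echo selection costs 60 %
of the HSQC signal; with the locking blocks riding on the coupled
gradients the sequence keeps 99.7 % of its reference intensity.

## Command line

```sh
Rscript -e 'quit(status = clocr::cloc_cli())' design --channel 1H --seed 1 --out out/
Rscript -e 'quit(status = clocr::cloc_cli())' chi --shape out/pulse.jdx --out chi.csv
Rscript -e 'quit(status = clocr::cloc_cli())' fixture --kind spillover --out cal.csv
Rscript -e 'quit(status = clocr::cloc_cli())' fit --kind spillover --input cal.csv
```

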