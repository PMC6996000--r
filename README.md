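# qboldsim

Monte Carlo and analytical simulation of asymmetric spin echo (ASE)
quantitative BOLD (qBOLD), for researchers studying why ASE-based qBOLD
systematically overestimates the deoxygenated blood volume (DBV) and
underestimates the oxygen extraction fraction (OEF) of brain tissue.

## The model

qBOLD reads OEF ($E_0$) and DBV ($V_0$) off the reversible relaxation rate
of tissue around a network of randomly oriented, deoxygenated cylindrical
vessels, assuming the static dephasing regime (SDR):

```
R2' = (4/3) pi gamma B0 dchi V0 Hct E0
S_S(tau) = S0 exp(-tE R2) exp(-0.3 tau^2 R2'^2 / V0)   tau < 1.5 V0/R2'
S_L(tau) = S0 exp(-tE R2) exp(-tau R2') exp(V0)        tau > 1.5 V0/R2'
V0 = ln S_extrap(0) - ln S_meas(0)
```

with `dchi = 0.27e-6` (CGS), `gamma = 2.675e8 rad/s/T`, `B0 = 3 T`. Water
diffusion breaks the SDR assumption around small vessels. The package
quantifies what that does to the estimator:

* **Extravascular signal** — proton random walks (20 µs steps,
  `sigma = sqrt(2 D dt)`) through fresh random cylinder networks inside a
  sphere, phase accrued from the exterior cylinder field
  `2 pi gamma B0 (1-Y) Hct dchi (Rc/r)^2 cos(2 phi) sin^2(theta)`, with
  fine-grid refinement near vessels and discarding of walks that enter a
  vessel. Per-proton phase increments are archived in 2 ms bins.
* **Signal synthesis** — any ASE/GESSE protocol on the storage grid is
  recombined from an archive; exact oxygenation scaling (phase linear in
  `1-Y`), volume-fraction scaling (log-magnitude), diffusion-radius
  equivalence (`tau_D ~ Rc^2/D`) and multi-radius products make parameter
  studies ~10^5 times cheaper than re-simulation.
* **Intravascular signal** — analytical blood model with
  `G0 = 4/45 Hct (1-Hct) (4 pi dchi (0.95-Y) B0)^2`, valid for arbitrary
  echo placement; total signal is the volume-weighted sum.
* **Estimator** — the log-linear SDR fit (spin-echo row plus long-`tau`
  rows, `tau > 15 ms`), returning apparent `R2'`, DBV (intercept gap), OEF
  and standard errors, plus a decomposition of the DBV error into
  spin-echo attenuation and intercept terms.
* **Experiments** — single-radius sweeps over log-spaced radii, the
  intravascular-contribution comparison, and the physiological
  distribution experiment built on an eleven-compartment vascular model
  (five arteriolar orders, capillaries at 2.8 µm, five venular orders)
  with per-compartment oxygen saturations.

## Worked example

Simulate a 20 µm-radius population at desk fidelity (500 kept protons),
synthesise the standard ASE protocol (tE = 80 ms, tau = 0, 16–64 ms), and
fit the SDR estimator:

```r
library(qboldsim)

arch <- run_population(Rc = 20, Vf = 0.03, fidelity_config("desk"), seed = 1)
arch
#> phase_archive: Rc = 20 um, Vf = 0.03 , Y_nominal = 0.6
#>   500 kept / 545 simulated protons (45 entered vessels), 60 bins of 2 ms

curve <- extravascular_signal(arch, protocol_ase80(), Y_target = 0.6,
                              T2_t = 80, apply_t2 = TRUE)
fit_qbold(curve)
#> qBOLD estimate: R2' = 3.44 s^-1 (se 0.122), DBV = 0.05306 (se 0.00838), OEF = 0.1786
```

The true parameters were OEF = 40%, DBV = 3%: at this vessel radius
diffusion inflates the apparent DBV to ~5.3% (+77%) and more than halves
the apparent OEF — the systematic error the package exists to
characterise. At
`Rc = 1000` µm the same pipeline recovers `R2'` near the SDR prediction of
4.36 s⁻¹ and DBV near truth.

A thin command-line front end over the same functions is included at
`inst/cli/qboldsim` (subcommands `simulate`, `sweep`, `decompose`,
`distribution`, `fit`, `fixtures`).

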