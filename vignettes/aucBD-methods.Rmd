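---
title: "Brownian-dynamics prediction of AUC concentration profiles: model and numerics"
author: "aucBD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian-dynamics prediction of AUC concentration profiles: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucBD)
```

## The problem

Analytical ultracentrifugation (AUC) characterizes macromolecules in
solution by spinning a sector-shaped cell at angular velocity $\omega$ and
recording the solute concentration profile $c(r,t)$ between the meniscus
$r_m$ and the bottom $r_b$. Centrifugal drift carries particles outward
with velocity $v = s\omega^2 r$ ($s$: sedimentation coefficient), while the
resulting concentration gradient drives a diffusive counterflow
(coefficient $D$). Macroscopically the balance is the Lamm equation,

$$\frac{\partial c}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
\left[\, r D \frac{\partial c}{\partial r} - s\omega^2 r^2 c \,\right],$$

whose numerical solution is the standard route to predicted profiles.
**aucBD** instead adopts a microscopic picture: it simulates a large number
of independent single-particle trajectories under the same drift plus
Brownian motion, and bins them into $c(r,t)$. The macroscopic and
microscopic routes must agree, and the package ships both: the
Brownian-dynamics (BD) engine is the product, and a deterministic
finite-volume Lamm solver serves as its cross-check.

## The Brownian-dynamics model

One particle carries a single coordinate, its radial distance $r$. Over a
step $\Delta t$,

$$r(t+\Delta t) = r(t) + \Delta r_{\mathrm{sed}} + \Delta r_{\mathrm{Brow}},$$

with two exact ingredients:

* **Drift.** $v = s\omega^2 r$ integrates in closed form to exponential
  growth, so $\Delta r_{\mathrm{sed}} = r\,[\exp(s\omega^2\Delta t) - 1]$
  evaluated at the start-of-step position. No step-size error is incurred
  by the drift alone; `driftDisplacement()` uses `expm1` for accuracy at
  small exponents.
* **Diffusion.** $\Delta r_{\mathrm{Brow}}$ is normal with zero mean and
  variance $2D\Delta t$. Because Brownian motion is self-similar, this is
  the exact free-space propagator at any step length; the normal choice
  makes the large-step algorithm exact in the cell interior.

What the additive form neglects is the coupling between the two terms
*within* one step (the drift rate changes while the particle diffuses).
This is the same approximation the underlying algorithm prescribes, and at
the default run conditions its bias is far below the Monte-Carlo noise of
$10^5$ particles — the step-size equivalence test (50 vs 4000 steps per
run) checks precisely this.

**Boundaries.** A particle ending a step below the meniscus is set to
$r_m$; one ending beyond the bottom bounces to $2 r_b - r$. The two rules
iterate until the position is inside the cell (relevant only for Brownian
steps comparable to the column length). These ad hoc rules approximate the
closed cell's no-flux conditions; their error is confined to the terminal
regions, which AUC practice discards anyway (5% of the column at each end
by default, configurable). One documented consequence: at very coarse
stepping the smearing of a steep bottom accumulation layer can extend past
the 5% cut — the lysozyme velocity preset at 40000 rpm, whose bottom layer
width $1/(\sigma r_b) \approx 0.045$ cm is comparable to its 800 s Brownian
step, is the one preset where the 50-step profile deviates measurably from
the Lamm solution just inside the cut, while 4000 steps restore agreement
to the noise floor.

**Initial state.** Uniform loading in a sector means the radial density is
$p(r) = 2r/(r_b^2 - r_m^2)$; `sampleInitialPosition()` inverts its CDF at
one uniform variate.

**Counting.** The cell is split into $N_r$ half-open slices of width
$\chi$ (the bottom radius belongs to the last slice). At each scan time the
per-slice counts $n(i,j)$ are converted by

$$\frac{c(r_i, t_j)}{c_0} = \frac{r_b^2 - r_m^2}{2\chi}\,
\frac{n(i,j)/N_{\mathrm{part}}}{r_i},$$

with $r_i$ the bin center. The sector angle and cell height cancel; the
division by $r_i$ is what realizes the radial-dilution effect. Column sums
of $n$ equal $N_{\mathrm{part}}$ at every scan — particles cannot leave —
and `massBalance()` exposes that invariant on the concentration scale.

## Reproducible parallel streams

Each particle $k$ owns a counter-based substream (a splitmix64 generator
keyed by the global seed and $k$), consuming exactly one uniform for its
initial position and a Box–Muller pair per step. Trajectories therefore
depend only on `(seed, k, configuration)`, never on execution order, so
partitioning particles over workers is bitwise irrelevant — the tests
assert identical count matrices for serial and multi-worker runs. A
hand-rolled generator is used deliberately: R's global RNG cannot provide
order-independent per-particle sequences, and the splitmix64 finalizer is a
small, well-characterized primitive.

## The Lamm oracle

`lammSolve()` discretizes the Lamm equation in flux form on cell-centered
volumes with the sector weight $r$: the outward flux through an interior
face is built with Scharfetter–Gummel exponential fitting, which reduces to
central differencing where diffusion dominates, to upwinding as
$D \to 0$, is monotone at any Péclet number, and — because the face Péclet
$s\omega^2 r_f \Delta r / D$ integrates the drift exactly across a cell —
has a discrete stationary state that matches the analytic
sedimentation-diffusion equilibrium at the bin centers to machine
precision. Time stepping is a trapezoidal $\theta$-scheme
($\theta = 0.5$) with one tridiagonal solve per step; the flux form
telescopes, so total mass drifts only at roundoff level. The default time
step keeps the drift Courant number $s\omega^2 r_b\,\Delta t/\Delta r$ at
0.2, capped by a fraction of the column diffusion time; both the 2000-cell
grid and the step are overridable, and the grid-refinement test confirms
second-order convergence in smooth regions.

## Equilibrium analysis

At sedimentation equilibrium the classical single-species profile is

$$c(r) = c_0 \exp\!\left[\frac{\omega^2 M (1-\bar v \rho)\,(r^2 - r_m^2)}{2RT}\right],$$

linearized as $\ln c$ vs $r^2 - r_m^2$ with slope
$\omega^2 M (1-\bar v\rho)/(2RT)$. `fitEquilibriumMass()` performs the
unweighted least-squares fit over the cell interior (5% excluded per end),
drops bins with $c/c_0 < 10^{-3}$ (log-domain noise), never
log-transforms non-positive values, and reports the late-scan change
$\max_i |\Delta c/c_0|$ as an equilibration diagnostic without enforcing
it. The fit is exact (relative $10^{-10}$) on noiseless exponential input
across $M = 10^3$–$10^7$ g/mol and invariant to profile scaling.

### What the radial BD chain actually converges to

The cylindrical Lamm operator, rewritten for the radial *number density*
$p = r c$, carries a geometric drift $+D/r$ in addition to $s\omega^2 r$.
The BD scheme — by design, following its source — propagates $r$ with the
sedimentation drift only, so its stationary concentration is not the pure
exponential but

$$c_\infty(r) \propto \exp\!\left[\tfrac{\sigma}{2}(r^2 - r_m^2)\right]\cdot\frac{r_m}{r},
\qquad \sigma = \frac{\omega^2 s}{D},$$

whose fitted slope is low by $\langle 1/r^2\rangle/\sigma$ relative to the
Svedberg-consistent mass. For γ-cyclodextrin at 30000 rpm that deficit is
about 12% — the dominant part of the downward deviations seen in
equilibrium-mode mass recovery, with finite run time contributing the rest
(the omitted term is $\sim\!D/r$ against $s\omega^2 r$, i.e. largest for
small, diffusive solutes at moderate speeds). The long-run property test
therefore checks convergence against this closed form, not against the
Svedberg mass; the distinction matters when interpreting recovered
equilibrium masses, which are expected a few to ~15% below the input $M$.

A second practical consequence: equilibration must be reached within the
simulated time. With the full 1.4 cm column, the poly(ethylene oxide)
preset ($D = 1.1\times 10^{-7}$ cm$^2$/s) needs runs of order $10^6$–$10^7$ s;
at its published $5\times 10^5$ s duration the fitted mass reflects a
developing transient, not equilibrium. Short solution columns (meniscus
moved close to the bottom) are the standard experimental remedy and can be
simulated by adjusting `rMeniscus`; the presets keep the published
geometry and durations as printed.

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| `rMeniscus`, `rBottom` | solution column (cm) | 5.80, 7.20 | standard 12 mm centerpiece |
| `phi`, `height` | sector angle (rad), height (cm) | 0.05236, 1.0 | cancel in all normalized output |
| `nRadial` | radial slices | 100 | bin noise vs resolution at $10^5$ particles |
| `nParticles` | trajectories | $10^5$ | per-bin counting noise ~2–4% |
| `nSteps` | BD steps/run | 50 | large-step algorithm suffices; 4000 for the equivalence check |
| `nScans` | recorded scans | 50 | matches practice; must divide `nSteps` |
| `temperature` | K | 293.15 | standard 20 °C reporting temperature |
| `exclusion` | terminal cut per end | 0.05 | end regions are unreliable in experiment and simulation |
| `minConcentration` | fit cutoff on $c/c_0$ | $10^{-3}$ | keeps log-domain noise out of the fit |
| `nNodes`, `theta` | Lamm grid, implicitness | 2000, 0.5 | second-order, conservative |

The four presets carry the literature parameters of γ-cyclodextrin,
lysozyme, poly(ethylene oxide) and T7 DNA together with their published
rotor speeds and durations for both modes; γ-cyclodextrin's printed molar
mass is retained even though it is about 4% above the value its own $s$,
$D$ and buoyancy imply through the Svedberg relation.

## What the simulation does and does not emulate

The generator reproduces ideal transport in an ideal instrument: dilute
(non-interacting) identical particles, instantaneous scans, no optical
artifacts (fringe jitter, baseline offsets), no rotor acceleration ramp,
no concentration dependence of $s$ or $D$, no solvent compressibility or
temperature gradients, and strictly radial motion (sector walls are never
struck, by construction of the geometry). Passing tests therefore
demonstrate the correctness of the transport model and its numerics — not
robustness to instrumental noise or thermodynamic non-ideality, which real
data analysis must add on top.

## Numerical choices and degenerate inputs

* Bin edges are half-open with $r_b$ assigned to the last slice; bin
  centers are used wherever a slice radius is needed.
* Boundary correction runs after the position update and iterates
  bounce-then-clamp until the position is inside; the meniscus clamp is
  implemented literally (particles may sit exactly at $r_m$), and that
  accumulation point lies inside the excluded terminal region.
* $D = 0$ is legal everywhere: the BD engine reduces to the exact
  exponential characteristics (relative $10^{-12}$ per step) and the Lamm
  fluxes reduce to pure upwinding.
* $s = 0$ leaves the uniform state an exact fixed point of the Lamm
  solver and gives drift-free BD.
* Non-decreasing scan times, positive geometry, divisibility of `nSteps`
  by `nScans`, and conservation of column sums are enforced by class
  validity; configuration errors carry the offending field name.

## Problem sizes in the test suite

Unit and property tests run at reduced sizes chosen to keep the full suite
around a minute: a few thousand particles where only invariants are
checked, $10^5$ particles where a published condition or a noise-scaled
agreement is asserted, 250–4000 Lamm cells depending on the check. All
stochastic agreement thresholds are multiples of Monte-Carlo noise floors
measured from repeat seeds at run time, never frozen constants. The
acceptance script simulates the three published equilibrium experiments at
full size ($10^5$ particles, five seeds each) in a few seconds.

## Known limitations

* The geometric $D/r$ drift omission described above is inherent to the
  simulated scheme; recovered equilibrium masses are biased low relative
  to the Svedberg-consistent input, exactly as the reference results show.
* Very coarse stepping distorts steep boundary layers near the cell ends
  (lysozyme at 50 steps being the documented case); increase `nSteps`
  when the near-bottom region matters.
* Slowly diffusing solutes do not equilibrate over published equilibrium
  durations in a full-length column; the equilibrium fit then measures a
  transient. The `convergence` diagnostic of the fit flags this.
* Single species only; no association equilibria, no concentration
  dependence, no multi-signal optics.
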