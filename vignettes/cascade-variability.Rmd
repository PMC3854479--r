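---
title: "Modeling cell-to-cell variability in kinase cascade signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell-to-cell variability in kinase cascade signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadevar)
```

## The question

Eukaryotic signaling pathways — the yeast pheromone pathway is the motivating
example — transmit an extracellular stimulus through a chain of
phosphorylation steps to a terminal kinase whose activity triggers the
cellular response. The total concentrations of the signaling proteins differ
substantially between genetically identical cells, yet some responses (the
pheromone-induced shmoo) occur at nearly the same stimulus concentration in
every cell. `cascadevar` implements a deterministic modeling framework that
asks when a five-step kinase cascade is variable and when it is invariant,
by propagating log-normal protein-concentration noise through the cascade's
steady-state dose-response curve and summarizing each cell by two features:

* the **pathway sensitivity** `K_m,5`, the stimulus at which the terminal
  kinase is half-maximally activated (the cascade-level EC50), and
* the **maximal pathway activation** `X_max,5`, the terminal activity under
  saturating stimulus.

## The model

Level 1 is receptor-ligand binding: the active fraction is the occupancy
isotherm `X1* = X1_tot * S / (S + K_D)`. Each downstream level `i` is a
phosphorylation-dephosphorylation cycle,

```
dXi*/dt = k_i X_{i-1}* (Xi_tot - Xi*) - p_i P_i Xi* ,
```

whose steady state is Michaelis-Menten in the upstream activity with
half-activation at `Q_i = p_i P_i / k_i`, the point where kinase and
phosphatase activities balance. This gives 9 fluctuating species: kinases
`K1..K5` and phosphatases `P2..P5` (level 1 has none; its deactivation is
ligand dissociation).

Because the composition of Michaelis functions is again Michaelis, the
gradual cascade's global dose-response is *exactly*
`X5*(S) = X_max,5 S / (S + K_m,5)` with the recursion

```
X_max,i = Xi_tot * X_max,i-1 / (X_max,i-1 + Q_i)
K_m,i   = K_m,i-1 * Q_i    / (X_max,i-1 + Q_i),   K_m,1 = K_D
```

(`lumped_parameters()`). The recursion is validated in the test suite against
numeric root finding, long-time ODE integration, and its limits: `K_m,5 ->
K_D` when every **activation resistance** `rho_i = Q_i / X_max,i-1` is large,
`X_max,5 -> X5_tot` when all are small, and the weak-stimulus slope
`X_max,5 / K_m,5 = (prod kinases)(prod k_i) / (K_D prod p_i P_i)` — linear
in every kinase concentration and inverse-linear in every phosphatase
concentration. That product form is the analytic heart of the variability
results: upon weak stimulation the log-variance of the output is the **sum**
of all nine species' log-variances, independent of the kinetic parameters.

### Variants

`cascade_variant()` builds seven parameterizations:

| variant | mechanism |
|---|---|
| `gradual` | minimal Michaelis cascade |
| `upstream_feedback` | X5* activates the level-2 phosphatase: dephosphorylation multiplied by `1 + strength * X5*^n` |
| `downstream_feedback` | X5* activates its own phosphatase |
| `distributed_switch` | levels 2-5 mildly ultrasensitive (Hill n = 2) |
| `single_switch` | levels 1-4 gradual, terminal level a steep Hill switch (n = 10) |
| `basal_feedback` | single switch plus slow transcriptional induction of the level-2 phosphatase, active only before acute stimulation |
| `feedforward` | single switch plus a receptor-driven branch multiplying the level-5 input by `1 + strength * X1*` |

For Hill levels the half-saturation threshold defaults to `Q_i`, so it is
proportional to the phosphatase concentration — fluctuations in phosphatase
expression move switching thresholds, which is essential to the phosphatase
tuning and correlated-noise analyses — and Hill n = 1 with the default
threshold reduces exactly to the Michaelis level. The feedback is modeled as
phosphatase activation; the algebraically equivalent kinase-inhibition form
(divide the steady-state balance by the feedback term) is not implemented
separately.

### Steady-state evaluation

All variants have analytic or semi-analytic steady states. Feedback variants
close a scalar fixed-point equation in `X5*` whose right-hand side is
monotone decreasing, so the fixed point is unique and found by `uniroot()`
to a relative tolerance of about 1e-13. `steady_state_by_integration()`
(deSolve's `lsoda`, rtol 1e-10, atol 1e-12, horizon doubling until
`max |dX/dt| < 1e-9`) is retained as an independent oracle: the test suite
requires agreement to 1e-6 (relative) on 100 random gradual cascades, and
uses non-convergence of the integrator as the behavioral signature of a
sustained oscillator.

## The synthetic population

`sample_population()` draws per-cell scale factors for the 9 species from
independent log-normal distributions with log-mean 0 (median 1) and log-sd
0.35, the magnitude of protein-expression variability reported for
eukaryotic cells (roughly a 3-fold range between low and high expressers;
the CV is `sqrt(exp(0.35^2)-1) ~ 0.36`). The log-sd reading of the 0.35 is
deliberate: only it reproduces the closed-form inter-quartile ratio
`exp(2 * 0.6745 * sqrt(9) * 0.35) = 4.1` for the nine-species product.
Options mirror the study's perturbations: perfect kinase-phosphatase
correlation is implemented as a shared draw (exact proportionality), and
noise elimination fixes a species at its median. One master seed is used and
reused verbatim across model variants, so variant comparisons are paired
cell by cell.

What the generator does **not** emulate: globally correlated "expression
machinery" noise across all species (independence is the conservative
assumption), intrinsic reaction stochasticity, and any nonlinearity between
total protein concentration and activity (sequestration, retroactivity).
Passing tests therefore show robustness *to independent extrinsic
concentration noise in a modular cascade*, not to every noise source of a
real pathway.

## Characterization and metrics

`dose_response()` evaluates a cell on a log-spaced grid spanning
`[1e-4, 1e4] * K_D`; `summarize_response()` reads the plateau at the top of
the grid (`1e4 * K_D` rather than an analytic limit, so numeric-only
variants are treated identically) and finds `K_m,5` as the root of
`response(S) - (basal + (plateau - basal)/2)`, bracketed on the grid and
refined with the continuous evaluator. A cell is a **responder** when the
plateau rise exceeds 1% of the terminal kinase pool — a floor that cleanly
separates the bimodal responder/non-responder regimes of the switch variants
without affecting unimodal ones — and, for switch variants, when the plateau
exceeds half the pool (the switch actually fires). `K_m,5` statistics are
computed over responders only, always reported next to the responder
fraction.

Variability is quantified by the inter-quartile ratio `Q3/Q1`
(`iq_ratio()`; quartiles by linear interpolation, `quantile()` type 7,
declared once and used everywhere) and the coefficient of variation
`sd/mean`. The basal transcriptional protocol is two-phase: solve the full
system including `dP2/dt = basal + induced * X5* - degradation * P2` at the
basal stimulus, then freeze `P2` and sweep the acute stimulus — the
time-scale separation that lets a slow feedback suppress variability without
flattening the acute dose-response.

## Parameter choices

The study's baseline is deliberately symmetric: all median totals, all
`k_i`, and `K_D` equal 1 a.u., with activation resistance tuned by a common
scale on the dephosphorylation rate constants `p_2..p_5` (`p_scale`).
Choices the framework had to fix itself:

* **Switch steepness.** Distributed variant n = 2 per level; single switch
  n = 10 (a "high" Hill coefficient giving a nearly digital terminal step).
* **Moderate feedback strength 100, cooperativity 1.** Strong enough that
  the feedback term `strength * X5*^n` dominates unity at the operating
  point, weak enough to stay far from the asymptotic regime; the asymptotic
  checks use the closed form and a gain of 1e4-1e9.
* **Basal feedback calibration.** Degradation 1, basal synthesis 0.5, basal
  stimulus `1e-3 * K_D`; the induced synthesis constant is solved so the
  *median* cell's pre-stimulus `P2` is exactly 1, keeping the variant
  comparable to the feedback-less switch. The basal protocol presumes the
  basal stimulus is sub-threshold; with this parameterization that holds for
  `p_scale` above roughly 0.1 (at very low resistance the median threshold
  drops as `p_scale^4` far below `1e-3 * K_D` and basal signaling would
  saturate), so the feedback-vs-no-feedback comparison is run at
  `p_scale = 0.3`, the low-resistance end of the meaningful window. There
  the mechanism is visible directly: sensitive cells accumulate phosphatase
  before stimulation, insensitive cells accumulate less, and both move
  toward a common threshold pinned near the basal operating point.
* **Feedforward comparison at `p_scale = 0.4`,** strength 100: intermediate
  resistance where the branch-less switch still responds
  (`X_max,4 = 0.62 > K_5 = 0.4` for the median cell) while the receptor
  branch is unsaturated at threshold, so both branches carry stimulus
  information and each enters the threshold as a square root.
* **Stability presets.** The oscillation scans use upstream feedback with
  gain 1e6, cooperativity 1-30, and `p_scale = 0.05` (low resistance) versus
  `p_scale = 10` (high resistance), the stimulus grid covering the dynamic
  range of the dose-response. The qualitative pattern is structural —
  sustained oscillations require the *long* (delayed) loop, high
  cooperativity and low resistance — but the precise onset cooperativity
  depends on the gain.

## Numerical conventions and degenerate inputs

Zero stimulus maps to the zero state without evaluating indeterminate
ratios; a Hill level with `K = 0` at zero input is rejected. Eigenvalue real
parts within 1e-8 of zero count as zero (the boundary of the sustained
class); the Jacobian uses central differences with steps scaled to the state
magnitude and is cross-checked against an exact hand-derived Jacobian of the
gradual cascade (bidiagonal lower-triangular, all eigenvalues real and
negative) and an independent finite-difference routine. For sustained
oscillators the dose-response summaries use the unique (unstable) fixed
point and the stability report carries the classification; limit-cycle
amplitudes and periods are out of scope.

## Problem sizes

The test suite runs 300-cell populations for variant comparisons (seed 7),
1000 cells for the gradual resistance sweep (13 log-spaced points over
`p_scale` in `[1e-3, 1e3]`), and 1e5 cells for Monte-Carlo checks of the
closed-form IQ ratios; the acceptance script re-derives the closed forms and
confirms each with a fresh 1e5-cell Monte-Carlo sample under the
caller-supplied seed. These sizes were chosen so quantile estimates are
stable to a few percent while the whole suite runs in about half a minute.

## Known limitations

The modularity assumption (each level an isolated Michaelis/Hill cycle)
ignores enzyme sequestration and retroactivity, which can feed activity
backwards through the cascade; ultrasensitivity is abstracted by Hill
functions rather than mechanistic multisite-phosphorylation or scaffold
models; and the per-figure parameter tables of the original experimental
literature are not modeled — sweeps target qualitative regimes
(trade-off, suppression, bimodality, oscillation windows), not
publication-exact curves.
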