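---
title: "Modeling antagomir control of TGF-beta/SMAD signaling in temporal lobe epilepsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antagomir control of TGF-beta/SMAD signaling in temporal lobe epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseize)
```

## The model

`mirseize` implements a dynamical model of seizure control in temporal lobe
epilepsy (TLE) through antagomir-mediated inhibition of three
seizure-modifying microRNAs. The intracellular network has eight species,
all measured in fold change (FC) over an untreated control baseline of 1.0:

* $A_1, A_2, A_3$ — the injected antagomirs (anti-miR-21a-5p,
  anti-miR-142a-5p, anti-miR-10a-5p), which only decay:
  $\dot A_i = -\mu_{A_i} A_i$;
* $R_1, R_2, R_3$ — the targeted miRNAs (miR-21a-5p, miR-142a-5p,
  miR-10a-5p), each with a constant source $\lambda_{R_i}$, an autocatalytic
  production term inhibited by its antagomir through a Hill-type
  denominator, and first-order decay:
  $\dot R_i = \lambda_{R_i} m(t) + k_{2i-1} k_{2i}^2 / (k_{2i}^2 +
  \sigma_i A_i^2) - \mu_{R_i} R_i$ with strengths
  $\sigma_i \in \{\alpha, \beta, \gamma\}$;
* $T$ — TGF-beta receptor-complex activity, inhibited jointly by the three
  miRNAs: $\dot T = \lambda_T + k_7 k_8^2 / (k_8^2 + \delta R_1^2 +
  \epsilon R_2^2 + \zeta R_3^2) - \mu_T T$;
* $S$ — SMAD transcriptional activity, additionally activated by TGF-beta:
  $\dot S = \lambda_S + \lambda T + k_9 k_{10}^2 / (k_{10}^2 + \eta R_1^2 +
  \theta R_2^2 + \kappa R_3^2) - \mu_S S$.

All inhibition enters through squares (Hill exponent 2, hard-coded): an
antagomir inhibits its own miRNA through $A_i^2$, and the miRNAs suppress
$T$ and $S$ through $R_1^2 + R_2^2 + R_3^2$ with per-miRNA strengths. Each
inhibition function is strictly increasing in every argument, which makes
the antagomir $\dashv$ miRNA $\dashv$ TGF-beta/SMAD cascade monotone: more
antagomir means less miRNA means more TGF-beta/SMAD signaling. Upregulated
$T$ and $S$ define the *anti-seizure* state; their suppression defines the
*seizure* state.

The timeline follows the underlying animal protocol: antagomirs are
administered from $t = -24$ h (the *control phase*), status epilepticus (SE)
is induced at $t = 0$, and the brain is analysed at $t = 24$ h (the *chronic
phase* is $[0, 24]$ h). Time is in hours throughout. The model assumes a
homogeneous intracellular distribution — there is no spatial component — and
lumps the individual mRNA/protein targets of each miRNA into the two
pathway-level variables $T$ and $S$.

A dimensional (concentration-unit) variant of the same system is provided,
together with the characteristic-scale map onto the dimensionless form
(`nondimensionalize()`). One subtlety: the map carries the
TGF-beta-to-SMAD activation rate over unchanged, which is exact only when
the TGF-beta and SMAD characteristic scales coincide; `nondimensionalize()`
warns when they differ.

### SE induction

The governing equations carry no explicit seizure-induction term, yet the
modeled miRNAs rise further once SE is induced. The package represents SE
induction minimally as a step multiplier $m(t)$ on the miRNA sources:
$m(t) = 1$ for $t < 0$ and `se_source_multiplier` (default 1.5) for
$t \ge 0$. This is the smallest mechanism consistent with
seizure-responsive miRNA up-regulation; it is a design choice of this
package, configurable in the parameter file.

## Parameters and calibration

All rates are per hour; sources, Hill constants and states are in FC-over-
control units; inhibition strengths are dimensionless. The shipped
calibrated set (`inst/extdata/params_calibrated.yaml`, also the package
default) was designed, once, to reproduce the published qualitative and
quantitative behavior:

* antagomir half-life of 12 h ($\mu_{A_i} = \ln 4 / 24 \approx 0.058$): a
  bolus decays to one quarter over the 24 h control phase, which is what
  places the bolus and infusion critical doses in a consistent ratio;
* control-arm miRNAs equilibrate slightly above baseline (1.2) before SE
  and rise to 1.35–1.55 after it; $T$ and $S$ equilibrate near 1.2 and fall
  below threshold only after SE induction;
* under a bolus of 1.0, miRNAs drop and $T$, $S$ roughly double during the
  control phase, then decline through the chronic phase while remaining
  anti-seizure;
* the antagomir-on-miRNA strengths are large ($\alpha = \beta = \gamma =
  60$) so that Hill sensitivity is concentrated at the *small residual*
  antagomir levels present at the analysis time point — that is what
  separates sustaining from non-sustaining doses at $t = 24$ h;
* the miRNA-on-$T$/$S$ strengths are deliberately unequal
  ($\zeta > \delta > \epsilon$, $\kappa > \eta > \theta$), reflecting the
  reported dominance of miR-10a-5p-mediated inhibition.

The phenotypic thresholds $th_T, th_S$ partition the $(T, S)$ plane:
anti-seizure iff both exceed their threshold, seizure iff both are strictly
below, and a *transitional* label otherwise (including exact equality; the
boundary is deliberately not anti-seizure). The threshold values are not
derivable from first principles, so `calibrate()` implies them from the
dynamics: each threshold is placed halfway between the chronic-phase
minimum of the weakest sustaining arm (bolus 1.0 / infusion 0.25) and that
of the strongest non-sustaining arm (bolus 0.6 / infusion 0.125). This
centres the critical doses inside the published brackets by construction.
A mean-based midpoint (between the two arms' chronic-phase averages) was
considered and rejected: with exponentially decaying antagomir the
treated arm's chronic mean sits far above its chronic minimum, and a
mean-midpoint threshold would classify even the full-dose arm as
switching. "Sustained" means anti-seizure at *every* chronic-phase grid
point, not a fraction — the strictest reading of keeping trajectories
confined.

## Dosing protocols

Four administration strategies are declarative `dosing_protocol()` objects:
scrambled control (no antagomir), bolus pre-injection (one impulse at the
window start), continuous infusion (levels clamped across the window, free
decay afterwards), and multiple dosage (the total dose split into $n$ equal
impulses at equal intervals, each adding to the current level). Impulses
are handled by stop–add–restart: integration halts at the event time, the
dose is added to the antagomir channels, and integration restarts — so $A$
jumps by exactly the impulse and $R$, $T$, $S$ are continuous across it.

The reference integrator is `deSolve::lsoda` (adaptive, implicit-capable;
rtol $10^{-8}$, atol $10^{-10}$, max step 0.1 h), integrating piecewise
between event boundaries (impulses, the infusion window edges, and $t = 0$
where the SE multiplier switches). The default output grid is 0.1 h on
$[-24, 24]$. States at an event time report the post-event value.

For the many-model-run stages (eFAST sweeps, repeated least-squares fits)
the package uses an internal fixed-step classic Runge–Kutta batch
integrator that propagates thousands of parameter sets simultaneously as
matrix rows and evaluates the antagomir channels analytically (they have
closed-form solutions under every protocol). At step 0.1 h it agrees with
the adaptive reference to better than $10^{-6}$ in every component (this
agreement is asserted in the test suite across all four protocol kinds).

## Equilibria and stability

With antagomir levels held constant the system is a feed-forward cascade,
so its equilibrium is available in closed form (`steady_state()`): each
$R_i^*$ from its own balance, then $T^*$, then $S^*$. Under the state
ordering $(A_1, A_2, A_3, R_1, R_2, R_3, T, S)$ the analytic Jacobian is
block lower-triangular, so its eigenvalues are exactly the negated decay
rates — all real and negative for any valid parameter set. Every
equilibrium is therefore a stable node, and the phase-plane projections
(`nullclines_2d()`, `vector_field_2d()`) show trajectories flowing into a
single attractor. The 2-D projections hold the six background variables
fixed, by default at their per-arm steady-state values (control arm
$A = 0$; antagomir arm at the level of interest); the stability tolerance
counts an eigenvalue real part below $-10^{-12}$ as negative.

## Sensitivity analysis

`run_efast()` implements the extended Fourier Amplitude Sensitivity Test:
each parameter is driven along a space-filling search curve
$x_j(s) = \mathrm{lo}_j + (\mathrm{hi}_j - \mathrm{lo}_j)\,(1/2 +
\arcsin(\sin(\omega_j s + \phi_j))/\pi)$ over $N$ equispaced $s \in
(-\pi, \pi]$. The focal parameter carries the largest frequency admitted by
the Nyquist condition $N \ge 2 M \omega_{\max} + 1$ (with $M = 4$
harmonics); the Fourier energy at its harmonics over the total spectral
energy gives the first-order index $S_1$, and one minus the energy below
$\omega_{\max}/2$ gives the total-order index $S_T$. Confidence intervals
are 2.5/97.5 percentiles over `NR = 5` resampling curves with fresh random
phases. Defaults analyse the nine inhibition strengths over
$[0.5\times, 1.5\times]$ their nominal values — a symmetric perturbation
band, since no published ranges exist — against each species at
$t = 24$ h, with $N = 1000$ samples per curve.

The complementary (non-focal) frequencies are distinct integers spread over
*half* the conventional $\omega_{\max}/(2M)$ bound. Both extremes fail:
clustering them at $1, 2, 3, \ldots$ makes pairs commensurate, so the
search curve degenerates and the variance estimate swings with the random
phases, while pushing them up to the full bound leaks their order-$M$
harmonics past the $\omega_{\max}/2$ cutoff and biases $S_T$ upward. The
half-bound spread keeps harmonics in-band with good space filling; the
suite validates the resulting indices against the closed-form variance
decompositions of an additive linear model and of the Ishigami function
(both at $N = 2049$) to within 0.03.

## Synthetic observations and parameter estimation

`generate_observations()` emulates the two-arm experimental readout:
species levels from the simulated scrambled-control and antagomir (bolus
1.0) arms at SE induction ($t = 0$) and Western-blot analysis
($t = 24$ h), in $\log_2$(FC over control), with i.i.d. Gaussian noise on
the $\log_2$ scale per replicate (default sd 0.1 — Western-blot fold
changes are conventionally log-normal; the default reflects a typical
blot-to-blot spread, as no published noise model exists). The generator
reproduces the hallmark pattern: all three miRNAs are lower at SE
induction under antagomir pre-injection than under scrambled control.

What the generator does *not* emulate: biological between-animal
variability (noise is i.i.d. across cells and replicates), normalisation
artefacts of reference-gene scaling, censoring or detection limits, and
any within-arm correlation. Passing recovery tests therefore demonstrate
estimator correctness under the stated noise model, not robustness to real
Western-blot systematics.

`fit_parameters()` minimises the summed squared $\log_2$ residuals over a
free subset — by default the miRNA sources, miRNA decay rates, the three
antagomir inhibition strengths and the SE multiplier — using multi-start
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, 8 starts by default,
box bounds at $[1/5, 5]\times$ nominal). Hill constants and the downstream
$T$/$S$ parameters stay frozen: two timepoints per arm cannot identify
them. With noise-free data the fit recovers the truth essentially exactly
(the generator and the objective share the same integrator, so the truth
is the exact global minimum).

### Identifiability limits

The two-arm, two-timepoint design carries limited information about some
free fields: each miRNA branch's (source, decay, inhibition-strength)
triple is sloppy. The antagomir strengths are identified mainly through the
small residual antagomir levels at 24 h — their effect at the injection
level is saturated, which is the same high-strength regime that separates
the sustaining from the non-sustaining doses — and the miRNA sources trade
off against the decay rates. A local Fisher-information (Cramér–Rao)
calculation at the calibrated set confirms the pattern: the SE multiplier
and the decay rates are well determined, the sources and antagomir
strengths are not, and this holds at the information bound, i.e. it is a
property of the design, not of the optimizer. Recovery to tight tolerances
for every field would require more timepoints or more arms than the
emulated experiment provides. The recovery study in the test suite and the
acceptance script (20 seeded datasets each) reports the per-field median
errors directly, making these limits visible rather than hiding them.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: 0.1–0.5 h output grids on
$[-24, 24]$ h; 100 random parameter sets for the eigenvalue identity; 50
random starts for the global-attractor check (500 h horizon); eFAST at
$N = 2049$ for the analytic benchmarks and $N = 1000$, $NR = 5$ for the
model sweeps (90,000 model evaluations per arm, batched); and a recovery
study of 20 datasets with 2 optimizer starts each. These sizes were chosen
so the whole suite completes in minutes on a single core while keeping
every Monte-Carlo margin comfortable.

## Known limitations

* The SE induction mechanism is a surrogate; the true biological form is
  unknown.
* Thresholds are calibrated, not measured; different parameter sets imply
  different thresholds.
* The model variants freeze masked miRNA branches at zero rather than
  removing them structurally, so all variants share one state layout.
* Post-SE ("post-treatment") dosing scenarios are expressible with the
  protocol machinery (windows with `window_start >= 0`) but no calibrated
  scenario is provided.
* No pharmacokinetic absorption/distribution compartments: doses act
  directly on intracerebral antagomir levels.
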