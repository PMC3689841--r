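---
title: "A mass-action model of VEGFR2 trafficking and Gab1/Gab2-dependent Akt activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of VEGFR2 trafficking and Gab1/Gab2-dependent Akt activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfr2akt)
```

## The biological system and the model

VEGF-A stimulates endothelial cells through the receptor tyrosine kinase
VEGFR2. Two Grb2-associated binder scaffolds compete downstream of the
activated receptor: Gab1 promotes Akt phosphorylation by recruiting PI3K,
while Gab2 — which binds the receptor complex only transiently —
antagonizes it. `vegfr2akt` implements a deterministic mass-action ODE
model of this system: 71 first- and second-order reactions over 14
proteins/lipids (VEGF, VEGFR2, Shc, Grb2, Gab1, Gab2, PI3K, Shp2, PIP2,
PIP3, PTEN, PDK1, Akt, PP2A) with 43 kinetic parameters, across a medium,
plasma-membrane (surface), early-endosome (internal), late-endosome
(degraded) and cytosol compartment.

The reaction network is organized in six modules:

1. **Receptor activation** — bivalent VEGF binds the pre-dimerized
   receptor pair; ligand stimulation is a step at $t = 0$ and binding is
   merged with autophosphorylation into a single reaction (no ramp, no
   explicit dimerization kinetics). Shc binds and is phosphorylated;
   Grb2 docks on phospho-Shc.
2. **Gab1 branch** — Gab1 binds Grb2, is phosphorylated, and recruits
   either PI3K (activating it in the same binding step) or Shp2
   (a competing dead-end in this model). The PI3K-loaded complex engages
   PIP2.
3. **Gab2 branch** — mirror-image recruitment with the same PI3K/Shp2
   kinetics, plus the hypothesized antagonistic step: free Shp2 attacks
   the PI3K-loaded Gab2 complex and strips `Gab2_p:PI3K_p` off the
   receptor, regenerating `R2_p:Shc_p:Grb2` and sequestering PI3K in a
   cytosolic `Shp2:Gab2_p:PI3K_p` complex (reaction 13). Its rate
   constant `k_2dShp2` is ten times the ordinary Shp2 association rate.
4. **Akt cascade** — the receptor-bound active PI3K converts PIP2 to
   PIP3 (reversed by PTEN, modeled with an explicit enzyme-substrate
   complex); PIP3 recruits PDK1; the PDK1:PIP3 complex phosphorylates Akt
   twice; PP2A dephosphorylates both forms, with doubly phosphorylated
   Akt activating PP2A through negative feedback, plus a weak basal PP2A
   activity. The feedback activation rate is deliberately gentle
   (`k_fb_PP2A` = 10^-7^ per molecule per second): stronger feedback at
   these pool sizes produces a spike–crash–rebound pAkt waveform,
   whereas the measured behavior this model represents is a single
   smooth rise-and-decay transient.
5. **Trafficking** — every one of the 14 receptor complexes
   internalizes and recycles reversibly (`kintf`/`krecf` for the free
   receptor, `kintb`/`krecb` for all ligated complexes alike) and
   internalized complexes degrade irreversibly (`kdegf`/`kdegb`).
   Degraded species keep their composition so that protein totals are
   conserved exactly.
6. **Ligand dissociation** — VEGF can leave any surface complex, upon
   which the whole complex disintegrates: the receptor returns to the
   free surface pool and every scaffold returns unphosphorylated to the
   cytosol. This is deliberately a maximal-reset convention and
   overstates the effect of dissociation. Plain unbinding from the bare
   phosphorylated receptor is reaction 71, grouped with the activation
   module.

Three conventions deserve emphasis because they are genuine design
choices rather than consequences of the biology:

* **Signaling reactions run at the surface only.** Internalized
  complexes keep their composition, recycle or degrade, but do not bind
  further cytosolic partners. Their profiles therefore mirror the
  surface pools (delayed and scaled by trafficking), which is also why
  global sensitivity indices of internal complexes equal their surface
  counterparts. Endosomal signaling chemistry is a known limitation.
* **Ligand dissociation is a surface process.** VEGF release back into
  the medium only makes physical sense at the plasma membrane; loss of
  endosomal ligand is subsumed in degradation.
* **Reaction 13 acts on the single PI3K-loaded Gab2 complex.** Because
  PI3K binding and activation are one step here, there is exactly one
  such complex, which resolves the otherwise ambiguous choice between
  `Gab2_p:PI3K` and `Gab2_p:PI3K_p` targets.

## Units, parameters and initial conditions

All state variables are in molecules/cell; first-order rate constants in
1/s, second-order in 1/((molecules/cell)·s); integration runs in seconds
and all interfaces report minutes. `default_parameters()` documents the
full set. Association rates were converted from molar units assuming a
1 pL cell volume (so 10^6^–10^7^ /M/s becomes 1.66×10^-6^–1.66×10^-5^
per molecule per second), which is where the recurring value 1.66e-6
comes from. The VEGF on-rate uses the per-cell medium volume instead
(about 1 nL, see below), and the dissociation rate is the typical
k~dV~ ≈ 10^-3^/s.

The Gab asymmetry is encoded exactly as the biology is described:
association and phosphorylation rates, and all PI3K/Shp2 kinetics, are
shared between Gab1 and Gab2; Gab2's receptor unbinding is ten times
faster (`kd_a_Gab2` = 0.1/s vs `kd_a_Gab1` = 0.01/s), and only Gab2 is
subject to the Shp2-mediated stripping reaction. Everything downstream —
the earlier, smaller Gab2 recruitment peak, the smaller Gab2 AUC, the
opposite knockdown responses — is emergent.

Basal pools: Gab1 = Gab2 = 10^5^/cell; Shp2 = 10^6^/cell with
PI3K/Shp2 = 0.1; receptor density 5000 dimers/cell (the middle of the
1000–10000 range the titration experiments explore); Shc, Grb2, Akt,
PDK1, PTEN, PP2A at 10^5^/cell and PIP2 at 5×10^5^/cell, typical of
mass-action signaling models of RTK pathways. The trafficking constants
(the class that is estimated from data rather than taken from prior
models, since published densitometry cannot be redistributed with this
package) were chosen once from
receptor-trafficking physiology: ligated complexes internalize about ten
times faster than free receptors (`kintb` = 2×10^-3^/s vs `kintf` =
2×10^-4^/s), recycling dominates degradation for both
(`krecf` = 1.5×10^-3^, `krecb` = 10^-2^, `kdegf` = 10^-4^,
`kdegb` = 10^-3^/s), placing roughly 85% of the receptor pool at the
surface at the internalization/recycling balance. All six lie within
the fitting bounds [10^-4^, 10^-1^] 1/s.

Because the originally fitted parameter values are not redistributable,
previously reported headline percentages (e.g. the precise knockdown
effect sizes) are not expected to be matched numerically; the package's
claims are the structural counts, the conservation laws, and the
qualitative/mechanistic behaviors, which are all tested.

### VEGF dose conversion

A dose in ng/ml is converted to a per-cell molecule count by assigning
each cell the medium column above its footprint: a cubic cell of volume
1 pL has a 100 µm² footprint, and a 10 mm medium depth then gives 1 nL
of medium per cell. With a 45 kDa molar mass (VEGF165 homodimer; the
choice is exposed in `default_geometry()` because reasonable values
range from 38 to 46 kDa), 50 ng/ml ≈ 6.7×10^5^ molecules/cell —
ligand in large excess over 5000 receptor dimers, as in typical culture
experiments.

## Pre-stimulus state

All complexes start at zero and free pools at their basal values, so the
VEGF-free system is quiescent except for one subtlety: first-order
degradation without synthesis admits no non-trivial true steady state.
`find_prestimulus_steady_state()` therefore returns the quasi-steady
state in which internalization balances recycling (about 12% of free
receptor resides in the endosomal pool, consistent with a non-negligible
internalized receptor fraction in unstimulated endothelial cells) and
reports the residual slow degradation drain explicitly. Because all
complexes are zero before stimulation, "difference from steady state"
and absolute concentrations coincide for every signaling species.

## Numerics

The ODE system (65 state variables) is integrated with `deSolve`'s
stiff-capable `lsoda` using the analytically compiled Jacobian
(`compile_rhs()` emits both the rate function and its exact Jacobian),
at rtol = 10^-8^ and atol = 10^-6^ molecules/cell by default, on a
1-minute output grid over 0–120 min. Conservation of every protein
(PIP2+PIP3 jointly, since they interconvert) is audited after every
simulation at 10^-6^ relative tolerance. Tiny negative undershoots are
clipped at zero; anything below −100·atol aborts. Halving rtol changes
reported observables by well under 0.1%, and scans reuse identical
solver settings so that control points are bit-identical to unperturbed
runs.

## Fitting the trafficking parameters

Densitometry time courses are semi-quantitative, so both the simulated
observable and the data are divided by their own maxima before the sum
of squared errors is computed — the objective is invariant to the
arbitrary intensity scale, and the implicit alignment assumption is that
the measured maximum approximates the true profile maximum.
`fit_multistart()` draws log-uniform random starts inside the
[10^-4^, 10^-1^] box (log-uniform because the box spans three decades),
refines each with a bounded Levenberg–Marquardt least-squares step in
log10-space, and discards infeasible runs — solver failure, a negativity
-guard trip, or a fitted observable that never rises above 1% of the
receptor population (the concrete reading of "physically unfeasible"
used here). The number of simultaneously fitted parameters must not
exceed the number of data points; with the default 8-point design all
six are fitted. Identifiability is limited by design of the experiment
(a single normalized profile constrains ratios and time scales more
than individual rates), which is why ensembles are summarized as
dot-lists with log-spaced histogram bins, means and medians rather than
point estimates.

## The synthetic-data generator

`generate_blot_dataset()` emulates the training data's statistical
structure: simulate the model at known "true" trafficking parameters,
sample the observable at 4–8 time points in 0–120 min (default the
8-point design 0, 2, 5, 10, 15, 30, 60, 120 min), apply multiplicative
log-normal noise (mean 1, CV default 0.1 — densitometry intensities are
positive and its error is closer to multiplicative than additive), and
rescale to an arbitrary maximum. It reproduces rise-and-decay transients
with an interior peak. What it deliberately does not emulate: blot
saturation and background, inter-experiment normalization drift, and
correlated errors between lanes — so a successful parameter recovery on
synthetic data demonstrates the machinery and the identifiability
structure, not that real western blots would constrain the parameters
equally well.

## eFAST

The extended Fourier Amplitude Sensitivity Test is implemented from
scratch. Each parameter is varied along the search curve
$x(s) = 1/2 + (1/\pi)\arcsin(\sin(\omega s + \phi))$ with a random phase
per resample curve; the parameter of interest gets the distinguished
frequency $\omega_{max} = \lfloor (N_s-1)/(2M) \rfloor$ and the
complementary set gets low frequencies no larger than
$\lfloor \omega_{max}/(2M) \rfloor$, so no complementary harmonic up to
order $M$ collides with the distinguished frequency. The first-order
index is the spectral power at the distinguished frequency's first $M$
harmonics over total power; the total index is one minus the power
fraction below $\omega_{max}/2$. One detail matters in practice: the
complementary frequencies are assigned from the *largest* admissible
values downward, because very low frequencies (1, 2) trace poorly
space-filling Lissajous curves whose single-curve total-variance
estimates fluctuate strongly between resamples; with the larger values
the Ishigami benchmark indices are stable to ±0.005 across resamples.
Defaults are $M = 4$, $N_r = 5$, $N_s = 257$ for function benchmarks.

Model analyses (`efast_on_model()`) perturb parameters log-uniformly
one decade either side of nominal, include a dummy parameter that is
sampled but never passed to the model (its index estimates the aliasing
noise floor), and use time-integrated (AUC) observables. For these the
package defaults are $N_s = 65$, $N_r = 2$ — the smallest design
satisfying the Nyquist condition at $M = 4$ — which keeps a full
module analysis (9 parameters × 2 curves × 65 samples ≈ 1200
simulations) around half a minute; indices reported in the tests use
these sizes.

Two caveats, established while validating against the published
qualitative claims about this pathway, are worth recording:

* In this topology, PI3K binding moves receptor complexes *within* the
  Gab1-bound aggregate rather than out of it, so the aggregate
  `R2p_Gab1` is dominated by its influx gate `k_a_Gab1` and nearly
  insensitive to `k_1_PI3K`. The previously reported ranking (PI3K
  association dominant) evidently refers to an output for which PI3K
  binding is a boundary — it does hold here for the specific complex
  `R2_p:Shc_p:Grb2:Gab1_p`. The acceptance test asserts the ranking on
  the aggregates and the Gab1 half is expected to differ.
* Enabling the ligand-dissociation module leaves the trafficking
  sensitivity balance essentially unchanged here (recycling indices move
  by < 0.02), rather than visibly shifting weight toward recycling; with
  dissociation confined to the surface and k~dV~ comparable to `kintb`,
  the disintegration loop is too weak to re-rank the trafficking
  parameters at these defaults.

## In-silico experiments

Knockdowns scale a protein's initial concentration by (1 − f) — the
natural siRNA analogue in a model without protein turnover. Percent
changes are computed on the peak of the named observable over the
simulated window. Degradation scans scale `kdegf` and `kdegb` jointly
(a proteasome-inhibition analogue); ratio scans reach each Gab1/Gab2 or
PI3K/Shp2 ratio both by varying the numerator and by varying the
denominator; titrations sweep VEGF dose and receptor density; the
`k_2dShp2` scan probes the Gab2-stripping rate. Under the defaults the
package reproduces, as emergent behavior: the log-linear Gab1 and linear
Gab2 knockdown dose–responses (R² > 0.95 both), the monotone
sustainment of pR2/pAkt under slowed degradation, the saturation of the
`k_2dShp2` effect (outputs change < 2% between 10^-3^ and 10^-2^), the
strict delay of the pR2 peak with falling VEGF dose, the pointwise
linear scaling of pR2 with receptor density, and a time-integrated
surface share of the signaling receptor pool of about 84% that varies
by < 5% across 5–500 ng/ml.

## Known limitations

No MAPK or PLCγ/PKC cross-talk, no VEGFR1/VEGFR3 or neuropilin
co-receptors, no site-specific phosphotyrosines, no receptor synthesis
or turnover, no endosomal signaling chemistry, and no stochasticity.
Quantitative agreement with previously reported headline percentages
depends on fitted parameter values that are not redistributable; where
those numbers are asserted in the acceptance suite they document the
divergence rather than being tuned toward it.
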