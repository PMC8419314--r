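---
title: "Concentration-independent profiling of sodium-channel inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-independent profiling of sodium-channel inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naveip)
```

## The problem

Small-molecule sodium-channel inhibitors act state-dependently: most bind
weakly to resting channels and tightly to inactivated ones, and they bind
and unbind on time scales comparable to channel gating itself. Any single
measure of "potency" therefore depends on the voltage history of the
membrane at the moment of measurement, and most primary observables (onset
rate, shift of half-inactivation voltage, delayed recovery) additionally
depend on the applied concentration. `naveip` implements an analysis that
removes the concentration axis: for every test pulse of a dynamic voltage
protocol a full concentration–inhibition curve is fitted, and the resulting
per-pulse IC50 — the *effective inhibitor potency* (EIP) — is followed as a
function of the conditioning history. The EIP fluctuates between two
compound-specific constants, the resting-state and inactivated-state
dissociation constants $K_R$ and $K_I$, and *how fast* it moves between
them is the compound's micro-kinetic fingerprint.

## The 17-pulse protocol

One sweep lasts 1 s (1 Hz stimulation) and contains 17 test pulses (5 ms at
−10 mV by default, from −130 mV holding), grouped into three sections:

* **SDO** (state-dependent onset), pulses #2–#5: depolarizing conditioning
  prepulses of 2.5, 7.5, 22.5 and 67.5 ms, each separated from its test
  pulse by a 2.5 ms hyperpolarizing gap. The EIP against conditioning
  duration shows how fast inhibition develops during depolarization.
* **RFI** (recovery from inactivation), pulses #6–#12 plus #1: test pulses
  preceded by hyperpolarizing gaps of 1, 2, 4, 8, 16, 32 and 64 ms; pulse
  #1, which follows the long inter-sweep holding period, contributes the
  nominal 498 ms point. The default gap→pulse assignment places the 1 ms
  gap before pulse #7 and is configurable (`rfi_gap_map`), because the gap
  order within the train is a protocol choice, not a scientific constraint.
* **SSI** (steady-state inactivation), pulses #12–#17: 50 ms equilibration
  at −130, −110, −100, −90, −80 and −70 mV before each test pulse. Only
  the −70 mV endpoint is fixed by the analysis (it defines $K_{app}$);
  intermediate levels and the equilibration time are configurable. 50 ms
  is a deliberate sweep-budget compromise and only approximates a true
  steady state; the bias affects intermediate SSI points, not the
  $K_R$/$K_I$ estimates.

With these defaults the scheduled segments occupy 572 ms and the sweep ends
with a 428 ms holding period. The RFI label of pulse #1 nevertheless uses
the nominal 498 ms inter-sweep value: for every compound whose micro-offset
is faster than a few hundred milliseconds the two are physically
indistinguishable, and a configuration whose explicit segments exceed the
sweep period is rejected rather than silently truncated. SDO prepulses are
independent (not cumulative); each is followed by the fixed gap and its
test pulse with no extra recovery interval, which is what keeps the sweep
inside its 1 s budget.

## The simulator

`navsim`-style ground truth comes from an eight-state Markov model: the
gating scheme C1 ⇌ C2 ⇌ O ⇌ I (plus an I ⇌ C1 recovery path) mirrored into
a drug-bound copy. All gating rates follow $r(V) = A e^{V/k_V}$. The
default "generic fast NaV" rate set is an engineering default, not a fit to
any particular channel; it was chosen so that at the protocol voltages
activation and inactivation complete within ~3 ms at −10 mV, recovery at
−130 mV has τ ≈ 3.5 ms, and the availability curve has its midpoint near
−72 mV (so that a realistic ~55% of channels are inactivated at −70 mV).

Binding follows the modulated-receptor picture: association at
`access_factor × k_on × conc` (per-state access factors implement
guarded-receptor access restrictions; default 1), dissociation at
`k_on × K` with $K = K_R$ for C1, C2, O and $K = K_I$ for I. Bound-state
gating rates are rescaled so every unbound↔bound four-state cycle is
microscopically reversible; the convention scales the rate leading *away*
from the higher-affinity side, so the bound inactivation backward rate
absorbs the full $K_R/K_I$ factor. This single choice reproduces the
canonical use-dependent phenomenology: bound channels recover slowly, and
at concentrations well above $K_I$ recovering channels rebind before they
can deactivate, making the *apparent* micro-offset concentration-dependent
and slower than the bare unbinding time constant $1/(k_{on} K_I)$. This is
also why micro-kinetics are not single exponentials and are summarized as
time *ranges* rather than time constants.

Within a sweep the generator is constant per segment; occupancies are
propagated by eigendecomposition (with a matrix-exponential fallback for
defective generators) and sampled on a 0.01 ms grid inside test pulses for
peak detection. Peak current is `-conductance_scale ×` the maximal
conducting-state occupancy (bound-open states conduct nothing by default;
a flag makes them conduct for pure-modulation scenarios). Across sweeps the
applied concentration relaxes exponentially toward each perfusion target
(`perfusion_tau_s`), and measured peaks receive multiplicative Gaussian
noise (default 2%) and optional linear rundown. Every stochastic path is
seeded; the same seed reproduces an experiment bitwise.

What the generator deliberately does *not* emulate: single-channel
stochasticity, temperature effects, series-resistance/capacitance artifacts
beyond a blanking window, and the membrane-partitioning/protonation
sub-steps of lipophilic drug access (lumped into `k_on`). Passing tests on
these simulations therefore validates the analysis pipeline's correctness
and identifiability, not the biological completeness of the channel model.

## The analysis chain

1. **Peaks** — `extract_peaks()` blanks 0.2 ms after each voltage step,
   fits a line to the immediately preceding baseline segment (for pulse #1,
   the terminal holding period, since recordings are gap-free), subtracts
   it, and takes the most negative value (inward convention). Published
   protocols rarely state their leak model; linear baseline
   extrapolation is a documented assumption, and `leak_mode = "none"` is
   available.
2. **Phases** — `annotate_phases()` tags the last 5 s of the drug-free
   block before each application as that application's control and the last
   5 s of the application as its drug window. Per-application controls
   cancel slow drift. The 5 s window is reused globally for symmetry.
3. **Ratios** — `make_ratio_table()` divides mean |drug| by mean |control|
   per pulse; ratios above 1 are kept in the table but clipped to zero
   inhibition for fitting.
4. **Hill fits** — `fit_hill()` fits
   $Inh = cc^{n_H}/(cc^{n_H} + IC_{50}^{n_H})$ in log-concentration space,
   unweighted, with $n_H \in [0.3, 4]$ and $IC_{50}$ within two decades of
   the tested range. Because the Hill equation is exactly linear on the
   logit scale, starting values come from a clipped logit regression; a
   coarse grid rescue guards against the optimizer sliding along the
   shallow (log IC50, nH) valley into a box bound, which otherwise happens
   precisely for the weakly-inhibited rested pulse that anchors $K_R$.
   Curves that never cross 5–95% inhibition are flagged `extrapolated`,
   never silently dropped; per-pulse $n_H$ is free (no global-$n_H$ mode).
5. **EIP curves** — `build_eip_curves()` arranges the 17 fits along the
   SDO/RFI/SSI abscissae from the protocol's condition map.
6. **Summary** — `estimate_affinities()` takes $K_R = IC_{50}(\#1)$ and
   inverts the classical mixed-population identity
   $1/K_{app} = (1-h)/K_R + h/K_I$ with $K_{app} = IC_{50}(\#17)$ and $h$
   the inactivated fraction measured as $1 - |\#17|/|\#1|$ in control.
   Each state class contributes to the apparent affinity in proportion to
   its occupancy; with this orientation the estimator recovers simulated
   ground truth without systematic bias (the orientation with swapped
   weights, which sometimes appears in print, biases $K_I$ low by roughly
   $(1-h)/h$). Limits: $h=1$ gives $K_I = K_{app}$; $h=0$ makes $K_I$
   unidentifiable (explicit error); a non-positive denominator flags
   inconsistent estimates rather than inventing a number.
7. **Kinetics** — `macro_offset_tau()` fits a single exponential to washout
   amplitudes (flagged `poorly_constrained` if the fitted τ exceeds twice
   the observation span; note that washing out from saturating
   concentrations genuinely inflates the amplitude time constant above the
   perfusion constant, because amplitude only tracks concentration linearly
   below $K$). `micro_range()` reduces an EIP section to the time interval
   between the 10% and 90% points of its cumulative log-IC50 progress,
   interpolated in log-time, with a flat-curve flag below a 1.5-fold span
   and a readability snap to the sampled-duration grid
   {0.1, 1, 2, 4, 10, 100, 500, 1000} ms (raw interpolated values are kept).
8. **Statistics** — `eip_change_test()` uses the Friedman test on log IC50
   with measurements as blocks (a blocked nonparametric test matches the
   replicate-by-pulse data structure without distributional assumptions),
   with a within-block permutation variant for small ensembles. At six
   blocks the chi-square approximation sits ~0.04 below the exact
   permutation p-value — the documented accuracy of the asymptotic variant.
   `power_detectable_effect()` is the standard noncentral-t two-sample
   power. `group_summary()` reports geometric mean/SD alongside arithmetic
   mean/SEM, and the $K_R/K_I$ ratio both as mean-of-ratios and
   ratio-of-means, since published tables are ambiguous on both points.
9. **QC** — `qc_filter()` applies the four ensemble exclusion rules
   (control amplitude < 2 nA; mean seal resistance < 80 MΩ — treating the
   "mOhm" seen in some sources as the obvious units slip; gradual seal loss
   > 20%; sudden amplitude drop with concurrent seal drop) and keeps the
   best six survivors by seal resistance and stability.
10. **Overlay** — `overlay_eip()` replays the SDO curve after each
    action-potential upstroke and the RFI curve after each repolarization
    (log-log interpolation), turning the two micro-kinetic curves into an
    EIP time course over a user-supplied spike train.

## Simulation presets and study conditions

Five mechanism presets span the kinetic space of well-characterized
inhibitors (`mechanism_preset()`): riluzole-like (strong state dependence,
~3 ms micro-offset), lidocaine-like (intermediate), benzocaine-like (very
fast), bupivacaine-like (very slow, shallow ratio) and a ttx-like
state-independent fast blocker parameterized by the published
outer-vestibule toxin affinities (0.028/0.017 µM). The association rate of
each preset is set through the inactivated-state unbinding time constant
$1/(k_{on} K_I)$, which is what actually clocks the EIP offset in this
model. Typical concentration sets (`preset_concentrations()`) are 3–4
log-spaced applications bracketing each compound's depolarized apparent
affinity, as in common experimental designs.

Validation studies in the test suite use 25-sweep perfusion blocks
(interleaved control/drug plus terminal washout, 1 Hz), 2% multiplicative
noise, 5 s analysis windows and six replicate "ensembles" per recovery
study; these sizes keep a full six-ensemble recovery study around half a
minute while leaving every window with five averaged sweeps, and they are
the conditions under which the documented tolerances (geometric-mean $K_R$
within ±30%, $K_I$ within ±25%, TTX-like EIP fold-range ≤ 2) were
established. The recovery scenario uses a 2 s perfusion constant so the
applied concentration fully equilibrates within each block; presets that
anchor realism to published washout constants (e.g. 13.6 s) need longer
blocks before the macro-offset fit is well constrained, and the fit says so
via its flag.

## Numerical choices and degenerate inputs

* Occupancy vectors are validated (non-negative, sum 1 within 1e−6) and
  renormalized after propagation; conservation holds to 1e−9 across whole
  sweeps.
* Generators are eigendecomposed once per (voltage, concentration) and
  reused; a reconstruction check (1e−8) triggers the expm fallback.
* Zero-duration propagation is the identity; zero concentration zeroes all
  binding rates exactly, so drug-free results are invariant to mechanism
  parameters up to eigensolver roundoff.
* One-way gating transitions between states of different bound affinity
  make cycle closure impossible and are rejected at matrix construction.
* Hill fits never fail on degenerate data: they fall back from LM to a
  grid+refine path and always return a flagged result; `at_bound` marks
  estimates pinned at the box constraints.
* Ties in the Friedman test use average ranks with the tie-corrected
  statistic; an all-tied matrix returns the null p-value 1.

## Known limitations

* The lumped two-affinity binding scheme cannot simultaneously reproduce a
  benzocaine-like compound's very fast escape *at concentrations far above
  $K_I$* (rebinding traps simulated channels); the under-detection artifact
  of the SDO section therefore manifests as an onset completed before the
  shortest prepulse rather than as gap-erased inhibition at high
  concentrations.
* $K_R$ rests on the weakly-inhibited rested pulse; with concentrations an
  order of magnitude below $K_R$ its per-measurement estimator is noisy
  (roughly ±2-fold at 2% amplitude noise), which is why compound-level
  reporting pools six ensembles geometrically.
* Micro-onset of fast compounds (offset ≲ 3 ms) completes before the
  shortest 2.5 ms conditioning pulse, so their SDO section is reported as
  flat ("no detectable micro-dynamics") — a protocol resolution limit, not
  an analysis failure.
* Intermediate SSI points inherit the 50 ms equilibration compromise and
  should not be read as true steady-state availability.
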