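---
title: "Models and methods: simulated sodium-channel recordings and the gating inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

navclamp studies how scorpion-venom peptides modify voltage-gated sodium
(Naᵥ) channels and neuronal firing. Because raw oocyte and snail-neuron
recordings of such experiments are rarely deposited, the package couples a
seeded generative model of the recordings to the complete analysis chain,
so that every estimator can be calibrated against known truth. This
vignette describes the models, the estimators, the numerical choices, and
what the calibrations do and do not demonstrate.

## The generative gating model

A channel population is summarised by `gating_params()`: maximal
conductance $G_{max}$, reversal potential $V_{rev}$, Boltzmann steady
states for the activation gate,

$$m_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2}^{act})/k_{act}}},$$

and for the inactivation (availability) gate,

$$h_\infty(V) = \frac{1}{1 + e^{(V - V_{1/2}^{inact})/k_{inact}}},$$

plus time constants: an activation tau (default 0.5 ms,
voltage-independent; recordings of this preparation do not constrain it,
so a single plausible value is used and `tau_act = 0` selects an
instantaneous-activation mode whose closed forms anchor the oracle tests),
fast and slow inactivation decay taus (defaults 1.5 and 8 ms, weights
0.8/0.2), a non-inactivating persistent fraction, and a recovery tau
(default 10 ms). The current during a step at voltage $V$ is

$$I(t) = G_{max}\,(V - V_{rev})\; m(t)^p \; \big[\pi + (1-\pi)h(t)\big],$$

with $\pi$ the persistent fraction and $p$ the activation-gate exponent.
The default $p = 1$ makes the Boltzmann fit of the peak conductance an
unbiased estimator of the generative midpoint and slope; $p = 2,3$ are
supported, but the apparent midpoint of $m_\infty^p$ is then displaced
positive relative to the generative one, which is why calibrations use
$p = 1$.

Two-component inactivation is modelled as a weighted sum of two
exponentials applied to the h-trajectory — the same functional family the
decay analysis fits — rather than a multi-state kinetic scheme. The
kinetic regime of the h gate is set by the epoch voltage: where
$h_\infty(V) < 0.5$ (depolarised) the fast/slow decay mixture applies,
where $h_\infty(V) \ge 0.5$ the single recovery tau applies. The regime
must depend on voltage, not on the direction of relaxation: at one test
potential every sweep must relax with the same time constants, whatever
availability it starts from.

Because commands are piecewise constant, the gate equations have exact
solutions within each epoch, and the voltage-clamp simulators evaluate
them analytically on the sample grid instead of stepping an ODE. This
makes the traces exact (grid refinement only adds sample points; peak
currents change by far less than 0.1 % when the rate doubles) and fast.
The current-clamp simulator cannot use closed forms — voltage is a state
variable there — and integrates $C\,dV/dt = -I_{Na} - I_K - I_{leak} +
I_{stim}$ with forward Euler at a fixed 0.025 ms step, aborting with a
diagnostic if the voltage leaves ±200 mV.

Recording noise is additive i.i.d. Gaussian, scaled to the maximum
absolute signal of the sweep family (default 1 %); the recordings do not
characterise their noise, so this is a declared convention. Sweeps are
independent — the seconds-long interstimulus intervals of the protocols
justify a full state reset between sweeps — except inside the two-pulse
recovery protocol, where the interpulse state is the measurand. Inward
current is negative; units are mV, ms, µS, and nA (µS × mV), which reads
as µA-scale traces for oocyte-sized conductances. Leak is not simulated:
the recordings subtract leak online (−P/4), so the generator produces
leak-free signals directly and the four-subpulse arithmetic is out of
scope.

Toxin exposure is a `toxin_effect()`: additive midpoint shifts,
multiplicative slope/conductance/tau scales, and a persistent-fraction
increment. This parameterisation expresses every effect class seen in the
experiments — alpha-like slowed or incomplete inactivation, beta-like
activation shifts, conductance depression, recovery deficits — as a
generative perturbation whose recovery the pipeline can be tested on.

### Default parameter choices

The Helix-style defaults (activation −25/5 mV, inactivation −35/6 mV,
reversal +50 mV) describe a molluscan Naᵥ1.7-like channel recorded from a
−50 mV holding potential. The inactivation midpoint matters most: at
−35 mV the resting availability at −50 mV is ~0.92, consistent with
recovery-from-inactivation curves that approach 100 % at this holding
potential, and a strong depressant-toxin shift of −19.4 mV still leaves
the displaced curve measurable above the −60 mV prepulse floor of the
protocol — both properties the emulated experiments evidently had. The
current-clamp fixture neuron (`neuron_params()`) adds a delayed-rectifier
potassium conductance and a leak around the same sodium model, tuned once
to rest stably near −60 mV (drift < 1 mV over 1 s) and to fire
repetitively at 12/24/32 Hz for 0.5/1.0/1.5 nA — rates typical of large
snail neurons — with firing graded down monotonically as the sodium
conductance is scaled away.

## The protocols

`protocol_preset()` encodes the stimulation programmes: oocyte
two-electrode voltage clamp (holding −90 mV; I-V: 50 ms steps −80…+65 mV
in 5 mV; SSI: 100 ms prepulses −80…0 mV then a test pulse to 0 mV) and
whole-cell snail-neuron patch (holding −50 mV; I-V: 200 ms steps
−60…+60 mV in 10 mV; SSI: 200 ms prepulses then 200 ms at −20 mV;
recovery: paired −20 mV pulses, interpulse 5–80 ms in 5 ms; current
clamp: 0.5/1.0/1.5 nA for 500 ms). Recovery pulses are 20 ms — long
enough to inactivate fully at the default taus, short enough to keep the
sweeps compact; published recovery protocols rarely state this duration.

## The inference chain

**Amplitude measurement.** The naive measurand — the raw peak of each
sweep — is biased two ways. First, by the time the activation gate opens,
part of the availability has already been lost, and the lost fraction
varies across voltage through $h_\infty(V)$; a Boltzmann fit of raw peak
conductance therefore mis-estimates the midpoint by of order 1 mV, which
is material when the quantity of interest is a few-mV displacement.
Second, picking the extremum of thousands of noisy samples is an
extreme-value statistic: at steps where the true current is near zero
(near $V_{rev}$) the "peak" is a ~4-sigma noise excursion.
`extract_amplitudes()` addresses both with the classical remedy,
back-extrapolation of the decay to the step onset, made stable by a
family-level fit: the two decay taus are shared across all sweeps of the
family (they are properties of the channel population, not of one sweep)
and optimised by variable projection — for candidate taus, each sweep's
fast/slow/steady amplitudes are a linear least-squares solve — after
which each sweep reports its fitted value extrapolated to onset. The fit
window starts 1.5 ms (three activation taus) after the step and spans
40 ms. Noise-dominated sweeps receive near-zero linear amplitudes rather
than extreme-value peaks. `extract_peaks()` (plain extrema with polarity,
blanking and an optional search window) remains available and is the
right tool for well-separated events such as the recovery pulse pairs.

**Conductance and activation fit.** `conductance()` applies
$g = I/(V - V_{rev})$, flagging (not dropping) points within an exclusion
window of the reversal potential, 1 mV by default. `estimate_vrev()`
interpolates the zero crossing of the I-V relation, falling back to the
full Boltzmann I-V fit when no crossing exists. `fit_activation()` fits
$g(V) = A/(1+e^{-(V-V_{1/2})/k})$ by bounded Levenberg–Marquardt with
five deterministic starts (midpoint at the interpolated 20/35/50/65/80 %
rise voltages), $k \in [0.5, 30]$ mV, lowest residual winning;
non-convergence and wrong-direction inputs return flagged, unconverged
objects rather than fabricated estimates. The composed `analyze_iv()`
widens the exclusion window to 5 mV (its reversal potential is itself an
estimate, so neighbouring points have unbounded relative error) and
weights the fit by $(V - V_{rev})^2$: conductance noise scales with
$1/|V - V_{rev}|$, so these weights restore ordinary least squares on the
current scale. Open probabilities are reported as $g/\hat A$ — the fitted
amplitude is robust to a noisy extreme point — with $g/\max g$ available
as an option.

**Steady-state inactivation.** All SSI test pulses run at one voltage, so
between sweeps the test-pulse kinetics are identical and the current at
any fixed time after onset is exactly affine in the prepulse-end
availability: $I = G h_\infty^{test}(1 - d) + G d\,h_{pre}$. The default
SSI measurand (`extract_ssi_levels()`) is therefore the mean current over
a fixed 2–6 ms window — past the activation settling, before the decay
completes — fitted with the floor-enabled Boltzmann
$y = c + A/(1+e^{(V-V_{1/2})/k})$, whose floor absorbs the affine
pedestal. This estimator is unbiased by construction and averages ~80
samples per point. It was chosen over per-sweep peaks because a strongly
left-shifted curve (a depressant toxin can displace the midpoint ~20 mV)
is truncated by the −60 mV prepulse floor, where a free-amplitude fit of
noisy peaks acquires a skew bias of about 1 mV along the
amplitude–midpoint ridge. The floor flag also serves its direct purpose:
channels with genuinely incomplete inactivation (an availability plateau
of ~10 % at depolarised prepulses) fit with $c > 0$ rather than a forced
zero. For paired recordings, `fit_inactivation(amplitude =)` can fix the
amplitude at the control cell's fitted value — the per-cell
normalisation convention — though the default pipeline does not need it.

**Maximal conductance.** `fit_iv_gmax()` fits the whole I-V relation with

$$I(V) = \frac{G_{max}(V - V_{rev})}{1 + e^{-z_{act}(V - V_{1/2})F/RT}},$$

$T = 294.15$ K (the middle of the 18–22 °C recording range), reporting
the equivalent slope $k_{equiv} = RT/(z_{act}F)$ alongside. Starts are
seeded from the observed zero crossing and ascending-limb slope over a
small grid of gating valences.

**Window current.** `window_area()` integrates the pointwise minimum of
the two normalised sigmoids (trapezoid rule, 0.1 mV grid) over the
protocol's voltage range, in percent·mV; the crossing voltage
$(V^{act}_{1/2} k_{inact} + V^{inact}_{1/2} k_{act})/(k_{act}+k_{inact})$
is exact. For a symmetric pair with equal $k$ the area is $2k\ln 2$ (in
probability·mV), the closed form the tests pin. Published window areas for this preparation (e.g. 9.4 falling to 4.3
under a depressant toxin) come without units or integration range, so
absolute agreement is not claimed — only
the qualitative behaviour (that such a shift pair more than halves the
area) is checked. Availability floors are excluded from the integrand:
with a floor the minimum no longer vanishes at depolarised voltages and
the "area" would grow without bound in the range.

**Decay kinetics.** `fit_decay()` fits
$a_f e^{-t/\tau_f} + a_s e^{-t/\tau_s} + c$ over a window, with a
deterministic tau start grid (rescaled with the window), post-fit
ordering so $\tau_f < \tau_s$ regardless of starts, and model selection
by small-sample-corrected AIC among constant, single- and two-exponential
models; the constant competitor keeps pure-noise windows from being
awarded spurious decay components, and a difference of 2 is required
before the richer model wins. The offset $c$ is free (no constraint is
imposed) and the window defaults to peak-to-step-end.
`persistent_fraction()` is the mean of the final 10 % of the step over
the peak.

**Recovery and firing.** `recovery_fractions()` pairs the two pulses per
sweep and reports peak₂/peak₁ per interpulse interval, optionally fitting
$a - (a - f_0)e^{-\Delta t/\tau}$. `detect_spikes()` scores a spike when
$dV/dt$ first reaches 10 mV/ms and the voltage attains 0 mV within 5 ms,
with a 2 ms refractory skip — a slope-plus-peak rule that is robust on
slow molluscan waveforms where a plain voltage crossing misfires; all
thresholds are arguments. Mean firing frequency is spike count over the
stimulus window in seconds: count-over-duration is defined for zero or
one spike and matches a frequency reported in Hz for a fixed 500 ms
injection, where inverse-mean-ISI is not.

**Paired statistics.** `paired_compare()` pre-tests differences with
Shapiro–Wilk at 0.05, then applies the paired t-test or the exact
Wilcoxon signed-rank accordingly; zero-spread differences are returned
flagged degenerate rather than as fake p-values. `adjust_pvalues()` wraps
Bonferroni and Benjamini–Hochberg. Voltage-wise model-based contrasts
(generalised additive location-scale models) are
out of scope; per-voltage paired tests with adjustment are the supported
route.

**Effect labels.** `build_condition_report()` reduces paired per-cell
summaries to displacement/ratio deltas and assigns a heuristic label
(alpha-like, beta-like-excitatory, beta-like-depressant, mixed, none)
from thresholds all exposed in `report_rules()`; the taxonomy is
interpretive, so the labels are deliberately configurable and carry no
acceptance weight.

## The structural interface stage

`read_structure()` parses PDB-format coordinates (fixed-column, via
bio3d) into a tidy atom table: waters out by default, alternate locations
keep blank/'A' with a first-present fallback for residues that have
neither, elements inferred from atom names where the element column is
blank. `find_contacts()` reports residue pairs with any cross-molecule
atom pair within 4.0 Å — polar and nonpolar alike, a pair whose closest
atoms are both carbon/sulfur classified nonpolar (hydrophobic) — using a
cutoff-sized cell grid that returns exactly the all-pairs answer (the
exhaustive scan is kept as a cross-check and the tests compare the two on
50 random complexes). `find_hbonds()` applies standard geometric criteria
(donor–acceptor ≤ 3.5 Å, hydrogen–acceptor ≤ 2.7 Å, angle ≥ 120°);
`report_all = TRUE` lists every candidate donor–acceptor pair to 5.5 Å
with its geometry and no judgement, reproducing the style of published
distance tables that include out-of-convention pairs (a reported
"hydrogen bond" at a 4.8 Å donor–acceptor distance fits no convention);
structures without hydrogens fall back, with a warning, to the
distance-only criterion. `find_salt_bridges()` pairs Lys/Arg/His
side-chain nitrogens with Asp/Glu/terminal oxygens within 4.0 Å.

Docking scores enter as a tidy (site, replicate, rank, energy) table in
arbitrary units, more negative meaning stronger predicted binding.
`best_energy_per_replicate()` takes the exact per-group minimum — the
highest-affinity pose of each run — and `site_stats()` applies one-way
ANOVA with Tukey's HSD and a PCA of the replicate-by-site matrix
(observations = replicates, variables = sites, centred, unscaled),
reporting variance fractions. Published per-site variance fractions depend on an unstated matrix
construction, so no particular value is targeted; the package's
construction is documented here instead.
`simulate_docking_scores()` generates replicate tables with known site
structure for calibration.

## Calibration experiments and what they show

`recover_shift()` and `recover_gmax_decrease()` run the full
simulate-then-analyse loop at the published effect sizes: six synthetic
cells per condition, 2 % trace noise (1 % for the conductance
experiment), seeded. With the estimators above, the recovered mean
displacements sit within ~0.1–0.5 mV of the injected values for
activation shifts of +3.94, −9.20 and −4.73 mV and inactivation shifts of
−19.36 and −6.31 mV, and a generative half-conductance condition is
recovered as a 50 ± 2 % fitted-Gmax decrease. Problem sizes (6 cells,
13–16 sweeps per family, 20 kHz sampling) were chosen to mirror the
experimental design while keeping a full calibration run around a minute.

These calibrations show that the inference chain is consistent for data
generated by its own model family — Boltzmann gating, mono-voltage taus,
additive Gaussian noise, perfect clamp. Real recordings violate all four
(voltage-dependent taus, series-resistance and space-clamp error,
correlated noise, rundown), so passing calibration bounds estimator bias
under ideal conditions; it does not certify accuracy on arbitrary real
data. The structural stage's calibrations are exact-geometry checks and
known-group-structure simulations; they do not validate any docking
scores themselves.

## Known limitations

No Markov channel schemes, temperature dependence, multi-compartment
neurons, calcium or synaptic currents; no liquid-junction or
series-resistance correction (command voltages are treated as exact); no
ABF binary I/O — the exchange format is delimited text with a JSON
sidecar; the current-clamp integrator is first-order (halving `dt_ms`
changes the fixture spike count not at all, but stiff parameter sets
should be checked); hydrophobic contacts are classified contacts, not an
independent detector; docking pose generation and binding free energies
are out of scope.
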