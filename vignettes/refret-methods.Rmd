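---
title: "refret: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{refret: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the kinetic and emission models behind the synthetic-trace generator, the
estimators in the inference chain, the numerical choices, and the points
where the design was genuinely open and a decision had to be made. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

# The measurement being modelled

A RecA filament on ssDNA is observed through single-molecule FRET between
a donor/acceptor dye pair. Two experimental geometries are modelled:

* **Nucleation geometry.** A short (21 nt) ssDNA tail accommodates one
  nucleation cluster and nothing more. Bare ssDNA is a flexible coil, so
  the dyes average to high FRET (E ≈ 0.7); a nucleated cluster stretches
  the tail and drops the signal to E ≈ 0.2. Both transitions appear as
  single steps at 0.1 s frame times, so the cluster (~6 monomers) is
  treated as binding and unbinding atomically.
* **5′-end geometry.** A long tail carries a stable filament; only the 5′
  disassembly end exchanges monomers. A dye pair spanning a 10-nt window
  at that end resolves zero, one or two bound monomers: states M0, M1, M2
  at E ≈ 0.7, 0.5, 0.3 (ΔE ≈ 0.2 per monomer). Two monomers, not the
  three that 10 nt could hold in principle, because the ss/dsDNA junction
  sterically blocks the third site; the package therefore hard-codes a
  three-state chain.

# Kinetic model (generator)

Both geometries are continuous-time Markov chains simulated exactly with
the Gillespie algorithm: the dwell in a state is exponential with the
state's total exit rate, and the next state is drawn proportionally to the
individual rates.

* Nucleation: `unbound → nucleated` at `k_nuc` (s⁻¹, at the experiment's
  fixed RecA concentration), `nucleated → unbound` at `k_disassembly`
  (s⁻¹). The concentration law of nucleation (plausibly high-order in
  [RecA] given the ~6-monomer cluster) is deliberately *not* built in:
  `k_nuc` is exposed directly and any concentration dependence is the
  caller's to impose.
* 5′-end: linear birth–death chain `M0 ⇌ M1 ⇌ M2`. Each binding step has
  rate `k_on·[RecA]` with a single `k_on` (µM⁻¹s⁻¹) shared by both steps
  (no statistical factor for landing sites — the experiment reports one
  binding constant per sequence), each dissociation step has rate `k_off`
  (s⁻¹). No direct `M0 ⇌ M2` transitions: single-monomer resolution.

Molecules in the 5′-end geometry start in a state drawn from the chain's
stationary distribution — recording starts on molecules already at steady
state with RecA in the chamber. Nucleation experiments start in `unbound`
(RecA is introduced to bare DNA).

# Emission model (generator)

Each latent path is rendered to donor/acceptor counts per frame:

* **Frame integration.** The noiseless frame FRET is the exact
  time-weighted mean of the state FRET levels over the frame, not a point
  sample. This reproduces the mid-frame-transition artifact (a frame
  halfway between two levels) that the HMM decoder must tolerate, and the
  tests assert exactness against a brute-force overlap oracle.
* **Channels.** Before bleaching, acceptor = `I·E + background`,
  donor = `I·(1 − E)`; Gaussian noise of s.d. `noise_sd` is added to each
  channel independently.
* **Acceptor photobleaching.** After an exponential time (rate
  `bleach_rate`) the acceptor emits only background and the donor recovers
  the full intensity — the apparent E ≈ 0 dark state of real traces. The
  frame containing the bleach instant is blended by its pre-bleach
  fraction. A configurable fraction of molecules is donor-only from the
  start (bleach time 0), producing the zero peak of population histograms.
  Donor bleaching simply ends a trace and is represented by finite trace
  duration rather than modelled separately.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| frame time | 0.1 s | the assay's typical camera integration time |
| FRET levels | 0.7/0.5/0.3 (M0/M1/M2); 0.7/0.2 (nucleation) | the reported population positions |
| total intensity | 500 counts | typical EMCCD counts for Cy3/Cy5 at these powers |
| noise s.d. | 25 counts | gives E-noise ≈ 0.05, matching the visible width of real FRET populations |
| bleach rate | 0.005 s⁻¹ | mean acceptor survival 200 s, typical for Cy5 under oxygen scavenging |
| donor-only fraction | 0.10 | typical incomplete-labelling fraction; also the documented zero-peak level |
| `k_on`, `k_off` | 0.2 µM⁻¹s⁻¹, 0.2 s⁻¹ | near the critical concentration at 1 µM RecA, giving uniform M0/M1/M2 occupancy and all four transition classes |
| `k_nuc`, `k_disassembly` | 0.01 s⁻¹, 0.05 s⁻¹ | events every ~100 s of unbound time with ~20 s bound dwells, the documented nucleation scale |
| [RecA] | 1 µM | the assay's standard (and near-physiological) concentration |

These are the stated world; they were chosen once and are not tuned
against test outcomes.

## What a green test does and does not establish

The generator emulates: Markovian two- and three-state dynamics,
exponential dwells, frame integration, additive Gaussian channel noise,
single-step acceptor bleaching, donor-only molecules, and
molecule-to-molecule Poisson variability in event counts. It does **not**
emulate: dye blinking, spectral crosstalk or gamma-factor asymmetry,
intensity heterogeneity between molecules, baseline drift, non-Markovian
(e.g. multi-exponential) dwell mixtures, secondary-structure artifacts of
G-rich sequences, or any spatial detail of the tail beyond the two-site
probe window. Parameter recovery on synthetic data therefore validates the
estimators under the stated noise model — it cannot certify them against
photophysics the model omits.

# Inference chain

## FRET and histograms

`compute_fret()` uses the proximity ratio `E = I_A/(I_A + I_D)` with no
gamma/crosstalk correction, because the modelled experiment reports
apparent E levels (0.2–0.7) without corrections. Frames with non-positive
total intensity are flagged invalid and bridged by the decoder. E is
clamped to [−0.1, 1.1] to tame noise outliers.

Per-molecule values are means of the first 10 valid frames (histograms of
initial states); traces shorter than that are excluded with a warning and
counted. Histograms use 0.02-wide bins on [0, 1] (50 bins, the standard
scale for smFRET histograms; configurable) with out-of-range values
clipped to the edge bins.

## Gaussian mixture fits

Population decomposition is least-squares fitting of a sum of Gaussians to
the bin counts — mirroring how such histograms are fitted in practice —
rather than a per-molecule likelihood model. Numerical choices:

* counts are normalized to a maximum of 1 so amplitude and position
  parameters share a scale; the box-constrained quasi-Newton (`nlminb`)
  gets an **analytic gradient** (first-10-frame averaging produces
  populations narrower than a bin, a badly conditioned valley where
  numeric gradients stall);
* initialization is deterministic: component means seed at the
  histogram's `n` tallest local maxima (excluding E < 0.15 when a zero
  peak is requested), falling back to equal spacing over the occupied
  range; s.d.s start at 0.05;
* the donor-only zero peak is pinned at E = 0 with free amplitude and
  s.d. (bounded at 0.2). Whether the original analysis constrained it is
  unknowable from the published material, so the pin is a documented,
  configurable choice;
* component weights are areas **truncated to [0, 1]** so the
  half-truncated zero peak is not double-counted; weights sum to 1
  including the zero peak; components are reported sorted by mean;
* non-convergence is a hard error with the optimizer's diagnostics
  ("false/singular convergence" at a box constraint is accepted but
  flagged `weak_convergence`). There is no silent fallback.

## HMM idealization

A maximum-likelihood Gaussian-emission HMM (pooled Baum–Welch, per-trace
Viterbi) rather than variational-Bayes model selection: the state count is
fixed by the experiment design (2 for nucleation, 3 for end dynamics), so
n_states is an input, not something to infer. One model is trained per
condition on all its traces (matching one TDP per condition), then each
trace is decoded separately.

* Initialization is deterministic: user-supplied means (e.g. from the
  mixture fit), else the pooled data's `(k − ½)/K` quantiles; s.d. 0.05;
  sticky transitions (0.95 self); uniform initial distribution.
* The EM log-likelihood is asserted non-decreasing at every iteration;
  convergence at relative tolerance 1e-6 or 100 iterations.
* Emission s.d.s are floored at 1e-3 and flagged when the floor binds
  (degenerate one-state data fitted with two states).
* Viterbi ties break toward the lower state index (ascending scan with
  strict `>`); the tests verify the decoder against brute-force
  enumeration of all paths.
* Invalid frames carry a flat emission term, so the decoder bridges them.
* After fitting, states are relabelled in ascending order of emission
  mean, making state identities stable across runs.
* Single-frame segments are retained — at 0.1 s resolution they are real
  events, not noise; a minimum-dwell filter would bias `k_off` downward.

Photobleach truncation precedes all kinetics: the trace is cut at the
first run of ≥ 5 frames below E = 0.1, which is the package's
operationalization of excluding the acceptor-dark E ≈ 0 state from rate
calculations. Three-state fits on truncated traces then need no explicit
dark state.

## Dwells, rates, TDPs

* **Censoring.** The first and last decoded segments of every trace are
  flagged censored (cut by the observation window or bleaching) and
  excluded from exponential lifetime fits, avoiding window-truncation
  bias. The exponential MLE is the sample mean of uncensored dwells with
  s.e. `τ/√n`; an optional left-truncation correction (`τ = mean − t_min`)
  is off by default. The minimum dwell count is an argument (default 5).
* **Rates.** The exact CTMC estimator: transitions counted over the
  occupancy time of the source state, `k = N/T`, pooling M0→M1 with M1→M2
  (divided by [RecA]) for `k_on` and M1→M0 with M2→M1 for `k_off`. All
  decoded occupancy time enters the denominator, censored or not — the
  N/T estimator is consistent as is, whereas dropping censored dwell time
  while keeping the transitions observed at their ends would bias rates
  upward. (Dark-state time never enters: it was truncated upstream.)
  Errors are counting statistics (`rate/√N`); bootstrap alternatives were
  deemed unnecessary for the package's validation purposes. Decoded
  non-adjacent jumps (M0↔M2), which the physical chain forbids, are
  counted, reported (`n_skipped`) and excluded from the pooled rates.
* **Nucleation frequency.** The published material does not fix the
  normalization of "nucleation frequency"; the package defines
  `f_nuc = (# unbound→nucleated events) / (total observed unbound time)`,
  pooled over molecules, with the raw event count always reported
  alongside. This makes `f_nuc` estimate `k_nuc` directly, so planted and
  recovered values are commensurable.
* **TDPs.** Transition coordinates are the decoded states' emission means,
  not raw frame values — this gives the sharp four-peak structure of an
  idealized transition map. Peaks are connected clusters (8-neighbour
  adjacency) of occupied bins holding at least 2% of all transitions; the
  threshold exists because rare mis-decoded non-adjacent jumps would
  otherwise count as extra "peaks".

## Growth rate and correlations

`growth_rate()` returns `k_on·[RecA] − k_off` (positive = net growth; the
same difference is often quoted with opposite sign as a shrinkage rate —
only the sign convention differs and it is documented). It is strictly
increasing in concentration for `k_on > 0` and crosses zero exactly at the
critical concentration `k_off/k_on`.

`correlate_rates()` reports the squared Pearson correlation of
label-matched condition pairs with the least-squares line — the standard
reading of a "correlation plot with R²" when no other definition is
given. Unweighted by default; weights are accepted. Two shared labels give
R² = 1 by construction and are flagged degenerate.

# The pipeline's stated world

`default_pipeline_config()` plants: five 5′-end sequence conditions whose
`k_off` is proportional to a shipped **synthetic** ATPase table
(`inst/extdata/atpase_rates_synthetic.csv` — no per-sequence ATPase
numbers were ever published for this assay; the table only mirrors the
qualitative ordering, TGG slowest) with weakly varying `k_on`; and six
nucleation conditions in which longer cluster lifetimes co-occur with
higher nucleation frequencies, the reported correlation structure.
Pipeline runs are deterministic given the config seed: every condition
(and every trace within it) receives a derived substream.

# Known limitations

* Rate recovery through the HMM carries a small systematic underestimate
  (missed sub-frame dwells and transition-frame blurring); the end-to-end
  acceptance bound (20%) absorbs it, and the estimator itself is verified
  unbiased on ground-truth paths.
* The mixture fit models clipped edge bins imperfectly (the zero peak's
  negative-E mass piles into the first bin); truncated-area weights keep
  the weight estimate within its documented ±0.03.
* Dwell-based lifetime fits need enough uncensored dwells; conditions with
  lifetimes comparable to the trace length lose most dwells to censoring
  and report wide errors rather than silently biased values.
* The CTMC generator cannot represent cooperative or history-dependent
  kinetics; sequence effects enter only through the planted rate values.
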