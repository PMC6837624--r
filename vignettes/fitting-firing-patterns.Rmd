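---
title: "Fitting Izhikevich models to firing-pattern phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Izhikevich models to firing-pattern phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izhifit)
```

## The problem

Hippocampal neuron types are distinguished not only by morphology but by
their *firing-pattern phenotypes*: the classes of somatic spike patterns a
neuron produces under different step currents, together with quantitative
features of those patterns. `izhifit` automates the construction of simple
phenomenological neuron models that reproduce such phenotypes: it simulates
candidate models, extracts spike-pattern features, classifies responses into
the firing-pattern taxonomy used by Hippocampome.org, scores candidates with
a feature-weighted error, and searches parameter space with an evolutionary
algorithm (EA). Compact multi-compartment extensions (up to four electrically
coupled compartments) add a spatial context for synaptic integration while
keeping the somatic compartment in charge of the intrinsic dynamics.

## The model

Each compartment follows the nine-parameter Izhikevich formulation

$$C\,\dot V = k\,(V - V_r)(V - V_t) - U + I,\qquad
  \dot U = a\,\bigl(b\,(V - V_r) - U\bigr),$$

with the reset rule: when $V \ge V_{peak}$, a spike is recorded,
$V \leftarrow V_{min}$ and $U \leftarrow U + d$. Parameters carry their usual
units (pF, pA/mV², mV, ms⁻¹, nS, pA). The sign of $b$ separates integrators
($b<0$) from resonators ($b>0$); only resonators can produce rebound spikes
after release from hyperpolarization, a fact the test suite verifies across a
random parameter sweep.

Compartments are joined by asymmetric resistive coupling: for an edge with
strength $G$ and asymmetry $P$,
$I_{prox} = G P (V_{prox}-V_{dist})$ and
$I_{dist} = G(1-P)(V_{dist}-V_{prox})$, each subtracted from its
compartment's current balance. $G P$ is the forward (dendrite-to-soma)
strength; $P < 0.5$ therefore encodes the weaker-toward-the-soma coupling
typical of the reconstructed electrotonic profiles these compact models
emulate. All compartments share $V_r$; every other parameter is free per
compartment, so each added compartment contributes ten open parameters
(eight intrinsic plus $G$ and $P$).

### Numerics

Integration is forward Euler at a fixed `dt = 0.1` ms (exposed everywhere).
The integrator is deliberately simple: the reset rule makes the vector field
discontinuous, so a high-order adaptive scheme buys little, and the
acceptance suite checks that halving `dt` moves the spike times of the
canonical regular-spiking run by less than 1 ms and that spike counts match
an independent high-resolution reference integration. Spikes are stamped at
the first step whose updated $V$ reaches $V_{peak}$; the stored series shows
$V_{min}$ at that step, so the reset contract can be asserted directly on
the output. Simulations start at $(V_r, 0)$ with a 100 ms pre-stimulus
settling window. A non-finite state (possible under the EA's unbounded
mutation) aborts the simulation with a diagnostic; the search treats such
genomes as maximally unfit.

Synapses, where probes need them, are instantaneous-rise single-exponential
AMPA-like conductances (decay 5 ms, reversal 0 mV, conductance increment
`weight × 0.1 nS × n_synapses`, weight 10 by convention). These constants
are declared defaults, not measurements, and all are configurable.

## Features and classification

From a spike-time list and its stimulus, `extract_features()` computes the
first-spike latency (*fsl*), the inter-spike intervals and their count
(*nISIs*), the post-spike silence (*pss*), the burst structure (burst widths
*bw*, post-burst intervals *pbi*, burst count, intra-burst ISI counts), the
delay factor (*fsl* over the mean of the first two ISIs), and the adaptation
magnitude *sfa*. Undefined quantities stay `NA`; a response with fewer than
two spikes is never classified. Spikes after stimulus offset (e.g. rebound
spikes) are not part of the pattern.

The published classification protocol defers several numeric criteria to its
supplementary material; this package re-implements the rules
equivalently-in-spirit with declared, configurable cutoffs
(`class_thresholds()`):

* **sfa definition.** The protocol's exact formula is not printed; we adopt
  the pairwise-normalized index
  $\mathrm{sfa} = \langle (ISI_{i+1}-ISI_i)/(ISI_{i+1}+ISI_i)\rangle$, which
  is zero for periodic trains, positive under adaptation, and scale
  invariant. Fitting targets and verification use the same definition, so
  fit/verify consistency holds regardless of the choice.
* **Delay (D).** Delay factor ≥ 2.
* **Adaptation (ASP/RASP).** A sustained trend is an OLS slope of ISI
  against index significant at α = 0.05; a rapid component requires the
  pairwise index over the first 2–3 ISIs to reach 0.1 while the remainder
  stays below a quarter of it. Both significant gives the multi-transient
  `RASP.ASP.`.
* **Bursts (TSTUT/TSWB/PSTUT/PSWB).** Clusters are split at ISIs exceeding
  3× a robust intra-cluster interval *and* 3× the neighbouring ISI — the
  second condition keeps smoothly adapting trains from being split at their
  own lengthening tails. Clustering that persists into the second half of
  the response is persistent (P-), clustering confined to the onset is
  transient (T-); a lone onset cluster followed by dominant silence is also
  transient. Slow-wave bursting (SWB) instead of stuttering (STUT) is
  selected by a slow-AHP flag, which can be supplied per trace or derived
  from the voltage minimum after a burst dropping ≥ 2 mV below the
  pre-stimulus baseline (the AHP itself is not observable from spike times).
* **Steady state.** Silence (SLN) when `pss > 2 × max(ISI)`; non-adapting
  spiking (NASP) when uninterrupted spiking shows no significant trend. A
  pattern whose stimulus ends mid-transient gets an incomplete label with a
  trailing dot.

The classifier is total and deterministic for any train with at least two
spikes, and labels round-trip through the dot-notation parser.

## The objective

For a target pattern with feature set $S$ (spiking classes:
*fsl, pss, sfa, nISIs*; bursting/stuttering classes: *fsl, pss, bw, pbi,
n_bursts, b_nISIs*) the error is

$$\mathrm{error} = \sum_{f \in S} W_f \cdot \ln\!\bigl(1 + |exp_f -
model_f|\bigr),$$

with natural logarithm and the unit convention fixed (ms, nA, mV): the log
makes the convention load-bearing, so it is asserted at the interface.
List-valued features are compared element-wise after zero-padding, so
missing or extra bursts are penalized by their full magnitude; an undefined
model feature draws a large finite penalty. During the search the weights
$W_f$ are set dynamically by comparing the target class with the model's
current class: features whose defining taxonomy element mismatches get their
base weight multiplied by 10 (the mechanism is published, the constant is
ours). The base weight of *sfa* defaults to 50 because its natural scale
(0.01–0.2) would otherwise vanish next to millisecond-scale features inside
the log, and the integer counts (*nISIs*, *n_bursts*) default to weight 10
because acceptance requires them exactly — a one-off count must cost more
than a marginal *sfa* error, or selection trades the count away. Class
mismatch and a failed rebound requirement each add a flat penalty of 20,
large enough that a well-fitting model of the wrong class never wins. All
of these constants are `ea_config()` knobs.

Compact multi-compartment models additionally pay four constraint errors per
dendritic compartment, each zero exactly when its constraint holds and
continuous at the boundary: dendritic rheobase at least somatic (decoupled
probes), dendritic voltage deflection at least somatic in magnitude,
forward spike-propagation ratio $R = 1$, and somatic EPSP amplitude for a
single dendritic synapse inside $[0.1, 0.9]$ mV.

## The search

`fit_phenotype()` runs a generational EA: tournament selection (size 3),
blend crossover (probability 0.7, α = 0.5), Gaussian mutation (per-gene
probability 0.25, s.d. 10% of the initialization-box width), one elite, and
a small immigrant fraction (8% fresh box draws per generation) against
premature convergence. The operator constants are not published; they live
in `ea_config()`. The population (120 for single-class phenotypes, 240 for
complex ones) is initialized from per-class subregion boxes — the published
subregions are not tabulated, so `default_class_boxes()` records boxes
derived with this package's own machinery: first-guess boxes from parameter
sweeps, and, for the adapting family, a refinement to the envelope of
accepted models from this package's own earlier fits (re-seeding subregions
from prior search runs is exactly how the published workflow bootstraps its
own initialization; sustained adaptation turns out to live at very slow
recovery rates, $a \sim 10^{-4}..3\times10^{-3}$ ms⁻¹, with small reset
increments). Initial draws are screened for viability — a candidate must
fire at least two spikes at the weakest target current (up to 20 redraws) —
so the search starts from excitability-compatible material. Mutation is
unbounded: only the physical invariants ($C, k > 0$;
$V_r < V_t < V_{peak}$; $V_{min} < V_{peak}$; $0 \le P \le 1$) are
repaired, so the search can leave the boxes. Every 20 generations (and with
150 Nelder-Mead iterations) the incumbent best genome is refined locally
against the *acceptance margin* — each feature's discrepancy in units of
its tolerance, zero inside the acceptance region — a memetic step that
pulls near-misses over the acceptance boundary; the polished genome
re-enters the population. When a spec requires
rebound spiking, the recovery-sensitivity gene $b$ is seeded in the
resonator range, since $b > 0$ is necessary for rebound; specs with a
rebound requirement add a fixed penalty when the model fails to rebound,
and class mismatch adds a fixed penalty on top of the boosted weights —
both our constants, both configurable. Unknown experimental amplitudes
('*' in published figures) are searched as extra genes inside their
declared bracket.

A model is **accepted** only if every pattern's class matches the target
(with the single published exception: a `RASP.ASP.` target may be satisfied
by `RASP.NASP` in single-compartment models), every quantitative target
feature lies within tolerance — counts exact, times within 10% or 5 ms,
*sfa* within 0.01 (declared, configurable) — the rebound requirement holds,
and, for multi-compartment layouts, all four constraint errors are exactly
zero under full-precision re-probing. All accepted genomes ever evaluated
form the model cloud; every member re-verifies from scratch.

## What the synthetic generator emulates — and what it does not

`synth_spec()` turns a known model into a fitting target by simulating,
extracting features and classifying — the generating model passes
acceptance by construction, giving ground-truthed recovery problems that
exercise every module at once. `family_exemplars()` records one such
generator per family (non-adapting, adapting, delayed, transient slow-wave
bursting, persistent stuttering), chosen from the subregion sweeps with
moderate spike counts so that exact ISI-count recovery is a meaningful but
bounded challenge. These fixtures emulate clean, stationary, noise-free
responses: real recordings add spike-shape variability, trial-to-trial
noise, drift and artifacts that this pipeline deliberately does not model
(it classifies clean spike-time lists only). Passing the recovery suite
therefore shows the search machinery works, not that experimental traces of
arbitrary quality can be fitted.

The built-in reference targets (`hippocampome_phenotypes()`) transcribe six
published exemplar phenotypes. Stimulus durations are not printed with the
source traces (calibration bars only); all fixtures adopt a 1000 ms step
with 100 ms onset. For the DG Total Molecular Layer entry both the
experimental feature values and the slightly different published model
constraints are stored; the fit targets the model constraints.

## Association statistics

Relations between fitted parameters and categorical knowledge are screened
with Barnard's unconditional exact test for 2×2 tables: columns are treated
as independent binomial samples (only the group margin is fixed, the
property that gives the test its power advantage), the statistic is the
pooled Wald z (the published work does not name the variant), two-sided by
absolute value, maximized over a nuisance-probability grid of step 0.001.
Refining the grid can only raise the p-value, and the implementation matches
an exhaustive-enumeration oracle to the grid resolution on all small-margin
tables. Continuous parameters are encoded by sign or by tertiles (top third
"high", bottom third "low", middle dropped; boundary ties broken by
first-occurrence rank). Multiplicity is handled by Benjamini–Hochberg
FDR control, conventionally at 0.25 for these screens (0.05 for strict
significance). The published 198-correlation screen itself needs the full
knowledge-base property matrix and is out of scope; the machinery is
exercised on synthetic tables.

## Problem sizes and limitations

The worked examples fit the DG Total Molecular Layer phenotype (three
adapting patterns, ISI counts 5/9/19) and the CA1 Trilaminar phenotype
(adapting-then-silent, 22 spikes with *sfa* 0.038, rebound at −0.1 nA) with
population 120–240 over at most 150 generations, a few minutes each on one
CPU; the five-family recovery suite and the two-compartment constraint fit
use populations of 120 over 40–60 generations. Known limitations: the
classifier's numeric cutoffs are declared stand-ins for the published
protocol's supplementary criteria; the EA is stochastic, so specific
published parameter values are not reproduced (only the phenotypes are);
back-propagating spike amplitudes use the $\max(V) - V_{min}$ convention
and show no activity-dependent attenuation; and the error function's unit
convention is fixed rather than dimensionless.
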