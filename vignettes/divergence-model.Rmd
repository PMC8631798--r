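---
title: "Estimating true divergence rates from dual-colour rabies tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating true divergence rates from dual-colour rabies tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtrace)
```

## The double-infection model

Dual-colour monosynaptic tracing injects two ΔG-rabies viruses into two
muscles. One retrograde trans-synaptic jump from the primarily infected
motoneurons labels the premotor interneurons of each pool; a neuron
contacting both pools ("divergent") can end up carrying both fluorophores.
The per-jump transfer efficiency $e$ — the probability that a virus crosses a
given premotor→motoneuron synapse and labels the presynaptic cell — is well
below 1 (for the SADB19 strain an upper bound of 0.25 is commonly assumed),
so double labelling is a stochastic undercount of divergence.

The model makes one simplifying assumption: transfer events are equally
efficient and mutually independent across synapses and regions. Then, for a
population with true divergent fraction $d$:

* a non-divergent neuron is labelled with probability $e$;
* a divergent neuron is double-labelled with probability $e^2$ and labelled
  at all with probability $2e - e^2$.

The observed rate — double-labelled over labelled —

$$r = \frac{d\,e}{1 + d\,(1-e)},$$

is strictly increasing in both arguments, bounded by
$r \le \min(d,\, e/(2-e))$, and algebraically invertible:

$$d = \frac{r}{e - r\,(1-e)}.$$

`observed_rate()` and `true_rate()` implement the pair; the package treats
the closed form as primary and keeps the Monte Carlo forward simulation
(`mc_observed_rate()`) as an independent cross-check, since the two must
agree within simulation error everywhere. At $e = 0.25$ an observed
$r = 0.04$ inverts to $d = 0.1\overline{81}$ — the 4% ↔ 18% anchor that the
test suite pins to 12 decimal digits of round-trip identity on a dense
$(d, e)$ grid.

### Feasibility and the implied minimum efficiency

No true rate in $[0,1]$ can produce an observed rate at or above the ceiling
$r_{\max} = e/(2-e)$ (0.143 at $e = 0.25$). `true_rate()` raises a typed
infeasibility error there — within $10^{-9}$ of the ceiling, to avoid the
numerical blow-up of the inverse — and reports `implied_min_e(r) = 2r/(1+r)`,
the smallest efficiency under which the observation is attainable. This
matters in practice: ventrally located long descending propriospinal
populations show observed double-labelling of 40–50%, impossible under
$e = 0.25$; rather than guessing a different efficiency per group, grouped
corrections (`correct_estimate()` on a summary table) flag such groups with
the implied bound and continue with the rest.

### Interval estimation

`correct_estimate()` uses a parametric bootstrap: resampled double counts
$n_d^* \sim \mathrm{Binomial}(n_\text{total}, \hat r)$ are mapped through the
inverse; percentile bounds give the CI. Resamples falling at/above the
ceiling are counted (`n_infeasible_boot`) and contribute the capped value
$d^* = 1$, so the upper bound never exceeds 1 — a deliberate choice that
keeps the interval honest near the boundary instead of discarding extreme
resamples. Default 10,000 resamples, seeded. At $e = 1$ the correction is the
identity and the CI collapses to the plain binomial percentile bootstrap of
$r$ (a test asserts this equivalence exactly). Interference is excluded from
the inversion — there is no closed form for it — and is available only in the
forward simulator, where it can only depress double labelling; corrected
rates are therefore conservative (biased low) whenever interference is real.

## What the synthetic cohorts emulate

`generate_cohort()` realises the population the model reasons about, with
known ground truth for validation:

* **Connectivity.** Each neuron is divergent with probability
  `divergent_fraction`; non-divergent neurons split between the two pools
  (50/50 by default — published counts per pool are unequal, but no
  generative ratio is available, so the split is configurable).
* **Geometry.** A quadrant (dorsal/ventral × ipsi/contralateral) is sampled
  from `quadrant_probs`, then the position is uniform within that quadrant of
  the normalised transverse plane. Real laminar structure is *not* modelled;
  quadrant occupancy is the only spatial signal, so spatial tests validate
  bookkeeping (conservation, normalisation), not anatomy.
* **Soma and markers.** Log-normal soma areas (defaults moment-matched to
  published group summaries: cervical 774 ± 231 µm², thoracic 359 ± 144,
  lumbar 320 ± 114) and Bernoulli GlyT2/ChAT flags, independent of
  connectivity — adequate for exercising the statistics stages, not a claim
  about biology.
* **Sections.** Each neuron sits on exactly one of `n_sections` sections; an
  optional spillover flag duplicates labelled cells onto an adjacent section
  to reproduce the double-counting artefact that one-in-three-section
  counting exists to avoid.
* **Animals.** `n_premotor` is a per-animal count: every animal receives that
  many neurons per region, making cohort size exactly
  `n_premotor × n_animals` and per-animal allocation trivially even and
  deterministic.
* **Motoneurons.** Excluded by default; an optional count emits
  primary-infected, single-pool, ChAT⁺ rows that are always filtered out of
  premotor denominators.

`simulate_infection()` transmits each connection's colour with probability
$e$ independently. Viral interference — the reduced chance of a second rabies
infection shortly after a first — has no quantitative model in the
literature we rely on, so it is parameterised minimally: per neuron the
infection order is randomised and, when the first virus has succeeded, the
second transmits with probability $e(1-\rho)$, $\rho \in [0,1)$, default 0
(independence). Tests verify that expected double counts decrease strictly in
$\rho$.

Defaults are fixed once and not tuned: the lumbar block uses 7,000 premotor
neurons per animal at $d = 0.18$ and $e = 0.25$ — the corrected lumbar
operating point — and forward-simulation checks of the 4% anchor use
$10^6$ neurons, a size at which the binomial standard error (≈0.02
percentage points) is far inside integer-percent rounding.

## Counting conventions

* **Coordinates.** `normalize_coordinates()` maps the central canal to
  (0, 0) and grey-matter borders to ±1 per region, dorsal and
  injection-side-positive; out-of-bounds points are flagged and excluded from
  summaries rather than clipped.
* **Quadrant ties.** Coordinates exactly on an axis go ipsilateral/dorsal
  (`x ≥ 0`, `y ≥ 0`): deterministic, and measure-zero for continuous data.
* **Section sampling.** Default plan: one-in-three sections for lumbar
  premotor cells, all sections elsewhere; overridable per region. The three
  offsets at `k = 3` partition the cells — a tested invariant.
* **Two rate estimators.** `divergence_summary()` always reports both the
  pooled rate (summed counts; exact for reproducing printed ratios) and the
  unweighted per-animal mean ± SD, because published figures mix the two and
  they genuinely differ under heterogeneity. `rate_consistency()` quantifies
  the gap and flags groups whose per-animal proportions fail a chi-squared
  homogeneity test (α = 0.05). Per-animal mean ± SD values from the
  literature cannot be reproduced without per-animal source tables, so only
  pooled ratios are used as exact expectations in tests.
* **Rounding.** Printed percentages use one decimal, half away from zero
  (`round_half_away()`), not banker's rounding.
* **Rank statistics.** Kruskal–Wallis and Mann–Whitney come from base R
  (two-sided, normal approximation with tie and continuity correction).
  Dunn's post-hoc test is implemented in the package (no installed package
  provides it): pooled-rank z statistics with tie correction and — since the
  correction family is conventionally unstated — Bonferroni adjustment,
  recorded in the output. Its values are frozen in tests against an
  independently computed fixture.

## Numerical and degenerate-input choices

* Round-trip identity `true_rate(observed_rate(d, e), e) = d` holds to
  1e-12 over $d \in [0, 1)$, $e \in (0.01, 1]$ (tested on a 100 × 100 grid).
* Groups with zero labelled cells are *absent* from summaries, never reported
  as rate 0; Monte Carlo replicates with zero labelled neurons are tracked
  and excluded from averages rather than averaged as 0.
* Zero doubles give a corrected rate of exactly 0 with a zero lower bound.
* Empty cell tables abort the pipeline with a typed error; empty inputs to
  the simulator return empty outputs.
* All randomness flows from explicit integer seeds through `withr::with_seed`
  (the caller's RNG state is untouched); identical config + seed reproduces
  byte-identical cohorts, labelled tables and report bundles, which the suite
  asserts file by file.

## Problem sizes used by the test suite

Simulation-based checks run at sizes where binomial error bars make the
assertions sharp but the whole suite stays quick: convergence and
enumeration checks at $n = 10^5$ (3 SE bands), the Monte-Carlo-vs-closed-form
grid at $n = 10^5$ × 100 replicates, interference monotonicity over 20 seeds
at $n = 10^5$, bootstrap coverage over 100 cohorts of 7,000 neurons with
2,000 resamples, soma-area separation over 200 replicates at the published
group sizes (38/135/61), and the forward anchor check at $10^6$.

## Known limitations

* The inversion assumes a single, known $e$; the package does not estimate
  $e$ from data, and heterogeneous per-synapse efficiencies (e.g. stronger
  synapses transmitting more readily) are outside the model.
* Interference biases corrected rates downward and is not invertible here.
* Two colours only; no multi-pool generalisation.
* Quadrants, not laminae: no atlas mapping, no 3-D anatomy beyond the
  normalised transverse plane plus segment labels.
* Synthetic cohorts are exchangeable within region × animal; passing tests
  demonstrate the estimators' arithmetic and the model's self-consistency,
  not robustness to the spatial and cytological structure of real tissue.
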