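---
title: "Spectral unmixing and gating of highly autofluorescent lung samples"
author: "lungspectral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral unmixing and gating of highly autofluorescent lung samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungspectral)
```

## The problem

Full-spectrum ("spectral") flow cytometers record each cell's emission
across every detector of every laser — 64 detectors on the 5-laser
instrument this package models (UV 16, Violet 16, Blue 14, Yellow-Green
10, Red 8) — instead of one bandpass filter per dye.  Per-dye signals
are recovered afterwards by *spectral unmixing*: for each event the raw
detector vector $y \in \mathbb{R}^{64}$ is modelled as a linear mixture

$$y \;=\; M a + \varepsilon,$$

where the columns of $M$ (the *endmember matrix*) are the unit-norm
reference spectra of the panel fluorochromes, and $a$ is the per-event
abundance vector.  Lung tissue complicates this badly: it is highly
autofluorescent, with alveolar macrophages fluorescing across all 64
detectors.  Treating autofluorescence (AF) as one more set of endmember
columns — "virtual fluorochromes" — absorbs that background instead of
letting it spill into antibody channels.

The package implements the full desk-side workflow around that idea:

1. **Single-stain controls** (beads or cells) → endmember extraction,
   stain index, spillover-spreading matrix, and a per-fluorochrome
   bead-versus-cell carrier decision.
2. **AF dissection** of an unstained sample → 35 scatter-binned AF
   candidates, near-duplicate pruning, greedy selection of the minimal
   AF endmember set.
3. **Per-event least-squares unmixing** against the assembled matrix,
   with a single-AF versus multi-AF comparison report.
4. **Hierarchical gating** of the unmixed abundances into 17 murine
   lung immune populations with frequency-of-parent statistics.

Everything runs on a synthetic generator with ground truth, so each
stage is testable end to end without instrument files.

## Spectral primitives

Two spectra are compared by their **similarity index**, implemented as
the cosine of the background-clamped intensity vectors: 0 means no
spectral overlap (disjoint detector support), 1 means identical shape
(proportional spectra).  Acquisition vendors do not publish their index;
cosine reproduces both printed anchor semantics and is symmetric, scale
invariant and bounded.  The **complexity index** of a panel is the
2-norm condition number of the unit-norm endmember matrix, computed from
the eigenvalues of the similarity (Gram) matrix; orthogonal spectra give
1, a rank-deficient panel gives infinity, and larger values mean
noisier unmixing.

Signatures carry a normalization tag: unit-norm spectra are used for
similarity and unmixing; peak normalization (maximum 1) is reserved for
plotting and export.  The pre-normalization maximum is retained as
`peak_intensity` so brightness comparisons survive normalization.

## The synthetic generator

The generator is first-class, tested code — it defines the study
conditions under which every downstream guarantee is stated.

**Spectra.** Fluorochrome endmembers are smooth skewed peaks (sharp
blue edge, longer red tail) with a distinct dominant detector each and
random cross-laser excitation; candidates are redrawn until all
pairwise similarities are below 0.95.  AF endmembers are broad
multi-laser humps.  Three AF components are shipped by default:
`AF-lym` (dim, lymphoid), `AF-mye` (mid-scatter myeloid) and `AF-amo`
(alveolar macrophage, bright across all lasers).

**Expression.** Each of the 17 population profiles assigns every panel
marker one of four levels — `neg`, `low`, `pos`, `hi` — mapped to mean
abundances of 1, 10, 100 and 1000 (decades typical of surface-marker
dynamic range; the decade spacing is what keeps automatic gates
unambiguous at default noise).  Per-event expression is log-normal with
coefficient of variation 0.25.

**Autofluorescence.** Each profile carries a mean abundance per AF
component; the realized AF abundance scales linearly with the event's
side scatter (reference SSC-A 50,000), so the scatter-binned dissection
has real structure to find.  The alveolar macrophage's `AF-amo` weight
(800) dominates every other population, cDC2 carries a moderate
`AF-amo` weight, and `AF-lym`/`AF-mye` are spread across several
subsets.  Only the *ordering* of these weights is anchored in published
observations; the magnitudes are the package's own choice.

**Noise.** Detector noise is Gaussian with variance
`shot_coefficient * mean signal` (Poisson limit) plus additive
electronic noise; defaults `shot_coefficient = 0.02`,
`electronic_sd = 0.5` put the unmixed-abundance noise floor roughly one
decade below the `pos` level on well-conditioned channels — the regime
of a well-set-up instrument.  Setting all noise parameters to zero
yields an exactly deterministic linear model, which the tests exploit.

**Scatter.** FSC/SSC are truncated normals (±2.5 SD) per population,
so scatter strata are bounded and the one scatter-derived gate (the
monocyte SSC cut) can sit in a true gap; this is what makes noise-free
gating recovery *exact* rather than merely good.  5% of each
population is dead (viability-dye positive) and 1% of events are
doublets (FSC-H/FSC-A deflated, FSC-A inflated).

**What the generator does not emulate:** real lung AF spectra
point-for-point (published spectra are not digitized), instrument gain
drift, spectral ripple within a dye, debris, aggregates beyond the
simple doublet factor, and biological covariance between markers
(levels are drawn independently).  Passing tests therefore demonstrate
that the *procedures* are correct under a faithful linear-mixture
model, not that any particular biological frequency is reproduced.

## Controls, stain index, spread and the carrier decision

Endmember extraction takes the top fraction (default 20%) of a
control's events on its brightest detector, subtracts the per-detector
median of a background reference, clamps at zero and unit-normalizes.
The right background is *carrier-matched*: bead controls carry no
cellular AF, so the dim events of the control itself (`control_blank()`)
are used rather than an unstained tissue sample.  A control whose
positives do not rise above the background's 95th percentile is flagged
and returns an all-zero signature.

The **stain index** is `(median(pos) - median(neg)) / (2 * robust SD(neg))`
with the robust SD taken as 1.4826 × MAD — robust estimators resist the
heavy tails the simulator (and real cytometers) produce.  **Spillover
spreading** is measured at the unmixed-abundance level: entry (f, g) is
the robust SD of channel-g abundances among f-positive events minus
that among f-negative events, floored at zero.

Fluorochromes can change emission shape when bound to cells instead of
beads.  The generator perturbs three channels (PE-Fire810, APC, AF700
by default) with a smooth multiplicative curve; the perturbation is
*dye chemistry*, so the same fixed perturbation appears in the
simulated biological sample and in the cell-carrier controls.  The
carrier decision evaluates both carriers' matrices on the cell-carrier
controls (the closest stand-in for the sample a matrix will actually
unmix) and picks, per fluorochrome, the carrier with the lower total
spread contribution, breaking ties by stain index.  This lexicographic
rule is the package's formalization of "reduced spread and higher
signal intensity"; the two objectives are not otherwise commensurable.

## AF dissection, pruning and selection

`af_dissect()` partitions the FSC-A × SSC-A plane into a quantile grid
— 7 FSC columns × 5 SSC rows = 35 bins by default; quantile edges keep
every bin populated for any scatter distribution — and takes each bin's
per-detector *median* spectrum (medians resist bright outlier cells
inside a bin).  `af_prune()` sorts candidates by mean total intensity
and greedily keeps those whose similarity to every kept candidate is
below 0.98: of two near-duplicates the dimmer is excluded.  The 0.98
default separates near-duplicates from the 0.8 co-expression guideline
by a wide margin; it is not a published constant.

`af_select()` runs greedy forward selection: starting from the
fluorochrome-only matrix it repeatedly adds the candidate that most
reduces the **background bias** — the mean absolute unmixed
fluorochrome abundance over the unstained events — and stops when the
relative improvement drops below 5% (or `max_af` is reached).  Visual
inspection of N×N unmixing plots is what practitioners actually do;
an L1 background criterion is the closest scalar surrogate and is
testable.  Selection is evaluated on unstained events; evaluating on a
fully stained sample would be the natural alternative and is noted as
such, but background bias is only unambiguous where the truth is "no
stain".

## Unmixing

Ordinary least squares per event, solved by one QR decomposition of the
endmember matrix shared across the event batch.  Abundances are signed:
no non-negativity constraint is applied, matching vendor convention
(negative unmixed values are what N×N plots display).  The solution is
checked in tests against an explicit pseudo-inverse oracle to 1e-10 and
satisfies the normal equations to 1e-8 relative.  A weighted variant
(`method = "wls"`) takes per-detector variances; equal variances reduce
it to OLS and an infinite variance removes a detector from the fit.
Near-collinear endmember pairs (similarity > 0.999) are rejected at
matrix assembly with a diagnostic naming the pair.

The single-versus-multi AF comparison unmixes the same sample with the
selected AF set and with one whole-sample AF column (the mean unstained
spectrum), and reports per-channel background bias and spread among
truth-negative events, grouped by laser.  Channels that are positive on
every population (CD45 here) have no negative stratum and are omitted.

## Gating

The lung hierarchy is a declarative tree of threshold predicates:
debris (FSC-A), singlets (FSC-H/FSC-A ratio), live (viability dye
negative), CD45+, Ly6G+ neutrophils, the myeloid branch (CD11b+ or
CD11c+; the only disjunctive gate) with monocytes below the myeloid
SSC-A median gap and the CD64/CD24 split into macrophages, eosinophils,
DCs and pDCs, and the lymphoid branch with B/T cells, the
CD4/CD8/Treg split, and the CD335/CD127 innate lymphoid logic.  Memory
T subsets (CD44/CD62L), mature NK (CD11b+KLRG-1+CD122+) and the
CD206/CX3CR1 macrophage confirmations are *parallel* side gates: they
overlap their siblings, are reported in the frequency table, but do not
enter parent/child conservation, and an unresolved threshold on a
parallel gate skips that gate rather than aborting the run.

**No numeric threshold is hard-coded.**  `derive_thresholds()` resolves
every named reference from a labelled reference sample, per channel, in
arcsinh space (cofactor 5): negative reference events are those of
populations at level `neg`/`low`, positives at `pos`/`hi`; the
threshold is the midpoint between the negatives' 99.5th percentile and
the positives' lower density mode, mapped back to the raw scale (so
gating is invariant under any monotone transform applied jointly to a
channel and its threshold).  Two robustness amendments matter in
practice: the negative bound is capped at the midpoint of negative
median and positive mode — heavy spillover-spread tails otherwise push
the gate into the positive population — and the positive mode is
searched only above the negative median, because spread can throw
spurious density bumps at strongly negative abundances.  A channel is
declared unresolvable when the positive mode fails to clear the
negative median by a quarter of the positives' robust SD, which is
where identical negative and positive distributions land.  Markers
positive on every population (CD45) resolve one-sided, just below the
positive distribution.  The Treg CD127 cut and the ILC CD127 cut are
distinct named references (they resolve to the same rule here, but the
tree does not assume it).

Labels are the population of the deepest *target* gate an event
reaches; events stranded at a branch are labelled
`"<gate>/unassigned"`.  The frequency table reports counts and
frequency-of-parent per gate; each parent's count equals the sum of its
non-parallel children plus its unassigned bucket.

## Numerical and reproducibility choices

* All randomness flows through a seed argument; generators restore the
  caller's RNG state, and every pipeline stage derives a sub-seed (kept
  within 32-bit range) from the master seed.  Two runs with the same
  configuration produce byte-identical outputs (MD5-hashed into the run
  manifest).
* Internal computation is double precision; FCS files store float32
  (the format's convention), and round-trips are exact to single
  precision.  Ground-truth labels, abundances and seeds travel in a
  JSON sidecar next to the FCS file.
* Degenerate inputs: all-zero spectra normalize to all-zero without
  dividing by zero; an all-zero similarity argument returns 0; a
  rank-deficient endmember matrix refuses to unmix, naming the
  offending pair; an empty candidate list selects an empty AF set with
  an explanatory trace.

## Problem sizes

The shipped defaults — and the sizes used throughout the test suite —
are: stained samples of 20,000 events (17 populations, equal weights),
unstained samples of 4,000–6,000 events, single-stain controls of
1,500 events, AF recovery judged over 20 seeds, and the multi-versus
single-AF comparison over 10 paired seeds.  These sizes give stable
estimates of every reported quantity while keeping a full run in
seconds on one core.

## Known limitations

* The similarity and complexity indices are this package's stated
  formalizations (cosine; condition number); vendor software may
  compute something else with the same anchor semantics.
* The AF dissection grid is a quantile stand-in for the vendor's 35-bin
  geometry, which is not published.
* Threshold derivation needs a labelled reference (ground truth here;
  FMO-style controls in practice).  Real FMO gating involves judgement
  the midpoint rule does not capture.
* The gating tree and the generator's profiles are mutually consistent
  by construction; accuracy on real lungs depends on staining quality
  and population abundances the generator does not model.
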