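---
title: "Methods: envelope-based activity calling on phenotypic screening panels"
author: "phenoscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-based activity calling on phenotypic screening panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

## The screening problem

Multiplexed phenotypic screening panels such as the 12-system BioMAP
Diversity PLUS platform profile a compound across stimulated primary human
cell systems — endothelial cells under inflammatory cytokines (3C), T-cell
receptor co-cultures (SAg), bronchial epithelium (BE3C), fibroblast fibrosis
models (HDF3CGF, MyoF), and so on — reading out ~148 protein biomarkers at
four ascending doses. Every measurement enters the analysis as a **log10
ratio** of the treated readout over vehicle control, so 0 means "no change"
and ±0.1 is roughly a ±20% effect. The analysis questions are: which
readouts did the compound move beyond assay noise, which of those movements
are dose-dependent, at which dose is the compound most active, and how much
of its activity signature is shared — with direction agreement — with
another compound. This package implements that rule set as a tested
pipeline, together with transcriptions of the published reference tables for
pentadecanoic acid (C15:0), rapamycin, metformin and acarbose, and a
synthetic panel generator with ground truth.

## The significance envelope

Assay noise is estimated from historical vehicle-control wells. For each
(system, biomarker) readout with control history, `estimateEnvelopes()`
computes a symmetric interval $[-w, +w]$ on the log10-ratio scale that
covers a stated fraction (default 95%) of the vehicle-control
*distribution*:

* **normal** method: $w = z_{1-\alpha/2}\,\hat\sigma$, i.e.
  $1.959964 \times$ the sample standard deviation at 95%;
* **empirical** method: the symmetrized sample quantile band
  $w = \max(|q_{\alpha/2}|, |q_{1-\alpha/2}|)$.

Two choices here were genuinely open and deserve a justification:

* The "95% confidence" is read as a **tolerance band of the control
  distribution**, not a confidence interval of the control mean. A CI of
  the mean shrinks as $1/\sqrt{n}$ with the number of historical controls
  and would eventually flag almost every readout; the envelope's job is to
  gate *individual* treated readouts against well-to-well noise, which is
  what a distribution-coverage band does.
* The envelope is **centered at 0**, not at the control mean: controls set
  the width only. This matches the symmetric upper/negative-lower-bound
  construction of the platform convention, keeps "no change" the reference
  point, and makes classification antisymmetric under sign flips.

Classification is strict: a value is `up` only if it exceeds $+w$, `down`
only if it is below $-w$; boundary values are `inside`. Readouts with fewer
than two historical controls fall back to a default half-width of 0.1
(configurable), chosen to coincide with the effect-size threshold so that an
un-characterized readout can never qualify on envelope grounds alone. No
multiple-testing correction is applied across the panel's readouts; the
platform convention applies none, and the calibration tests quantify the
resulting per-readout false-positive rate instead.

## Three tiers of activity

```{r tiers, eval = FALSE}
hits <- callHits(profile, envelopes)             # single-dose tier
acts <- annotateActivities(profile, envelopes)   # dose-dependent tier
flags <- flagCytotoxicity(profile)               # viability tier
```

* A **biomarker hit** is a single (system, biomarker, dose) measurement that
  is outside the envelope *and* has $|\log_{10}\text{ratio}| > 0.1$ (a
  >20% effect). Both conditions are required: a 0.105 value inside a wide
  envelope is not a hit, nor is a 0.08 value outside a narrow one.
* An **annotated (dose-dependent) activity** requires at least two
  *consecutive* tested concentrations classified outside the envelope on
  the same side, with at least one concentration in the run passing the
  effect-size gate. Each concentration in the run must individually be
  outside the envelope — the stricter of the two possible readings of
  "changed in the same direction and were outside the envelope", and the
  one that reproduces the sparseness of the reference signatures. Runs are
  maximal (a 3-dose run is one activity, not two overlapping 2-dose ones),
  and at most one activity per (system, biomarker, direction) is reported;
  if disjoint qualifying runs share a direction, the run with the larger
  peak effect wins, the earlier one on ties. A readout may legitimately
  carry an `up` and a `down` activity (a U-shaped response crossing zero);
  both are reported, and `labelModulated()` marks biomarkers moving up in
  one system and down in a *different* system.
* **Cytotoxicity**: a viability readout (SRB or alamarBlue) below −0.3
  (>50% loss of total protein) flags the (system, dose) as cytotoxic; a
  low-density proliferation-context readout below −0.1 flags it as
  antiproliferative. One qualifying concentration suffices. When
  cytotoxicity is flagged in ≥3 distinct systems at one concentration, that
  concentration is **broadly cytotoxic** and `applyBroadCytotoxExclusion()`
  removes it panel-wide before hit calling and annotation. A removed
  *interior* dose breaks run adjacency: "consecutive concentrations" means
  adjacent in the tested series actually eligible for annotation, so
  annotation can only become more conservative after exclusion (a property
  the test suite checks).

All comparators are strict (`> 0.1`, `< −0.3`, `< −0.1`); boundary values
never qualify. Whether viability readouts themselves may appear among hits
and activities is a configuration switch (`includeViability`, default TRUE —
the reference optimal-dose signatures list SRB entries).

## Optimal doses and shared signatures

The **optimal dose** is simply the tested concentration with the most
biomarker hits (`optimalDose()`); ties resolve to the lowest tied dose by
default, a conservative dosing convention (no tie occurs in the reference
hit counts). Signatures are compared as sets of (system, canonical
biomarker, direction) triples: `sharedActivities()` counts exact triples in
common, so the same readout moved in *opposite* directions by two compounds
is not shared. That direction-matching rule is what reproduces the
reference result of 24 optimal-dose activities shared between C15:0 (17 µM)
and rapamycin (9 µM) across 10 of 12 systems — E-selectin in the macrophage
co-culture moves up under one compound and down under the other and is
correctly not counted.

Because the typeset reference tables spell several readouts inconsistently
(PAI-1/PAI-I, TIMP-1/TIMP1, Esel/E-selectin, Col-I/collagen-I, TM, TF,
MMP9, soluble "s"-prefixed readouts, bare "proliferation"), all names pass
through `canonicalBiomarker()`: case/hyphen/whitespace folding plus a
packaged synonym dictionary, with bare proliferation readouts resolved to
the system's qualified name (e.g. "T cell proliferation" in SAg). The
dictionary is necessarily partial — it covers the names appearing in the
packaged tables — and unknown names pass through folded with a warning
rather than failing, so user panels with their own nomenclature remain
analysable. The mapping is idempotent and deterministic.

`reproduceReferenceReport()` recomputes every summary claim printed with
the reference tables and reports `pass` or `discrepancy` per claim. The
published tables are internally inconsistent in places — summary totals of
36/32/17 activities against enumerations of 34/30/16, a stated 12
dose-dependent C15:0/rapamycin overlaps where the tables yield 13, a stated
11-across-5 optimal-dose metformin overlap where the tables yield 13 across
6, and a stated single C15:0/acarbose shared activity where the synonym
rule also matches TIMP-1 in MyoF. These are flagged as discrepancies, never
silently reconciled: the packaged transcriptions stay faithful to the
printed cells and the report shows both numbers.

## The synthetic panel generator

`panelSpec()` defaults define the conditions the package is calibrated on,
mirroring the reference platform's geometry: 12 systems × 12 soluble
biomarkers (~148 readouts, the exact per-system split being unspecified in
the platform description) plus one SRB viability readout per system, the
4-dose grid 1.9/5.6/17/50 µM, vehicle noise with sd 0.025 on the log10
scale (so that the 95% normal envelope, ≈0.049, sits well below the 0.1
effect gate, as it must for a platform whose hits are dominated by real
effects), and 100 historical control replicates per readout.

Injected effects are shaped on the dose grid: `monotone_up`/`monotone_down`
are graded ramps rising linearly from an onset dose to full amplitude at
the top dose; `threshold_onset` is a step to full amplitude at the onset
dose; `u_shape` places the peak at an interior dose with half-amplitude
shoulders, emulating a compound whose activity recedes at the top dose —
the characteristic profile of C15:0, whose hit count drops from 81 at 17 µM
to 40 at 50 µM. Noise is independent across doses and readouts — the
simplest model consistent with threshold/run rules; within-series
correlation, batch structure, heteroscedastic readouts and
readout-specific biology are *not* modelled, so passing recovery tests
demonstrate correctness of the rule implementation under the stated noise
model, not performance on real panels. Amplitudes live directly on the
log10-ratio scale; there is no raw-signal model. All draws are reproducible
under the spec's seed (controls use `seed`, profile noise `seed + 1`).

Ground truth records the annotations the pipeline must produce from the
*noise-free* signal under a stated envelope half-width; `evaluateRecovery()`
scores called annotations against it on (system, biomarker, direction).

## Numerical and design choices

* **Tie-breaks**: optimal dose → lowest tied dose; equal-strength
  same-direction runs → earliest run.
* **Degenerate inputs**: zero-variance controls give a zero-width envelope
  (only the effect gate then protects against noise); readouts with <2
  controls use the default half-width with a warning; an all-excluded
  profile is returned empty with a warning; profiles without viability
  readouts produce no cytotoxicity flags, with a message.
* **Explicit gaps**: a missing measurement is an `NA` row, never an implied
  zero; `NA` classifies as a gap and breaks runs.
* **Determinism**: pipeline outputs (`runAnnotate()`, `runCompare()`,
  `simulatePanel()`) serialize the resolved configuration into their
  machine-readable summaries and are byte-identical under identical inputs,
  configuration and seed.
* **Problem sizes in the test suite**: the annotation rule is verified
  exhaustively against an independent brute-force scanner over all $5^4 =
  625$ per-dose state combinations (covering all $3^4 = 81$ classification
  patterns crossed with effect-size outcomes); envelope calibration uses
  ~100,000 null readout-dose classifications against envelopes estimated
  from 100-replicate control histories; recovery uses 500 simulated panels
  (200 in the standalone acceptance script) at amplitude 0.3 and noise sd
  0.025. These sizes give Monte-Carlo error comfortably below the margins
  being asserted (the null outside-rate, for instance, is checked at 5% ± 1
  percentage point, where estimation noise at $n = 10^5$ is ~0.07
  points and the envelope-estimation Jensen bias at 100 controls is ~+0.2
  points).

## Limitations

The hit counts of the reference hit-count table are inputs, not outputs:
the per-biomarker raw profiles behind them are not published in the main
text, so the package reproduces the optimal-dose *rule* on those counts
rather than the counts themselves. The synonym dictionary covers the
packaged tables only. Profile-similarity search, clustering and
benchmarking against reference-compound databases are out of scope, as are
dose–response curve fits (EC50/Hill): the calling rules are purely
threshold- and run-based, and that is what this package implements.
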