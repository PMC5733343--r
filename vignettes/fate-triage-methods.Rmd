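---
title: "Classifying metabolic fates from in vitro fecal fermentations"
author: "gutfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metabolic fates from in vitro fecal fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutfate)
```

## The experimental system

`gutfate` analyzes in vitro batch fermentations in which a plant extract is
added to a human fecal suspension (HFS, 0.1 g feces/ml in anoxic PBS) and
sampled over a day. The design it expects — and that its simulator
generates — has five channels, each in triplicate at 0.5, 4 and 24 h:

| channel           | extract (mg/ml) | microbes | purpose                          |
|-------------------|-----------------|----------|----------------------------------|
| `HFS_WBE`         | 2               | yes      | treatment, low concentration     |
| `HFS_WBE`         | 10              | yes      | treatment, high concentration    |
| `HFS_VEHICLE`     | 0               | yes      | fecal matrix + vehicle           |
| `HFS_PBS`         | 0               | yes      | fecal matrix                     |
| `EXTRACT_CONTROL` | 10              | no       | abiotic stability of the extract |

The first sampling is at 0.5 h, not 0, because handling in an anaerobic
chamber takes that long; the labels t0/t4/t24 map to 0.5/4/24 h. This
matters: very labile compounds can be gone before t0, which is exactly what
the fast-metabolized rule detects.

## The fate rules and their order

For each feature and concentration, the replicate areas of the three time
groups are compared as group-mean ratios with an unpaired, two-tailed
Student's *t*-test (pooled variance, df = n₁ + n₂ − 2; `fold_test()`).
The rules, in the order `run_triage()` applies them:

1. **MATRIX** — present (≥ `min_detected` of the replicates detected, default
   2 of 3) in any extract-free fecal channel at any time point. Such a
   feature belongs to the fecal background and is excluded regardless of
   its time course.
2. **FAST_METABOLIZED** — present in the extract control at t0 and never
   present in any extract-treated fecal cell. The compound demonstrably
   exists in the extract but is consumed before the first sampling.
3. **INSUFFICIENT_DATA** — not present in any time group of the channel
   under test; there is nothing to rate.
4. **INTERMEDIATE** — t4/t0 > 2 with *p* < 0.05 and t4/t24 > 1.25.
5. **INCREASING** — t24/t0 > 2 with *p* < 0.05.
6. **DECREASING** — t24/t0 < 0.5 with *p* < 0.05.
7. **UNCHANGED** — everything else.

The intermediate rule is evaluated before increasing/decreasing because a
rise-then-fall trajectory can also satisfy either monotone rule (its t24/t0
ratio may land on either side of 1); no precedence is implied by the rules
themselves, so the package fixes one and documents it here. Independently
of the label, `crosscheck_abiotic()` sets a flag when the microbe-free
extract control shows the same-direction significant change — such features
(e.g. ester rearrangements proceeding in plain buffer) are chemically, not
microbially, unstable and are dropped from substrate/metabolite reports by
`compound_fates()`.

Design choices worth knowing:

* **Not-detected ≠ zero, but counts as zero in means.** Areas below the
  limit of detection are stored as `NA`; for testing they are zero-filled,
  which preserves decreasing-to-zero dynamics, while presence (≥ 2/3
  detected) separately gates whether a group is trustworthy at all.
* **Zero-variance limits.** Noiseless groups are legal inputs (they occur
  in simulation oracles): the t-test limit is *p* = 1 for equal means and
  *p* = 0 for different means. `stats::t.test()` refuses constant data,
  which is why the statistic is computed directly; it is verified against
  `t.test` to 1e-9 wherever the latter is defined.
* **Ratios are ratios of group means**, not means of per-replicate ratios,
  and a zero reference mean yields an infinite ratio with a
  `ratio_undefined` flag (a metabolite appearing from nothing is a real
  increase, not an error).
* **No multiple-testing correction.** The procedure screens features at raw
  *p* < 0.05, as is conventional for this kind of triage; the p-values are
  filters, not inferential claims. Treat downstream compound lists
  accordingly.
* Welch's test is available (`pipeline_config(welch = TRUE)`) but the
  pooled-variance Student test is the default, matching the named
  procedure.

## Mass arithmetic and annotation

`parse_formula()` accepts C/H/N/O/P/S formulas; anything else errors by
design rather than silently computing a wrong mass. `monoisotopic_mass()`
sums exact lightest-isotope masses from a versioned table bundled with the
package (C = 12 exactly, H = 1.007825032, O = 15.994914620, ...), so results
are reproducible without runtime lookups. Neutralization of negative-mode
ions adds the proton mass (1.007276 Da) — not the hydrogen-atom mass — which
keeps the electron on the correct side for [M−H]⁻.

Annotation (`match_feature()`) compares the neutralized feature mass
against *formula-derived* theoretical masses of the bundled 58-compound
willow-bark library, not against the library's printed observed masses:
five library rows print masses that are internally inconsistent with their
printed formulas (they carry a `note` documenting the discrepancy and are
transcribed verbatim rather than guessed at). The default tolerance is
5 ppm. Retention-time gating (default window 0.3 min) is off unless
requested, because retention times transfer only within one chromatographic
method; ties are broken by |Δppm|, then |ΔRT|, then peak id, so ranking is
total and deterministic — this resolves isobaric pairs such as the two
acetylsalicins when RT is usable.

## Pathway overlays

The bundled fixtures encode the literature-described degradation routes of
naringenin glycosides, catechin, and salicylic alcohol derivatives as
directed acyclic graphs whose edges carry transformation types
(deglycosylation, C-ring cleavage, dehydroxylation, ...). `overlay_fates()`
assigns each annotated node a role:

* DECREASING or FAST_METABOLIZED → **precursor**;
* triaged INTERMEDIATE → **intermediate**;
* INCREASING → **terminal metabolite** if the node is a sink of the graph,
  otherwise **intermediate**;
* anything else → unknown.

The one genuinely open design question here was how to treat a chain of
significantly increasing metabolites. In a degradation cascade observed
over 24 h, an interior compound can accumulate (formation outruns
consumption) while still feeding its successors — a cascade in which nearly
every downstream acid increases is the expected signature of active
degradation, not a contradiction. Mapping every increasing node to
"terminal" would brand such cascades inconsistent, so the role instead uses
the graph's own structure: only increasing *sinks* are terminal. An edge is
then **consistent** when a precursor or intermediate feeds an intermediate
or terminal metabolite, **inconsistent** when a terminal metabolite is
drawn as feeding a formed product (`edge_verdict()` exposes this check
directly), and **undetermined** when either endpoint is unknown. Nodes
flagged `expected_undetectable` (compounds such as phloroglucinol and
3-(4-hydroxyphenyl)propionic acid that ionize too weakly in negative ESI)
stay unknown when absent, so their edges read undetermined rather than
inconsistent. Coverage is simply detected nodes / total nodes.

## What the simulator does and does not emulate

`simulate_experiment()` draws each observed area as
*trajectory × exp(N(0, σ²))* and censors areas below the LOD as
not-detected. The archetype trajectories are first-order: decay
A·e^(−kt) for substrates, formation A·(1 − e^(−kt)) for products, the
two-step series solution A·k₁/(k₂ − k₁)·(e^(−k₁t) − e^(−k₂t)) for
intermediates (peak at ln(k₂/k₁)/(k₂ − k₁)), constants for stable and
matrix features, and decay in *all* channels — including the microbe-free
control — for abiotically unstable features. Biotic kinetics freeze in the
extract control (substrates sit at their initial level; products never
form), which is precisely the contrast the abiotic crosscheck exploits.

Defaults, chosen once on closed-form grounds: amplitude 1000 area units,
σ = 0.2, LOD = 1 (so stable features are never censored), k = 0.2 /h for
substrates and products, k₁ = 0.35 and k₂ = 0.10 /h for intermediates,
k = 0.15 /h for abiotic decay, k = 30 /h for fast-metabolized features, and
an inhibition factor of 1.5 dividing biotic rates at 10 mg/ml (a minimal
mechanism for slower turnover at high extract concentration, where formed
aglycones can inhibit the degrading taxa). With these values every
archetype clears its classification thresholds at both concentrations —
e.g. the intermediate's noiseless ratios are t4/t0 = 3.8 and t4/t24 = 4.7
at 2 mg/ml and 4.8 / 1.9 at 10 mg/ml, against thresholds of 2 and 1.25 —
so noiseless recovery is exact and σ = 0.1 recovery exceeds 90 %, which
the test suite verifies on 235 features (50 per biotic archetype plus
abiotic, matrix and fast features). Multiplicative lognormal noise was
chosen over additive Gaussian because peak areas are positive and
heteroscedastic.

The simulator does **not** emulate chromatographic peak shapes, retention
drift, ionization suppression, correlated noise between co-eluting
features, missing-at-random dropouts above the LOD, or isotopologue/adduct
features of one compound. Passing recovery tests therefore show that the
rule implementation is faithful and robust to realistic area noise — not
that the pipeline would reach 90 % accuracy on real instrument data, where
those unmodeled effects dominate the error budget. Rate constants are free
simulation parameters, not estimates for any real compound: the source
experiments report no quantitative kinetics.

## Numerical and degenerate-input conventions

* Deterministic everywhere: one integer seed fixes the simulated table
  bit-for-bit; triage, annotation and overlays are pure functions of their
  inputs.
* `fold_test()` with fewer than two values per group signals
  `insufficient` rather than erroring, and `classify_fate()` converts that
  into `INSUFFICIENT_DATA`.
* OTU utilities: "represented by 5 or less sequences" is implemented as
  *total across all samples* ≤ 5 (the alternative, per-sample, is not what
  a removal-before-analysis step wants and would drop consistently present
  low-abundance OTUs); total-sum normalization errors on zero-total
  samples, naming them; the > 1 % abundance cut is strict.
* Problem sizes in the shipped tests (a few hundred features, 100 random
  oracle tables, 10⁴ null replicates) were picked to exercise every rule
  branch while keeping the default suite quick on a laptop.

## Known limitations

* The triage thresholds are the screening conventions of the source
  procedure; nothing in the package estimates kinetic parameters or fits
  time-series models.
* Annotation is mass(+RT) only — level 2/3 evidence. MS/MS matching and
  structure elucidation are out of scope, so isobaric and isomeric
  compounds beyond RT resolution stay ambiguous.
* Pathway fixtures encode only transformations named in the accompanying
  degradation literature for these three compound classes; they are not a
  general metabolic network, and the overlay scores direction
  compatibility, not flux.
* Only the [M−H]⁻ ion is modeled; multiply charged ions and other adducts
  are not.
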