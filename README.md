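# gutfate

Metabolic fate classification for in vitro fecal fermentation metabolomics.

When a complex herbal extract is incubated with a human fecal suspension
(HFS) under anoxic conditions, its constituents are degraded by gut
bacteria into smaller, often more bioavailable metabolites. Untargeted
LC-MS tracks this as thousands of features — (m/z, retention time) pairs
with peak areas per sample — sampled here at 0.5 h (t0), 4 h (t4) and 24 h
(t24), in triplicate, across five channels: HFS + extract at 2 and
10 mg/ml, two extract-free fecal controls (vehicle and PBS), and a
microbe-free extract-in-buffer control. `gutfate` turns such feature tables
into per-compound verdicts: what was consumed, what was formed, what passed
through transiently, and what changed for reasons that have nothing to do
with the microbes.

## The classification rules

For each feature and extract concentration, group-mean ratios between time
points are tested with an unpaired, two-tailed Student's *t*-test
(pooled variance, df = n₁ + n₂ − 2) on the replicate areas:

* **intermediate** — t4/t0 > 2 (*p* < 0.05) and t4/t24 > 1.25
  (rise then fall: formed, then further degraded);
* else **increasing** — t24/t0 > 2 (*p* < 0.05);
* else **decreasing** — t24/t0 < 0.5 (*p* < 0.05);
* else **unchanged**.

Two control-driven rules take precedence: a feature present (≥ 2 of 3
replicates detected) in an extract-free fecal channel at any time point is
a **matrix** peak, and a feature present in the extract control at t0 but
never detected in any fecal incubation is **fast-metabolized**. Finally,
each fate is crosschecked against the microbe-free extract control: a
same-direction significant change there flags the feature as **abiotic**
(not caused by the microbes), excluding it from substrate/metabolite
reports. Not-detected areas enter group means as 0; no multiple-testing
correction is applied (raw *p* < 0.05).

Annotation converts each observed negative-mode m/z to a neutral mass
(m/z + 1.007276, the proton mass) and matches it against a bundled
58-compound willow-bark library by formula-derived monoisotopic mass within
5 ppm, optionally gated by retention time. Annotated fates can be overlaid
on bundled directed degradation pathways (naringenin glycosides, catechin,
salicylic alcohol derivatives) to score each transformation edge as
consistent, inconsistent, or undetermined. A seeded simulator with known
kinetic ground truth (first-order decay/formation, two-step series
kinetics, lognormal noise, LOD censoring) makes the whole chain testable,
and small OTU-table utilities cover rare-OTU filtering (total ≤ 5 reads
removed), total-sum normalization and > 1 % abundance selection.

## Worked example

Simulate the full design with feature kinetics anchored to library
compounds, then triage, annotate and overlay:

```r
library(gutfate)
res <- run_pipeline(pipeline_config(seed = 42, noise_sigma = 0.1),
                    truth_config = demo_truth_config())
res
#> <pipeline_result>
#>   fates: 74 records; labels: DECREASING, FAST_METABOLIZED, INCREASING, INTERMEDIATE, MATRIX, UNCHANGED
#>   annotations: 53 hits
#>   overlay naringenin: coverage 0.75
#>   overlay catechin: coverage 1.00
#>   overlay salicyl: coverage 0.71

subset(res$fates, feature_id == "P56",
       select = c(concentration, label, ratio_t4_t0, ratio_t4_t24))
#>    concentration        label ratio_t4_t0 ratio_t4_t24
#> 21             2 INTERMEDIATE    3.107992     4.419110
#> 22            10 INTERMEDIATE    5.064238     2.058308
```

The feature anchored to naringenin rises between t0 and t4 and falls again
by t24 at both concentrations — an intermediate — and the fall is weaker at
10 mg/ml, where the simulator slows biotic rates to emulate
concentration-dependent inhibition of the degrading bacteria. Overlaying
the 2 mg/ml fates on the catechin pathway confirms every drawn
transformation:

```r
coverage_report(res$overlays$catechin)$verdicts
#>   CONSISTENT INCONSISTENT UNDETERMINED
#>           13            0            0
```

Annotation of a single observed ion:

```r
match_feature(285.09798, rt = 6.7, library = load_compound_library())[1, ]
#>   peak_id    name theoretical_mass  delta_ppm delta_rt
#> 1      10 salicin         286.1053 0.01241152    -0.02
```

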