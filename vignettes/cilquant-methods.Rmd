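---
title: "Peak-pair quantification for chemical isotope labeling LC-MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-pair quantification for chemical isotope labeling LC-MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilquant)
```

## The measurement model

In chemical isotope labeling (CIL) LC-MS, every metabolite carrying a
labelable functional group appears in the spectrum twice: once
derivatized with the light (^12^C) reagent applied to the individual
sample and once with the heavy (^13^C~2~) reagent applied to a pooled
reference made from equal mole amounts of all study samples.  For
dansylation of amines and phenols, each tag adds a net C~12~H~11~NO~2~S
moiety (233.05105 Da) and the heavy reagent carries two ^13^C atoms per
tag, so the protonated ions of an *n*-tag metabolite of neutral mass
*M* sit at

$$ m/z_\text{light} = M + n \times 233.05105 + 1.007276, \qquad
   m/z_\text{heavy} = m/z_\text{light} + n \times 2.00671 . $$

Because both channels co-elute and experience the same suppression,
the light/heavy intensity ratio of the pair is a matrix-robust measure
of the sample's concentration relative to the pool, which acts as a
universal internal standard across all injections.  `labeled_mz()`
implements this arithmetic from elemental monoisotopic masses; for
dansyl-serine it predicts *m/z* 339.10092, within the instrument-class
10 ppm of the observed 339.1023 reported for this chemistry.

## What the simulator emulates

`build_design()` reproduces the structure of a longitudinal
disease/treatment study in rats: three arms (normal, sham-operated,
surgically induced osteoarthritis) sampled biweekly over weeks 0–14,
four treatment arms sampled biweekly over weeks 8–14, six animals per
group, duplicate injections, and a pooled QC injection after every ten
sample runs.  With the sham week-12 group dropped (encoded as a design
field, not hard-coded) this enumerates 39 groups, 234 samples, 468
sample runs and 46 QC injections.

`simulate_metabolome()` draws metabolites with lognormal base
concentrations and MS response factors and assigns trajectory classes.
The planted biomarker class (`treatment_reversing`) rises in all
disease-bearing arms to a 2-fold change by week 6 through log-ramp
fractions 0, 0.65, 0.9, 1 at weeks 0/2/4/6 — a fast post-surgery
response that saturates, the shape reported for the real markers — and
decays log-linearly back to the sham level by week 14 in treated arms
while staying elevated in the untreated disease arm.  Disease-only
classes (`oa_up`, `oa_down`) shift without reverting; the `random`
class adds independent lognormal drift (σ = 0.10) to every group mean,
emulating unmodeled biology that the selection logic must reject.

Animal-to-animal biological variation is lognormal with σ = 0.15
(≈15% CV, a typical plasma metabolome value); the pool concentration
is the exact per-metabolite mean over samples, so QC (pool vs. pool)
ratios are exactly 1 in truth.  `simulate_run()` emits Gaussian
chromatographic peaks (8 s FWHM, 1 scan/s), per-channel lognormal
amplitude noise (σ = 0.1, the dominant ratio-error term), per-scan
jitter (σ = 0.05), Gaussian m/z error (3 ppm SD, consistent with a
~12,000-resolving-power TOF), shared RT jitter (3 s SD, preserving
co-elution), M+1 natural-isotope satellites (abundance ≈ carbon count
× 1.1%), a detection threshold, and sparse chemical-noise centroids
just above that threshold.  The noise centroids matter: they ground
the picker's signal-to-noise estimate the way real chemical background
does.  Under these defaults the median relative error of recovered
pair ratios is ≈9–10%, comfortably inside the <20% accuracy
characteristic of this chemistry — the error scale was chosen from
the per-channel noise model, not tuned to the bound.

What the simulator does **not** emulate: retention-time warping
between runs (all runs share an axis, so alignment needs no RT
correction), batch/day effects, ion suppression that varies by
co-elution context (dropout is a flat per-run probability instead),
adducts other than [M+H]^+^, multiple charge states, and MS/MS.
Passing tests therefore demonstrate the correctness of the pipeline's
logic under idealized chromatography, not robustness to
instrument-specific artifacts.

## Detection and quantification

`extract_features()` bins centroids into EIC traces by a 10 ppm
tolerance on the sorted m/z axis, tolerates one missing scan inside a
trace, and splits traces at valleys that drop below half of the lower
adjacent apex.  A peak needs ≥4 scans and an apex above 3× the run
noise level, estimated as the median intensity of centroids in traces
too short to be chromatographic peaks.  `pair_features()` then finds
co-eluting features spaced *n* × 2.00671 Da apart (n = 1–3, 10 ppm
relative to the light m/z, inclusive boundaries, apexes within 10 s),
excludes light candidates that are themselves +1.003355 Da satellites
of a stronger co-eluting feature, and assigns features to at most one
pair greedily by summed area (ties: lower m/z, then fewer tags).
These four predicates are the minimal set that makes pairing
unambiguous; on small feature sets the implementation is tested
against an exhaustive all-pairs oracle applying the same rules.

`quantify_pairs()` reports two ratios per pair: the MS ratio at the
shared apex scan and the chromatographic ratio — light area over heavy
area within the intersection of the two RT windows.  The
chromatographic ratio is what propagates downstream, as it averages
over the whole elution profile.

## Assembly of the ratio table

`align_runs()` clusters pairs across runs greedily in descending
intensity order against running intensity-weighted consensus m/z/RT
(10 ppm, 20 s), never letting one run contribute twice to a row; the
ordering rule makes the result deterministic, and every input pair
lands in exactly one cell.  `zero_fill()` revisits the raw centroids
of each run at the consensus coordinates of missing cells with a
relaxed threshold (1× noise instead of 3×) and fills the cell only
when both channels are found on ≥3 scans — completeness is monotone
and detected values are never touched.  `presence_filter()` keeps rows
observed in strictly more than 50% of the sample runs ("more than
50%" is a strict inequality; zero-filled cells count as present, and
QC columns are excluded from the count).

`lcuv_normalize()` mirrors the equal-mole normalization step: volumes
inversely proportional to the LC-UV total concentration, with samples
outside 50–150% of the study mean flagged but retained.

## Chemometrics

Before modeling, missing cells are imputed with half the row minimum
(standard for left-censored missingness), log-transformed, centered,
and unit-variance scaled.  `cil_pca()` is an SVD with 7-fold
venetian-blind cross-validation in which each held-out entry is
predicted by a leave-one-variable-out projection onto the training
loadings (so the prediction never uses the entry itself), pooling
PRESS into Q².  `cil_oplsda()` implements single-response O-PLS:
orthogonal components are stripped by orthogonal signal correction
before one predictive component is fit; with zero orthogonal
components the model is exactly one-component PLS-DA, which the test
suite verifies against an independent PLS implementation.  Q² again
uses 7-fold venetian blinds, and a permutation mode refits under
shuffled labels (sound models give permuted Q² ≤ 0).

`volcano_compare()` averages ratios on the natural scale for fold
changes (the convention for reported peak-ratio fold changes), takes
p-values from Welch's t-test on log ratios (the paper-style workflow
does not specify the variant; Student is available via `var_equal`),
and flags rows with fold change ≥1.2 **and** p ≤ 0.05, with no
multiple-testing correction by default and an optional FDR mode.
Rows with fewer than two observations per group are reported as
untestable rather than silently dropped.

## Time-course marker selection

The selection logic chains four rules:

1. **Per-week significance.** Disease vs. control volcano comparisons
   at weeks 2, 4 and 6; a candidate must be significant, with a
   consistent direction, in all but at most one week (the
   "one-missing" tolerance).
2. **Gradual change.** The candidate's disease/control ratio of group
   means over weeks 0–6 must reach a net 1.3-fold change with no
   adjacent step opposing the net direction by more than 0.75× the
   net log change.  Both numbers come from the sampling properties of
   group means: with six animals per group the standard error of a
   group-mean ratio is ≈8–12%, so (a) a fixed 10% per-step
   monotonicity rule would reject genuinely monotone trajectories at
   an unacceptable rate — opposing steps of that size are expected
   sampling noise, hence the generous, net-change-relative backtrack —
   and (b) the net-change requirement, which carries the selectivity
   against drifting metabolites, must sit above what four noisy group
   means produce by chance (a 1.2-fold net alone would pass roughly a
   fifth of purely drifting trajectories; 1.3-fold brings that under
   10% while costing well under 1% of true 2-fold markers).
3. **Treatment response.** Early-vs-final treatment-week volcano
   comparisons within each treatment arm, intersected across arms
   with the same one-missing tolerance.
4. **Reversion to control.** In at least half of the treatment arms,
   the final-week treated group must either show *no* significant
   volcano difference from the control arm (the 1.2-fold prong is
   precisely a ±20% band around the control level) or have traveled
   at least half of the final-week control–disease log gap away from
   the disease level, toward the control.  The relative clause is
   the operative notion of reversion — the large disease/control
   difference reduced to (nearly) no difference — and anchoring the
   distance at the disease arm makes the rule robust to sampling
   noise in any single reference group: all treated arms are
   compared against the *same* six control animals, so a chance off
   draw of that one group would otherwise fail every arm at once for
   a truly reverted marker, whereas a disease-anchored distance puts
   the shared term on both sides of the inequality where it largely
   cancels.  Markers that stay shifted (disease-only trajectories)
   travel no distance from the disease level and fail both clauses
   in every arm.

`cross_reference()` intersects the disease and treatment-response
lists (directions must agree) and ranks by completeness at the run
and sample level.  On the default simulated study this chain returns
exactly the planted treatment-reversing metabolites with no false
positives: disease-only metabolites die at rule 3–4, random-drift
metabolites at the conjunction of rules 1, 3 and 4.

## Numerical and scale choices

- Ties and degenerate inputs: pairing and alignment order by
  intensity then m/z, making outputs independent of input order;
  empty runs raise errors while empty pair lists propagate as empty
  tables; a valley splits two peaks only below 50% of the lower apex
  so apex-level jitter cannot shatter a peak.
- All tolerances are inclusive at the boundary; ppm windows are
  relative to the light m/z.
- Problem sizes: the bundled tests exercise a compact study (two
  control/disease arms over five weeks, two to three treatment arms,
  4–6 rats, duplicate injections, 60–300 metabolites) chosen so the
  group sizes, effect sizes and noise match the full design's
  statistical power per comparison; the acceptance script runs the
  complete 39-group design (514 injections, 300 metabolites) in a few
  minutes.  The 20-replicate recovery experiment uses the compact
  design with 300 metabolites and all 11 planted markers.
- Tag-count mixture defaults to 80/15/5% for 1/2/3 tags; the true
  distribution over a real submetabolome is unknown, and the value is
  configurable.
- Library retention times bundled with the package are synthetic
  placeholders on the simulated RT axis; real standard libraries use
  normalized RT, for which a mapping hook (`rt_tol`, custom library
  CSVs) is the extension point.

## Known limitations

Q² values from 7-fold venetian blinds are comparable in spirit, not
numerically, to other software's output on other data.  The zero-fill
re-search trusts the consensus coordinates, so a row built from a
mis-aligned cluster would be filled at the wrong coordinates.  The
greedy one-pair-per-feature rule can mis-assign when two metabolites
co-elute within the ppm window; at realistic metabolome densities
(hundreds of pairs over a 1300 s gradient) this is rare, and tag-count
agreement in simulation exceeds 99%.  OPLS-DA is implemented for a
single binary response only.
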