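# cilquant

Quantitative metabolomics for **chemical isotope labeling (CIL)
LC-MS** studies, in which each metabolite is derivatized twice — with
a light (^12C) reagent applied to the individual sample and a heavy
(^13C2) reagent applied to a pooled reference mixed into every
injection — and therefore appears as a co-eluting **peak pair** whose
light/heavy intensity ratio measures the sample's concentration
relative to the pool. The package targets the dansylation
(amine/phenol submetabolome) flavor of this chemistry and the
longitudinal disease/treatment designs it is used for: tracking a
disease model over time and asking which metabolites shift with the
disease and revert under treatment.

It is aimed at method developers and computational metabolomics
researchers who need a fully testable, ground-truth-driven
re-implementation of this workflow: every stage can be exercised on
simulated labeled runs whose true design, trajectories, and ratios
are known.

## The model in brief

For an *n*-tag metabolite of neutral monoisotopic mass *M*,
dansylation places the protonated ions at

```
m/z_light = M + n x 233.05105 + 1.007276
m/z_heavy = m/z_light + n x 2.00671        (two 13C per tag)
```

(for dansyl-serine: 339.10092, matching the observed 339.1023 within
the 10 ppm instrument window). The pipeline is:

1. **simulate** — a 39-group rat osteoarthritis-style study (normal /
   sham / OA arms weeks 0–14, four treatment arms weeks 8–14, 6 rats
   per group, duplicate injections, QC every 10 runs → 234 samples,
   468 sample runs, 46 QC injections) with planted biomarker
   trajectories and instrument noise;
2. **detect** — EIC peak picking, ^12C/^13C peak pairing with
   natural-isotope exclusion, chromatographic-ratio quantification;
3. **assemble** — cross-run alignment into the metabolite-intensity
   (ratio) table, zero-filling of missing cells from raw centroids,
   presence filtering (> 50 % of runs), LC-UV equal-mole
   normalization records;
4. **annotate** — positive identification against a dansyl standard
   library (10 ppm + 60 s), then mass-only matching;
5. **stats** — PCA and OPLS-DA with 7-fold cross-validated Q²,
   volcano comparisons (≥ 1.2-fold and p ≤ 0.05);
6. **markers** — per-week significant sets, cross-time intersection
   with one-missing tolerance, gradual-trend filtering, and
   disease-marker x treatment-response cross-referencing.

## Worked example

```r
library(cilquant)

build_design()
#> CIL study design: 39 groups, 234 samples, 468 sample runs, 46 QC injections

res <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)

res$table
#> CIL ratio table: 300 aligned pairs x 514 runs
#>   (152692 detected, 32 zero-filled, 1476 missing cells)

res$markers
#> CIL marker selection: 63 disease markers, 11 treatment-response
#>   markers, 11 final candidates

res$stats$oplsda
#> OPLS-DA (1 predictive + 1 orthogonal): R2X = 15.3%, R2Y = 93.9%, Q2 = 73.4%

head(res$markers$markers, 3)
#>     row_id direction net_fold completeness_runs completeness_samples
#> 1: row0109         1 1.805940         0.9978632                    1
#> 2: row0224         1 2.439430         0.9935897                    1
#> 3: row0073         1 1.891587         0.9935897                    1

table(res$annotation$tier)
#> identified    unknown
#>         10        290

head(res$annotation[res$annotation$tier == "identified", ], 3)
#>     row_id       tier      top_match n_candidates
#> 1: row0020 identified           GABA            1
#> 2: row0023 identified         serine            1
#> 3: row0034 identified pipecolic acid            1
```

Reading the output: all 300 simulated metabolites were detected,
aligned and (almost entirely) quantified across the 514 injections;
the disease arm separates from its control with a cross-validated Q²
of 0.73; and the time-course selection returns exactly the 11
metabolites that were planted with disease-rising,
treatment-reverting trajectories — each rising (`direction = 1`),
with net fold changes near the planted 2-fold and near-complete
run/sample coverage, mirroring how real candidates are reported.

The same stages are scriptable from a shell via
`inst/cli/cilquant-cli.R` (subcommands `simulate`, `detect`,
`assemble`, `zerofill`, `filter`, `annotate`, `stats`, `volcano`,
`markers`, `run-all`), exchanging CSV intermediates in a working
directory.

See `vignettes/cilquant-methods.Rmd` for the full account of the
models, noise parameters, and design choices.

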