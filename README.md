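# grscreen

Analysis pipeline for plate-based *ex vivo* drug sensitivity screens of
patient-derived tumor cells, built around normalized growth-rate inhibition
(GR) metrics. The package covers the full arc of a screening campaign —
primary library triage, multi-technique validation, dose–response potency
estimation, and fixed-ratio drug-combination analysis — together with a
seeded synthetic 384-well screen generator that provides ground truth for
every statistical step.

## The problem

Endpoint viability screens confound drug effect with how fast the cells
happen to divide during the assay window: a slowly growing primary culture
makes every drug look weak on a percent-viability scale, and the same drug
panel screened in 2D and 3D culture (where division rates differ) produces
incomparable numbers. GR metrics fix this by scoring drug response *per
cell division*.

With `x` the treated signal, `x0` a no-division reference and `x_ctrl` the
untreated control,

    GR(x) = 2^( log2(x / x0) / log2(x_ctrl / x0) ) − 1

so GR = 1 means uninhibited growth, GR = 0 complete cytostasis, and
GR < 0 net cell kill, on any assay technique and at any division rate. An
endpoint screen has no day-0 read, so this package uses the 2 mM
hydroxyurea proliferation-stall control median as `x0` and the 0.05% DMSO
negative-control median as `x_ctrl`, both per plate. That convention makes
the hit rule literal: **a compound is nominated when GR < 0 at every tested
dose** — more inhibitory than the hydroxyurea stall across the whole
dilution series — and the library is ranked by mean GR across doses.

The culture's division rate itself comes from the same controls:
doublings per window `k·T = log2(neg_median / hu_median)`, doubling time
`T / (k·T)` hours.

Around this core the package provides:

* **GR dose–response curves** `GR(c) = GR_inf + (1 − GR_inf) / (1 + (c/GEC50)^h)`
  by bounded multi-start least squares, with a flat-line F-test fallback,
  GR50 crossing and GR-AOC;
* **Percent-viability 4PL fits** (top, bottom, hill, relative EC50) with
  the absolute IC50 solved analytically from the fitted curve and censored
  outside the tested range;
* **Chou–Talalay combination analysis**: median-effect fits
  `log10(fa/fu) = m·log10(D) − m·log10(Dm)` for each single agent and for
  the fixed-ratio mixture (total dose), and the combination index
  `CI = d1/Dx,A + d2/Dx,B` at chosen effect levels (CI50 at fa = 0.5;
  < 1 synergy, 1 additivity, > 1 antagonism);
* **Screen-level statistics**: per-dose Pearson concordance between assay
  techniques, top-30 overlap, average-linkage hierarchical clustering on
  1 − r distance, and Welch's t across dilution series
  (doses-as-replicates);
* **A synthetic screen generator** that inverts the GR definition, so the
  expected well counts of any planted drug are exactly consistent with its
  ground-truth GR curve at any division rate — the basis for all
  recovery and equalization tests.

## Worked example

A small simulated plate (8 compounds, three 2-fold doses from 5 µM,
two planted cytotoxic drugs, 5% noise) ships as plain CSV:

```r
library(grscreen)
readout <- system.file("extdata", "example_readout.csv", package = "grscreen")
map     <- system.file("extdata", "example_plate_map.csv", package = "grscreen")
run <- assay_run(read_screen_table(readout, map), "imaging_2d")
estimate_growth(run)
#> <growth_estimate> 0.300 doublings / 72 h (doubling time 240.4 h)
hits <- call_hits(gr_table(run))
hits[c("compound_id", "mean_gr", "is_hit", "rank")]
#>  compound_id    mean_gr is_hit rank
#>        C0002 -0.5522354   TRUE    1
#>        C0001 -0.4677902   TRUE    2
#>        C0007  1.0051463  FALSE    3
#>        ...
```

The control medians recover the culture's 240-hour doubling time (0.3
divisions over the 72-h window), and exactly the two planted cytotoxic
compounds are nominated: their GR is below zero at all three doses, while
the inactive compounds sit at GR ≈ 1. `gr_profiles()` adds the fitted
GR curves, `viability_curves()` the 4PL/IC50 table, and
`combination_result(simulate_combo_matrix(...))` a CI50 for a 6×6
fixed-ratio matrix.

## Analysis workflow

The `analysis/` scripts run the full campaign on the synthetic screen and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_primary_screen.R` | 1160-compound primary screen, 49 planted hits |
| `02_growth_and_hits.R` | growth estimate, GR, hit nomination and ranking |
| `03_validation_concordance.R` | top-90 re-screen on three techniques, concordance, clustering |
| `04_dose_response.R` | 4PL viability fits and absolute IC50s |
| `05_combination.R` | fixed-ratio 6×6 matrices and Chou–Talalay CI50s |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript $f; done`

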