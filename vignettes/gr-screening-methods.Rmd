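---
title: "Growth-rate normalized screening analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate normalized screening analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscreen)
```

## The measurement model

An endpoint viability screen reads one signal per well after an assay
window of `T` hours (72 by default): luminescence for enzymatic assays
(ATP-proportional), or a nuclei count for image-based assays. Each 384-well
plate carries three control groups — 0.05% DMSO wells (untreated growth),
2 mM hydroxyurea wells (proliferation stalled, cells alive), and 5 µM
staurosporine wells (killed). Per-plate medians of these groups anchor all
normalization; the median is used because single clogged or empty control
wells are routine in high-throughput screening and the median ignores them.

Two normalized scales are derived per treated well:

* **Percent viability**, `100 · (x − pos) / (neg − pos)`: a linear scale
  anchored at the staurosporine floor (0) and the DMSO median (100),
  deliberately unclipped, so wells that outgrow the negative control are
  visible.
* **Normalized growth-rate inhibition**,
  `GR = 2^(log2(x/x0) / log2(x_ctrl/x0)) − 1`, with `x0` the hydroxyurea
  median and `x_ctrl` the DMSO median of the same plate.

The GR scale is the package's core. Exponent arithmetic shows its defining
property: if the culture makes `k·T` doublings in the window, a drug that
lets cells make a fraction `g` of those divisions scores the same GR no
matter what `k·T` is. Division-rate differences between assay techniques —
2D vs 3D culture, fast vs slow primary cells — therefore cancel exactly,
which is what makes cross-technique comparison of a drug panel meaningful.

Two assumptions matter and should be stated plainly:

1. **Hydroxyurea as the time-zero surrogate.** A true GR computation uses a
   day-0 cell count. An endpoint screen has none, so the stalled-well
   median stands in for it. This assumes 2 mM hydroxyurea arrests division
   without killing over 72 h. The payoff is that "GR < 0" becomes a
   directly interpretable statement — stronger than the stall — and the hit
   rule inherits that meaning. If hydroxyurea partially kills, `x0` is
   biased low and all GR values shift upward; the package flags plates
   whose control ordering `neg ≥ hu ≥ pos` fails, but cannot detect a
   partially lethal stall.
2. **Per-plate normalization.** Controls are summarized per plate, not per
   run, so plate-to-plate drift (reagent batch, edge evaporation, imaging
   session) is absorbed locally. This is standard HTS practice; it costs
   nothing when plates are homogeneous.

The division rate itself is estimated from the same two medians:
`k·T = log2(neg/hu)` doublings per window, doubling time `T/(k·T)` h. A
culture with `neg ≤ hu` is flagged as non-growing and GR computation is
refused rather than silently producing nonsense.

## Dose–response models

**GR curves.** `GR(c) = GR_inf + (1 − GR_inf)/(1 + (c/GEC50)^h)`, with
`GR_inf ∈ [−1, 1]` (asymptotic response; < 0 = cytotoxic), `GEC50 > 0` µM
(half-effect dose) and `h ∈ [0.1, 5]` (steepness). The upper asymptote is
pinned at 1 — an untreated well is by construction at GR 1 — so only three
parameters are free. Fits are bounded least squares (Levenberg–Marquardt
via `minpack.lm`) on `log10(GEC50)`, started from three log-spaced GEC50
values across the tested range, using every replicate well (not dose
means): with five-dose designs the extra degrees of freedom materially
improve identifiability. An F-test against the flat mean at α = 0.05
decides whether the sigmoid is warranted; otherwise the profile falls back
to the constant mean with `GR_inf` reported as that mean and GR50 censored.
This keeps inactive drugs (flat at 1) and fully saturated cytotoxics (flat
below 0, no dose trend in range) honest: both are flat lines, and the mean
GR still ranks them correctly. GR50 (the dose where the fitted curve
crosses 0.5) is solved analytically and censored when `GR_inf ≥ 0.5`;
GR-AOC is the trapezoidal integral of `1 − GR` over `log2(dose)`
normalized by the log-range, a ranking diagnostic only.

**Viability 4PL.** `y(c) = bottom + (top − bottom)/(1 + (c/EC50)^h)` with
`top ∈ [50, 150]`, `bottom ∈ [−10, 60]`, `h ∈ [0.1, 5]`, EC50 log-bounded
to two decades beyond the tested range. Two potency numbers are reported
because they answer different questions: the **relative EC50** (inflection
dose) and the **absolute IC50**, the dose where the fitted curve crosses
50% viability, solved in closed form
`IC50 = EC50 · ((top − 50)/(50 − bottom))^(1/h)` and censored
(`>max_dose`, `<min_dose`) when the crossing lies outside the bounded
range. Headline potencies are absolute IC50s — the common convention for
viability screens — with the relative EC50 retained beside them. With only
three dose points the hill slope is fixed at 1 (a free slope is not
identifiable from three points). Dose-0 wells never enter fits; no
weighting is applied.

## Combination analysis

Combinations are analyzed on the percent-viability scale (not GR) with the
classic mutually-exclusive Chou–Talalay formulation. For each single agent
and for the fixed-ratio mixture treated as one virtual drug in *total*
dose, the median-effect line `log10(fa/fu) = m·log10(D) − m·log10(Dm)` is
fitted by ordinary least squares, where `fa = 1 − viability/100` and
`fu = 1 − fa`. Only points with `fa ∈ [0.005, 0.995]` are used —
near-degenerate wells are discarded, not squashed to the band edge, which
would distort the line. Replicate wells are averaged before linearization.
A fit needs ≥ 2 usable points and a positive slope; anything else is
flagged invalid and propagates.

From a 6×6 dose matrix (drug A in six 3-fold dilutions from 2 µM, drug B
from 5 µM, every cell in triplicate, plus the partner-dose-0 margins), the
diagonal — both drugs diluting in matched steps — forms the fixed-ratio
series with constant molar ratio `R = d_B/d_A = 2.5`, checked to 1e−6
relative. The combination index at effect level `x` is

    CI_x = d1 / Dx_A + d2 / Dx_B,    d1 = D_mix/(1+R),  d2 = D_mix·R/(1+R)

with `Dx = Dm·(x/(1−x))^(1/m)` for each fit. CI50 is CI at `fa = 0.5`.
A sham self-combination (a drug combined with itself) gives CI ≡ 1 at
every effect level directly from the algebra — the package's tests verify
this identity exactly, and verify `compute_ci` against a numerical
root-finding oracle that never uses the closed form.

The mixture is fitted on total dose (standard Chou–Talalay); whether to
fit on the drug-A component instead is a genuine ambiguity in fixed-ratio
designs, and total dose was chosen once and documented here.

## The synthetic screen generator

The generator exists so that every statistical claim in the package can be
tested against known truth. It *inverts* the GR definition: a drug with
ground-truth curve `GR_true(c)` planted in a culture making `k·T`
doublings from `x0` seeded cells produces the expected endpoint count

    x(c) = x0 · (x_ctrl/x0)^(log2(GR_true(c)+1)),   x_ctrl = x0 · 2^(k·T)

so the downstream GR computation recovers `GR_true(c)` *exactly* in the
noise-free case, at any division rate. DMSO wells grow to `x_ctrl`,
hydroxyurea wells stall at `x0`, staurosporine wells decay to 2% of
seeding (a log-safe floor rather than exactly zero). Enzymatic runs report
`gain × count` luminescence; imaging runs report counts. Noise is
multiplicative lognormal with unit mean: signals are positive and HTS
coefficients of variation are scale-proportional, which plain additive
Gaussian noise would misrepresent.

Default study conditions (chosen once, as the conditions the emulated
screening campaign describes): a 1160-compound library at three 2-fold
doses from 5 µM, single wells per dose; 384-well plates with 14 DMSO, 14
hydroxyurea and 8 staurosporine wells in the leftmost columns and 348
treated wells (ten full plates for the library); division rates 0.6 / 0.5
/ 0.3 doublings per 72 h for imaging-2D / enzymatic-2D / imaging-3D (the
primary-culture fixture uses 0.3 throughout, a 240-h doubling time);
seeding 1000 cells in 2D and 2000 in 3D; noise CV 0.05 (a typical
plate-reader CV); 49 planted fully cytotoxic drugs with
`GR_inf ∈ [−0.95, −0.5]` and GEC50 two to three decades below the lowest
dose, so their GR is below zero at every tested dose by construction;
40% of the remaining drugs are partial responders with
`GR_inf ∈ [0.3, 0.95]`, the rest inactive at `GR_inf = 1`. The margin
between planted hits (≤ −0.5) and the weakest partial responders (≥ 0.3)
is deliberate: at 5% signal CV and 0.3 doublings, noise on GR is large
enough that a gap-free population would make "exactly N nominated hits"
a coin flip rather than a property of the screen.

Combination matrices support four interaction modes: `independent`
(combined survival = product of single-agent survivals, i.e. Bliss — a
generator convention only, CI is computed downstream regardless), `synergy`
/ `antagonism` (both GEC50s divided/multiplied by a factor wherever both
drugs are present), and `sham` (the same drug responding to total dose).

What the generator does **not** emulate: edge effects and spatial plate
gradients, imaging segmentation errors, spheroid morphology, carry-over,
or drug-specific deviations from the sigmoid shape. Passing tests
therefore demonstrate correctness of the *computation*, and the
noise-propagation behaviour of the *statistics*, on idealized plates —
not robustness to spatial artifacts in real screens.

## Numerical choices

* Signals are floored at `max(1e−6, 1e−4 · pos_median)` before logs; GR is
  clipped below at `−1 + 1e−12` so the kill limit is representable without
  reaching −1 exactly.
* Non-convergence of any bounded fit, or a fit that cannot beat the flat
  mean, yields the flat fallback (GR curves) or a censored curve (4PL) —
  never a silent extrapolation.
* Clustering uses `1 − Pearson` distance with average linkage (the common
  configuration of classic clustering tools for dose-response heatmaps;
  the choice is a documented assumption, not derivable from first
  principles). Rows are pre-sorted by compound id so ties break
  deterministically; zero-variance rows are treated as uncorrelated.
  Missing cells are imputed by row mean and flagged.
* Welch's t across a dilution series treats doses as biological
  replicates. This is a fidelity choice mirroring screening practice under
  scarce primary material, not an endorsement: doses are not exchangeable
  replicates, and the resulting p-values should be read as descriptive.
  Degenerate inputs (both vectors constant) return `p = 1` when means
  agree and are flagged otherwise.
* All randomness flows from one integer seed; equal seeds give
  bit-identical tables, and the pipeline writes byte-identical output
  bundles for equal configurations.

## Validation studies and their problem sizes

The packaged studies (shared by the test suite and the acceptance script)
use sizes chosen to characterize the statistics well while staying
desk-scale: the hit-rule fixture is the full 1160-compound library; the
cross-technique equalization check uses 60 drugs at five doses, noise-free;
parameter recovery uses 100 drugs at five 2-fold doses from 5 µM in
triplicate at 5% CV; the Welch null study uses 10 000 simulated pairs at
n = 5; concordance uses 90 drugs on three techniques.

The sham-combination consistency check runs at **one doubling per window**
with a negligible staurosporine floor. At one doubling the generated
survival fraction is exactly a Hill function of dose, the median-effect
model holds exactly, and CI50 = 1 is a sharp prediction. At the screening
division rates (0.3–0.6 doublings) the generated `fa` saturates below 1
and the median-effect line is only an approximation, so a sham CI50 there
reflects model mismatch (tens of percent) rather than pipeline error —
a useful reminder that Chou–Talalay fits assume the effect truly spans
(0, 1).

## Known limitations

* `GR_inf` recovery is information-limited at slow division rates: GR
  normalization divides log-signal noise by `k·T`, so a 5% signal CV
  becomes a ~10% CV on `GR + 1` at half a doubling per window. For drugs
  whose GEC50 sits near the top tested dose (plateau unobserved) or whose
  curves are shallow, the asymptote is weakly identified regardless of the
  fitting method; GEC50 is recovered much more robustly (fold-error well
  under 2). A recovery study quantifying this ships with the package.
* The hydroxyurea-stall surrogate for time zero cannot be validated
  internally (see assumptions above).
* IC50s are censored, not extrapolated, outside two decades of the tested
  range; partial responders whose curves never cross 50% viability have no
  absolute IC50 by design.
* No response-surface synergy models (Loewe, ZIP, MuSyC): CI only.
* No multiple-testing correction is applied anywhere; the hit rule and
  Welch comparisons are reported raw.
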