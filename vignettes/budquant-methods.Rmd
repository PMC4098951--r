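---
title: "Quantifying tumour budding, lymphatic vessel density and invasion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour budding, lymphatic vessel density and invasion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumour budding (TB) — single cells or small clusters of up to five tumour
cells detached from the invasive front — lymphatic vessel density (LVD) and
lymphatic vessel invasion (LVI) are prognostic features in colorectal
cancer, but their manual scoring on stained sections suffers from strong
inter-observer variability and no agreed counting protocol. Multiplexed
immunofluorescence makes all three features visible on a single section:
DAPI marks every nucleus, pan-cytokeratin (panCK, "Marker 1") marks
epithelium, and D2-40 (podoplanin, "Marker 2") marks lymphatic endothelium.
`budquant` implements a fully scripted image-analysis pipeline over such
three-channel fields plus the downstream survival statistics, so that the
entire path from pixels to hazard ratios is reproducible and testable.

## Pipeline

The pipeline mirrors a three-step digital-pathology workflow, each step a
separate module surface.

**Step 1 — tissue segmentation.** A supervised per-pixel classifier
assigns each pixel to Tumour, Stroma, NecrosisLumen or NoTissue. The
commercial tool originally used for this step is a black box; here the
classifier is a random forest over a documented per-pixel feature stack
(raw intensity per channel, Gaussian-smoothed intensities at two or more
scales, and a windowed local variance as a texture cue;
`pixel_feature_config()`). Training uses sparse annotation strokes
(`region_annotation()`), emulating a pathologist marking up representative
areas, with a stratified held-out split reporting pixel accuracy. Because
downstream stages consume only the resulting label map, the classifier is
swappable; its contract is recovery of planted region masks on synthetic
fields. After per-pixel prediction, connected label regions smaller than
`min_region_area_um2` (default 100 µm²) are absorbed into the largest
adjacent region; ties take the fixed priority Stroma > Tumour >
NecrosisLumen > NoTissue so the clean-up is deterministic.

**Step 2 — object segmentation.** Nuclei, panCK objects and D2-40 objects
are segmented by intensity and area thresholds. Marker fluorescence varies
between sections, so thresholds are selected per section: a manual value
always wins (`select_marker_threshold(..., manual_value = )`); otherwise a
bimodal-histogram (Otsu) threshold is computed over tissue pixels only,
implemented on the intensity histogram directly so that NoTissue pixels can
be excluded. Because the lymphatic channel's positive class can be a tiny
fraction of the pixels — a regime in which plain Otsu prefers splitting the
dominant background mode — candidate thresholds are restricted to lie above
a robust background floor (median + 3 × MAD-σ of the pixel distribution)
before the Otsu criterion picks among them. Components are 8-connected everywhere, and components under
`min_marker_area_um2` (default 5 µm², below any meaningful bud fragment)
are dropped. Touching nuclei are split by a distance-transform watershed;
an optional minimum-solidity filter (off by default) stands in for further
nuclear morphometrics, which the source workflow names but does not define.

**Step 3 — object optimisation and hierarchical classification.** The
constants of this step live in `classification_params()`:

| parameter | default | meaning |
|---|---|---|
| `debris_area_um2` | 16 | nuclei strictly under this area are debris |
| `edge_distance_um` | 50 | marker objects within this distance (inclusive) of NoTissue are edge effect |
| `merge_gap_um` | 0 | stromal merge gap; 0 = 8-connected touching |
| `association_min_fraction` | 0.5 | fraction of a nucleus' area that must lie inside a marker object (strict >) |
| `lvi_minimum_overlap_px` | 1 | minimum bud-vessel pixel overlap for an LVI event |

Boundary semantics are read literally: "under 16 µm²" and "over 5 nuclei"
are strict inequalities, "within 50 µm" is inclusive. Autofluorescent
structures (e.g. muscle in the epithelial channel) are suppressed by an
object-level signature — mean intensity inside a configured window combined
with the median of the windowed local variance over the object's pixels.
The median (not the mean) is used because boundary pixels of genuinely
bright objects carry huge local variance; the median isolates interior
texture. The same mechanism can be pointed at DAPI artefacts
(`flag_false_nuclei()`, disabled by default).

Surviving stromal panCK objects are merged across `merge_gap_um` and
classified by associated nucleus counts into `irrelevant_marker` (none),
`bud_with_debris_nucleus` (debris only), `tumour_bud` (1–5 true nuclei) and
`large_bud` (>5). The nucleus-association rule is not defined in the
source workflow; the majority-area rule adopted here (> 50 % of the
nucleus' pixels inside the object) reproduces the documented exclusion of a
stromal-nucleus sliver clipped by a bud, and the fraction is configurable.
D2-40 objects are merged the same way and each merged wall is combined with
its enclosed lumen by hole filling; an open, unclosed wall encloses nothing
and keeps an empty lumen. LVI is then pixel co-localisation: one event per
(tumour bud, vessel) pair overlapping by at least one pixel. Candidacy
defaults to `tumour_bud` only, matching the 1–5-cell definition of budding;
`include_large_buds = TRUE` extends it, since the figure illustrating
invasion does not state the class of the invading object. Counting is
per pair — a bud entering two vessels is two events — with the per-invaded-
vessel alternative available by deduplicating `vessel_id` in the event
table; the "vessel border" display class of the original figure is treated
as visualisation only.

**Quantification.** Per field: TB count, small-bud (1–2 nuclei) and
large-bud counts, LVI count, and LVD = 100 × vessel area / stromal area.
The stromal denominator keeps the vessel pixels it contains ("vessel
percentage of stroma" does not exclude vessel area, and for small vessel
fractions the choice is numerically immaterial); `exclusive_stroma = TRUE`
switches to the exclusive denominator. Per patient, the 15 fields with the
most LVI events are selected (ties by field id, a stable documented rule),
TB and LVI are totalled over exactly those fields, and LVD is their
arithmetic mean. Fewer than 15 available fields are all used, with a
warning and `n_fields_used` recorded, since 15 is the capacity of the
smallest section's invasive front rather than a hard requirement. Bud-size
variant totals (1–2, >5, and 1–5 plus >5 summed) support re-categorisation
sensitivity analyses. Patients are dichotomised strictly above a cut-off
(a value equal to the cut-off falls below, consistent with ">cut-off"
group naming).

## Survival statistics

Cut-offs are derived by a minimum-p scan: candidates are the midpoints
between consecutive distinct values, splits leaving fewer than 10 % of
patients on either side are excluded (a standard guard against degenerate
minima; the floor is configurable), the two-group log-rank statistic is
computed at each candidate, and the maximiser wins, ties towards the
smaller cut-off. The scan is a vectorised Mantel–Cox computation over
cumulative at-risk and event matrices with patients sorted by the scanned
variable, so a full scan costs little more than one log-rank test; the
per-candidate statistics agree with `survival::survdiff` to machine
precision, and that agreement is a standing test.

The minimum p over a search is optimistically biased, so
`monte_carlo_corrected_p()` re-runs the entire search on `n_sim`
permutations (default 1000) of the feature against the survival records and
reports `(1 + #{simulated min-p ≤ observed min-p}) / (1 + n_sim)`. The
original workflow describes its correction as cross-validation within
Monte Carlo simulations without further detail; the permutation null of the
full search is the standard published equivalent, and an optional
split-sample mode (`method = "split"`: derive the cut-off on a random half,
test it on the other) is provided for users who want a held-out p-value
instead. Cut-offs derived on a full cohort can be applied to a
subpopulation by calling `dichotomise()` on the subgroup, keeping the
derive and apply steps explicit.

Kaplan–Meier estimation, the log-rank test and Cox regression are delegated
to the `survival` package; ties use the Efron approximation. All analyses
accept a restriction horizon (e.g. 5 years: later follow-up is
administratively censored). Log-rank p-values across features are
FDR-corrected by Benjamini–Hochberg; pairwise Pearson correlations between
features are Bonferroni-adjusted for the family size. Cox fits flag
suspected separation (|coef| > 10) and refuse clearly non-converged models.

## The synthetic data generator

Clinical images cannot ship with the package, so `generate_field()` renders
fields in which every downstream contract is checkable against exhaustive
ground truth: a no-tissue border with a wavy edge, a stromal compartment,
an optional tumour mass with an invasive front and a necrosis/lumen pocket,
buds as epithelial disks carrying exactly the requested number of nuclei
(each ≥ 16 µm², placed on a phyllotaxis layout grown until a 3-px
separation holds), vessels as 2–4-px annular walls with lumina at
background intensity (so hole filling is genuinely exercised), planted
bud-in-vessel events overlapping the wall by a few pixels, debris nuclei
under 16 µm², edge-zone staining within 50 µm of the border, and textured
mid-intensity autofluorescence streaks distinguishable by the
local-variance statistic. Objects are placed by rejection sampling with a
minimum 3-px separation per mask, bounded at 1000 retries, so
connected-component counts equal planted counts exactly and exact-count
tests are valid. All randomness flows from the single spec seed;
generation is bit-identical under a repeated seed.

Default conditions: 512 × 512 px at 0.5 µm/px (a typical 20× field crop),
foreground/background intensity contrast around 0.8 vs 0.06 with additive
Gaussian noise of SD 0.05 — a high-signal regime appropriate for
tyramide-amplified immunofluorescence. The generator does **not** emulate
photorealistic histology: no point-spread blur, no intensity gradients
within objects, no scanner noise physics, no out-of-focus fields, and
region textures are far cleaner than real tissue. Passing recovery tests
therefore demonstrates the correctness of the object logic and the
statistical machinery, not segmentation robustness on real slides, where
thresholds and the tissue classifier would need per-cohort tuning.

`generate_cohort()` plants a survival structure directly at the feature
level: per-patient TB/LVI/LVD drawn from negative-binomial and gamma
distributions on the scales seen in invasive-front cohorts (TB totals in
the low hundreds, LVI totals in the tens, LVD below a few percent), coupled
by a log-normal latent factor so the three features correlate positively,
exponential survival with the hazard multiplied by `exp(log_hr)` above a
planted quantile cut-off (default: hazard ratio 3 above the 60th percentile
of the TB total), and independent exponential censoring with a rate matched
to the target censoring fraction. Exponential times make the planted
hazard ratio exact under proportional hazards, so Cox recovery and
confidence-interval coverage have a closed-form truth.

## Numerical and design choices

- Coordinates are 0-based row-major pixel centres with the origin at the
  top left; all areas are reported in µm² via `pixel_size_um²`.
- Connectivity is 8-connected everywhere, stated once and reused, so object
  counts are implementation-independent.
- Region clean-up absorbs small regions smallest-first and repeats until
  stable, which keeps the region count monotone non-increasing in the
  minimum-area parameter in practice.
- The per-section automatic threshold is Otsu restricted to tissue pixels;
  the original workflow's per-section manual assessment is preserved as the
  manual override, which always wins and is recorded for audit.
- Channel identification is by TIFF page order (DAPI, Marker 1, Marker 2)
  with a JSON sidecar carrying the pixel size — an open convention
  replacing the proprietary import step.
- Whole-slide (pyramidal) handling is out of scope: fields are the unit of
  analysis.

## Problem sizes in the test-suite

The packaged tests validate the contracts at sizes chosen to keep a full
run comfortable on a laptop: object recovery on ten clean and ten noisy
512-px fields; filter-oracle equivalence on 100 randomised object sets;
cut-point recovery on 100 cohorts of 200 patients; permutation-correction
calibration on 200 null cohorts of 60 patients at 200 permutations
(scaled down from the 1000 used in production settings); Cox coverage on
200 cohorts of 500 patients. The same quantities are recomputed from
scratch, at similar sizes, by `scripts/acceptance.R`.

## Known limitations

- The tissue classifier is trained and validated on synthetic textures;
  real sections require their own annotation strokes and will not reach
  synthetic accuracy.
- LVD uses whole-field stroma; restriction to an invasive-front band is
  not implemented.
- Only binary cut-offs are specified end-to-end; n-level groupings can be
  built manually from `dichotomise()` output but have no dedicated path.
- Competing risks, time-varying covariates and proportional-hazards
  diagnostics beyond convergence/separation checks are out of scope.
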