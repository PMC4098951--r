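# budquant

Quantification of **tumour budding (TB)**, **lymphatic vessel density
(LVD)** and **lymphatic vessel invasion (LVI)** from multiplexed-
immunofluorescence fields of the colorectal-cancer invasive front, with the
downstream survival statistics needed to relate the three features to
disease-specific outcome.

Manual scoring of these features on stained sections is poorly reproducible:
lymphatic vessels are easily confused with retraction artefact, and there is
no agreed bud-counting protocol. With a single multiplexed section — DAPI
(all nuclei), pan-cytokeratin ("Marker 1", epithelium) and D2-40
("Marker 2", lymphatic endothelium) — all three features can be measured by
image analysis. `budquant` implements that pipeline as scripted, tested R
code, for digital-pathology researchers who want the whole path from pixels
to hazard ratios to be reproducible.

## What it computes

Per 20×-style field:

1. **Tissue segmentation** — a trainable random-forest pixel classifier
   labels every pixel Tumour / Stroma / NecrosisLumen / NoTissue from
   intensity + texture features, after sparse stroke annotations.
2. **Object segmentation** — nuclei (DAPI, with watershed splitting) and
   marker-positive objects by per-section intensity and area thresholds
   (automatic Otsu-over-tissue or manual override).
3. **Object classification** — nuclei under 16 µm² become *debris*; marker
   objects within 50 µm of no-tissue become *edge effect*; textured
   mid-intensity autofluorescence is suppressed; stromal epithelial objects
   are merged and classified by associated nucleus count
   (majority-area rule) into *irrelevant marker* (0 nuclei), *bud with
   debris nucleus*, **tumour bud** (1–5 nuclei) and *large bud* (>5);
   D2-40 walls are merged with their filled lumina into **vessels**; pixel
   co-localisation of tumour buds with vessels yields **LVI events**.

Per patient, the 15 fields with the most LVI events are selected; TB and
LVI are totalled over them and LVD (vessel area as % of stromal area) is
averaged. The statistics layer provides minimum-p survival cut-points with
Monte Carlo (permutation) correction, Kaplan–Meier / log-rank with BH-FDR,
Cox regression (Efron ties) and Bonferroni-adjusted Pearson correlations.

A synthetic-field generator (`generate_field()`) with exhaustive ground
truth and a synthetic cohort generator (`generate_cohort()`) with a planted
feature–hazard link make every stage testable without clinical data.

## Worked example

```r
library(budquant)

# one synthetic field: 4 tumour buds (1,2,3,3 nuclei), 1 large bud,
# 3 vessels, 1 planted bud-in-vessel event, 3 debris nuclei
out <- generate_field(field_spec(
  n_buds_by_nucleus_count = c("1" = 1, "2" = 1, "3" = 2, "7" = 1),
  n_vessels = 3, n_lvi_events = 1, n_debris_nuclei = 3, seed = 42))

res <- process_field(out$field, out$truth$region_mask)
res$features[, c("tb_count", "small_bud_count", "large_bud_count",
                 "lvi_count", "lvd_percent")]
#>   tb_count small_bud_count large_bud_count lvi_count lvd_percent
#> 1        4               2               1         1   0.9993572
```

Every planted object is recovered: 4 tumour buds (2 of them with 1–2
nuclei), the 7-nucleus object is classified `large_bud` (not a bud count),
the planted invasion event is found, and the vessel area is ~1 % of stroma.

```r
# a 120-patient synthetic cohort with hazard ratio 3 planted above the
# 60th percentile of the TB total
coh <- generate_cohort(cohort_spec(n_patients = 120, seed = 7))
rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")

cp <- find_optimal_cutpoint(rec, "tb_total")
cp <- monte_carlo_corrected_p(rec, "tb_total", n_sim = 500, seed = 1,
                              result = cp)
cp
#> <cutpoint_result> tb_total: cutoff 269.5, chi-sq 46.64, raw p 8.53e-12,
#>   corrected p 0.002 (500 permutations)
coh$truth$cutoff
#> [1] 269
```

The scan recovers the planted cut-off (269.5 vs 269), and the corrected
p-value stays significant after accounting for the cut-off search. The
dichotomised group is then a Cox covariate:

```r
grp <- dichotomise(rec, "tb_total", cp$cutoff)
cox_regression(dplyr::mutate(grp, above = as.integer(group == "above")),
               "above")
#>    term       hr conf_low conf_high      p_value
#> 1 above 4.264452 2.732858  6.654409 1.677725e-10
```

The hazard ratio estimate (4.26, 95% CI 2.73–6.65) covers the planted
HR of 3 at this cohort size. `autoplot()` methods draw the Kaplan–Meier
curves and the cut-point scan profile; `survival_analysis()` bundles
cut-points, KM/log-rank with FDR, Cox and correlations for a whole feature
table, and `simulate_dataset()` / `quantify_dataset()` run the image
pipeline over a directory of fields. A thin CLI wrapper with `simulate`,
`quantify`, `survival` and `all` subcommands is installed at
`inst/cli/budquant.R`.

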