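test_that("spec validation enforces the planting invariants", {
  expect_error(field_spec(width_px = 100), class = "budquant_spec_error")
  expect_error(field_spec(n_buds_by_nucleus_count = c("3" = 1),
                          n_vessels = 3, n_lvi_events = 2),
               class = "budquant_spec_error")
  expect_error(field_spec(n_buds_by_nucleus_count = c("3" = 5),
                          n_vessels = 1, n_lvi_events = 2),
               class = "budquant_spec_error")
  # LVI events must be hostable by 1-5-nucleus buds
  expect_error(field_spec(n_buds_by_nucleus_count = c("7" = 2),
                          n_vessels = 2, n_lvi_events = 1),
               class = "budquant_spec_error")
  expect_error(field_spec(n_buds_by_nucleus_count = c("15" = 1)),
               class = "budquant_spec_error")
  expect_error(field_spec(autofluorescence_level = 1.5),
               class = "budquant_spec_error")
})

test_that("an all-zero spec yields an object-free field", {
  out <- generate_field(field_spec(
    n_buds_by_nucleus_count = integer(), n_vessels = 0, n_lvi_events = 0,
    n_debris_nuclei = 0, noise_sd = 0, seed = 1))
  expect_true(all(out$truth$nucleus_mask == 0))
  expect_true(all(out$truth$marker1_mask == 0))
  expect_true(all(out$truth$marker2_mask == 0))
  expect_identical(nrow(out$truth$bud_table), 0L)
  expect_identical(out$truth$true_lvd_fraction, 0)
})

test_that("ground-truth tables reflect the requested plan", {
  out <- cached_field("plan_check", function() {
    field_spec(n_buds_by_nucleus_count = c("3" = 5), n_vessels = 2,
               n_lvi_events = 1, n_debris_nuclei = 0, seed = 21)
  })
  expect_identical(nrow(out$truth$bud_table), 5L)
  expect_true(all(out$truth$bud_table$n_nuclei == 3L))
  expect_identical(nrow(out$truth$lvi_pairs), 1L)
  expect_true(out$truth$lvi_pairs$bud_id %in% out$truth$bud_table$bud_id)
  expect_true(out$truth$lvi_pairs$vessel_id %in% out$truth$vessel_table$vessel_id)
})

test_that("generation is bit-identical for a repeated seed", {
  spec <- field_spec(n_buds_by_nucleus_count = c("2" = 2), n_vessels = 1,
                     n_lvi_events = 1, n_debris_nuclei = 1, seed = 33)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a, b)
})

test_that("mask component counts equal the spec's object counts", {
  for (seed in c(1, 5)) {
    out <- clean_field(seed)
    tr <- out$truth
    n_buds <- nrow(tr$bud_table)
    n_nuc <- sum(tr$bud_table$n_nuclei) + sum(tr$nucleus_table$type == "debris")
    expect_identical(max(budquant:::label_components(tr$marker1_mask > 0)),
                     n_buds)
    expect_identical(max(budquant:::label_components(tr$marker2_mask > 0)),
                     nrow(tr$vessel_table))
    expect_identical(max(budquant:::label_components(tr$nucleus_mask > 0)),
                     as.integer(n_nuc))
  }
})

test_that("pixel areas calibrate back to the recorded physical areas", {
  out <- clean_field(1)
  tr <- out$truth
  ps <- 0.5
  px_area <- ps^2
  for (i in seq_len(nrow(tr$nucleus_table))) {
    nid <- tr$nucleus_table$nucleus_id[i]
    measured <- sum(tr$nucleus_mask == nid) * px_area
    expect_lt(abs(measured - tr$nucleus_table$area_um2[i]), px_area + 1e-9)
    if (tr$nucleus_table$type[i] == "debris") {
      expect_lt(tr$nucleus_table$area_um2[i], 16)
    } else {
      expect_gte(tr$nucleus_table$area_um2[i], 16)
    }
  }
  # LVD is recomputable exactly from the masks
  filled_area <- sum(tr$vessel_table$total_px)
  expect_equal(tr$true_lvd_fraction,
               filled_area / sum(tr$region_mask == 2L))
})

test_that("geometric infeasibility raises a placement error", {
  expect_error(
    generate_field(field_spec(width_px = 128, height_px = 128,
                              pixel_size_um = 0.5,
                              n_buds_by_nucleus_count = c("5" = 40),
                              n_vessels = 0, n_lvi_events = 0,
                              n_debris_nuclei = 0, seed = 1)),
    class = "budquant_placement_error")
})

test_that("cohort spec rejects degenerate settings", {
  expect_error(cohort_spec(n_patients = 5), class = "budquant_spec_error")
  expect_error(cohort_spec(censoring_rate = 1), class = "budquant_spec_error")
  expect_error(
    cohort_spec(feature_distributions = list(
      tb = list(mu = 0, size = 4), lvi = list(mu = 12, size = 3),
      lvd = list(shape = 2, rate = 2.5))),
    class = "budquant_spec_error")
})

test_that("zero censoring means every patient has an event", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, censoring_rate = 0,
                                     seed = 4))
  expect_true(all(coh$survival$event == 1L))
})

test_that("the planted hazard ratio is recovered across replicates", {
  log_hrs <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_spec(n_patients = 200, seed = 100 + s))
    rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
    rec$above <- as.integer(coh$truth$above)
    fit <- survival::coxph(survival::Surv(time, event) ~ above, data = rec,
                           ties = "efron")
    unname(stats::coef(fit))
  }, numeric(1))
  expect_gt(exp(mean(log_hrs)), 2.6)
  expect_lt(exp(mean(log_hrs)), 3.5)
})

test_that("a null cohort gives exchangeable groups", {
  ps <- vapply(1:40, function(s) {
    coh <- generate_cohort(cohort_spec(n_patients = 60, log_hr = 0,
                                       seed = 500 + s))
    rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
    rec$group <- factor(ifelse(coh$truth$above, "above", "below"))
    logrank_test(rec, "group")$p_value
  }, numeric(1))
  # roughly uniform: the empirical CDF at 0.5 stays near 0.5
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.5), 0.75)
})
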