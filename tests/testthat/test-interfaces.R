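test_that("the pipeline configuration round-trips losslessly through JSON", {
  cfg <- pipeline_config(marker1_threshold = 0.42, k_fields = 12,
                         classification = classification_params(
                           debris_area_um2 = 20, merge_gap_um = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(budquant:::unclass_deep(back), budquant:::unclass_deep(cfg))
})

test_that("fields and ground truth round-trip through TIFF plus sidecar", {
  out <- plain_field(61)
  dir <- withr::local_tempdir()
  sc <- write_field(out$field, dir, out$truth)
  back <- read_field(sc)
  expect_identical(back$truth$region_mask, out$truth$region_mask)
  expect_identical(back$truth$nucleus_mask, out$truth$nucleus_mask)
  expect_identical(back$truth$marker1_mask, out$truth$marker1_mask)
  expect_equal(back$truth$bud_table, out$truth$bud_table,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$truth$true_lvd_fraction, out$truth$true_lvd_fraction)
  # 16-bit quantisation bounds the channel error
  expect_lt(max(abs(back$field$channels$dapi - out$field$channels$dapi)),
            1 / 65535 + 1e-9)
  expect_identical(back$field$pixel_size_um, 0.5)
})

test_that("annotations and region maps round-trip", {
  out <- plain_field(61)
  ann <- sample_region_annotations(out$truth$region_mask, n_per_class = 50,
                                   seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_identical(length(back$strokes), length(ann$strokes))
  expect_identical(back$strokes[[1]]$pixels, ann$strokes[[1]]$pixels)
  rpath <- withr::local_tempfile(fileext = ".tif")
  write_region_map(out$truth$region_mask, rpath)
  expect_identical(read_region_map(rpath), out$truth$region_mask)
})

test_that("simulation is byte-identical for a repeated seed and infeasible
           requests fail loudly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(d1, n_patients = 1, fields_per_patient = 2, seed = 5)
  simulate_dataset(d2, n_patients = 1, fields_per_patient = 2, seed = 5)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(
    generate_field(field_spec(width_px = 128, height_px = 128,
                              n_buds_by_nucleus_count = c("4" = 60),
                              n_vessels = 0, n_lvi_events = 0, seed = 1)),
    class = "budquant_placement_error")
})

test_that("dataset quantification matches a module-by-module recomputation", {
  dir <- withr::local_tempdir()
  simulate_dataset(dir, n_patients = 1, fields_per_patient = 3, seed = 7)
  cfg <- pipeline_config(k_fields = 3)
  res <- suppressWarnings(quantify_dataset(dir, cfg))
  expect_identical(nrow(res$field_features), 3L)
  # recompute via the module surface
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[!grepl("survival", sidecars)]
  manual <- dplyr::bind_rows(lapply(sidecars, function(sc) {
    dat <- read_field(sc)
    process_field(dat$field, dat$truth$region_mask, cfg)$features
  }))
  expect_equal(res$field_features, manual, ignore_attr = TRUE)
  pf <- aggregate_patient(select_fields(manual, 3))
  expect_equal(res$patient_features$tb_total, pf$tb_total)
  expect_equal(res$patient_features$lvi_total, pf$lvi_total)
  expect_equal(res$patient_features$lvd_mean_percent, pf$lvd_mean_percent)
  # manifest traceability: every segmented epithelial object is either
  # retained (candidate) or excluded with a reason
  log1 <- res$manifest$field_log
  expect_true(all(log1$n_marker1_excluded <= log1$n_marker1))
  expect_identical(res$manifest$n_fields, 3L)
  expect_match(res$manifest$config_hash, "^[a-f0-9]+$")
  # an empty directory errors
  expect_error(quantify_dataset(withr::local_tempdir(), cfg),
               class = "budquant_io_error")
})

test_that("the survival bundle is reproducible and joins defensively", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, seed = 17))
  res1 <- suppressWarnings(
    survival_analysis(coh$features, coh$survival, n_sim = 50, seed = 2))
  res2 <- suppressWarnings(
    survival_analysis(coh$features, coh$survival, n_sim = 50, seed = 2))
  expect_identical(res1$cutpoints, res2$cutpoints)
  expect_identical(res1$logrank, res2$logrank)
  expect_identical(nrow(res1$cutpoints), 3L)
  expect_identical(nrow(res1$logrank), 3L)
  expect_true(all(c("tb_total", "lvi_total", "lvd_mean_percent") %in%
                    res1$cutpoints$variable))
  expect_identical(length(res1$km), 3L)
  expect_s3_class(res1$cox_univariate, "cox_result")
  expect_identical(nrow(res1$correlations), 3L)
  # a patient without survival record is named in the error
  bad <- coh$features
  bad$patient_id[1] <- "ghost"
  expect_error(
    survival_analysis(bad, coh$survival, n_sim = 10, seed = 1),
    regexp = "ghost", class = "budquant_survival_error")
  # no events is an explicit error
  dead <- coh$survival; dead$event <- 0L
  expect_error(
    suppressWarnings(survival_analysis(coh$features, dead, n_sim = 10,
                                       seed = 1)),
    class = "budquant_survival_error")
})

test_that("tidy, glance and autoplot methods cover the result types", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, seed = 19))
  rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
  cp <- find_optimal_cutpoint(rec, "tb_total")
  expect_s3_class(tidy(cp), "tbl_df")
  expect_identical(glance(cp)$cutoff, cp$cutoff)
  expect_s3_class(autoplot(cp), "ggplot")
  grp <- dichotomise(rec, "tb_total", cp$cutoff)
  km <- km_estimate(grp, "group")
  expect_s3_class(autoplot(km), "ggplot")
  rec$above <- as.integer(coh$truth$above)
  cx <- cox_regression(rec, "above")
  expect_s3_class(tidy(cx), "tbl_df")
  expect_identical(glance(cx)$n_terms, 1L)
  out <- clean_field(2)
  res <- process_field(out$field, out$truth$region_mask)
  expect_s3_class(plot_field_overlay(out$field, res$buds, res$vessels,
                                     res$lvi_events,
                                     out$truth$region_mask), "ggplot")
})
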