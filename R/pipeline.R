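#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its documented default:
#' intensity thresholds (`"auto"` = bimodal-histogram over tissue pixels, or
#' a manual per-section number), minimum object areas, the object-
#' classification constants (16 um^2 debris bound, 50 um edge distance,
#' majority-area nucleus association, 1 px LVI overlap), the number of
#' fields aggregated per patient (15) and the survival-statistics settings
#' (1000 permutations, 10% group-size floor). The configuration round-trips
#' losslessly through JSON via [write_config()] / [read_config()].
#'
#' @param dapi_threshold,marker1_threshold,marker2_threshold `"auto"` or a
#'   numeric intensity threshold.
#' @param min_nucleus_area_um2 Minimum nucleus area retained at segmentation
#'   (0 keeps everything; debris is handled downstream by area class).
#' @param min_marker_area_um2 Minimum marker-object area in um^2.
#' @param classification A [classification_params()].
#' @param k_fields Fields aggregated per patient.
#' @param n_sim Monte Carlo permutations for cut-point correction.
#' @param min_group_frac Group-size floor of the cut-point scan.
#' @param min_region_area_um2 Minimum connected tissue-region area kept by
#'   [segment_tissue()].
#' @param seed Base seed for seeded pipeline steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dapi_threshold = "auto",
                            marker1_threshold = "auto",
                            marker2_threshold = "auto",
                            min_nucleus_area_um2 = 0,
                            min_marker_area_um2 = 5,
                            classification = classification_params(),
                            k_fields = 15L,
                            n_sim = 1000L,
                            min_group_frac = 0.1,
                            min_region_area_um2 = 100,
                            seed = 1L) {
  structure(list(
    dapi_threshold = dapi_threshold,
    marker1_threshold = marker1_threshold,
    marker2_threshold = marker2_threshold,
    min_nucleus_area_um2 = min_nucleus_area_um2,
    min_marker_area_um2 = min_marker_area_um2,
    classification = classification,
    k_fields = as.integer(k_fields),
    n_sim = as.integer(n_sim),
    min_group_frac = min_group_frac,
    min_region_area_um2 = min_region_area_um2,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- x$classification
  cl$autofluorescence <- as.list(cl$autofluorescence)
  cl$false_nuclei <- as.list(cl$false_nuclei)
  x$classification <- do.call(classification_params, cl)
  do.call(pipeline_config, x)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Run segmentation, classification and quantification on one field
#'
#' Executes the object-level pipeline against a field and its tissue-region
#' map: nucleus and marker segmentation, debris / edge / autofluorescence
#' filters, stromal merging, bud classification, vessel assembly, LVI
#' detection and field-feature quantification.
#'
#' @param field A [multiplex_field()].
#' @param region_map Integer region matrix (from [segment_tissue()] or a
#'   ground-truth mask).
#' @param config A [pipeline_config()].
#' @return A list: `nuclei`, `markers1`, `markers2`, `buds`, `vessels`,
#'   `lvi_events`, `features` (one-row tibble).
#' @export
process_field <- function(field, region_map, config = pipeline_config()) {
  stopifnot(inherits(field, "multiplex_field"))
  if (!identical(dim(region_map), dim(field$channels$dapi))) {
    abort("region_map shape does not match the field.",
          class = "budquant_field_error")
  }
  ps <- field$pixel_size_um
  cp <- config$classification

  nuclei <- segment_nuclei(
    field$channels$dapi,
    nucleus_params(threshold = config$dapi_threshold),
    ps, region_map)
  nuclei <- flag_false_nuclei(nuclei, field$channels$dapi, cp$false_nuclei)
  nuclei <- flag_debris_nuclei(nuclei, cp$debris_area_um2)

  thr1 <- if (identical(config$marker1_threshold, "auto")) {
    select_marker_threshold(field$channels$marker1, region_map)
  } else config$marker1_threshold
  m1 <- segment_marker(field$channels$marker1, thr1,
                       config$min_marker_area_um2, ps, "marker1")
  m1 <- flag_edge_effect(m1, region_map, cp$edge_distance_um, ps)
  m1 <- suppress_autofluorescence(m1, field$channels$marker1,
                                  cp$autofluorescence)

  thr2 <- if (identical(config$marker2_threshold, "auto")) {
    select_marker_threshold(field$channels$marker2, region_map)
  } else config$marker2_threshold
  m2 <- segment_marker(field$channels$marker2, thr2,
                       config$min_marker_area_um2, ps, "marker2")
  m2 <- flag_edge_effect(m2, region_map, cp$edge_distance_um, ps)

  merged1 <- merge_stromal_markers(m1, region_map, cp$merge_gap_um)
  buds <- classify_buds(merged1, nuclei, cp$association_min_fraction)
  vessels <- build_vessels(m2, region_map, cp$merge_gap_um)
  lvi <- detect_lvi(buds, vessels, cp$lvi_minimum_overlap_px,
                    cp$include_large_buds)
  features <- quantify_field(buds, lvi, vessels, region_map, ps,
                             patient_id = field$patient_id,
                             field_id = field$field_id)
  list(nuclei = nuclei, markers1 = m1, markers2 = m2, buds = buds,
       vessels = vessels, lvi_events = lvi, features = features)
}

#' Quantify a directory of fields into field and patient feature tables
#'
#' Reads every field sidecar in `dir` (written by [write_field()] /
#' [simulate_dataset()]), obtains each field's tissue-region map either from
#' the stored ground-truth mask (`region_source = "truth"`) or by applying a
#' trained classifier (`region_source = "classifier"`), runs
#' [process_field()], and aggregates per patient over the
#' `config$k_fields` fields with the most LVI events. A run manifest records
#' the configuration hash, package version, per-field log and all warnings,
#' so every excluded object or shortfall is traceable.
#'
#' @param dir Directory of fields.
#' @param config A [pipeline_config()].
#' @param region_source `"truth"` or `"classifier"`.
#' @param classifier Required when `region_source = "classifier"`.
#' @param out_dir Optional directory for `field_features.csv`,
#'   `patient_features.csv` and `manifest.json`.
#' @return A list: `field_features`, `patient_features`, `manifest`.
#' @export
quantify_dataset <- function(dir, config = pipeline_config(),
                             region_source = c("truth", "classifier"),
                             classifier = NULL, out_dir = NULL) {
  region_source <- match.arg(region_source)
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[!grepl("survival|manifest|config", basename(sidecars))]
  if (!length(sidecars)) {
    abort(paste0("No field sidecars found in '", dir, "'."),
          class = "budquant_io_error")
  }
  if (region_source == "classifier" && is.null(classifier)) {
    abort("region_source = 'classifier' requires a classifier.",
          class = "budquant_io_error")
  }
  warnings_log <- character()
  field_logs <- list()
  feats <- list()
  for (sc in sidecars) {
    dat <- read_field(sc)
    region <- if (region_source == "truth") {
      if (is.null(dat$truth)) {
        abort(paste0("No ground-truth masks for '", sc, "'."),
              class = "budquant_io_error")
      }
      dat$truth$region_mask
    } else {
      segment_tissue(dat$field, classifier, config$min_region_area_um2)
    }
    res <- withCallingHandlers(
      process_field(dat$field, region, config),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    feats[[length(feats) + 1L]] <- res$features
    field_logs[[length(field_logs) + 1L]] <- tibble::tibble(
      field_id = dat$field$field_id, patient_id = dat$field$patient_id,
      n_nuclei = nrow(res$nuclei$objects),
      n_marker1 = nrow(res$markers1$objects),
      n_marker1_excluded = sum(res$markers1$objects$status != "candidate"),
      n_marker2 = nrow(res$markers2$objects),
      n_buds = nrow(res$buds$buds),
      n_vessels = nrow(res$vessels$vessels),
      n_lvi = nrow(res$lvi_events)
    )
  }
  field_features <- dplyr::bind_rows(feats)
  patient_features <- dplyr::bind_rows(lapply(
    split(field_features, field_features$patient_id),
    function(ff) {
      sel <- withCallingHandlers(
        select_fields(ff, config$k_fields),
        warning = function(w) {
          warnings_log <<- c(warnings_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      aggregate_patient(sel)
    }))
  manifest <- list(
    config_hash = rlang::hash(unclass_deep(config)),
    package_version = as.character(utils::packageVersion("budquant")),
    n_fields = nrow(field_features),
    field_log = dplyr::bind_rows(field_logs),
    warnings = warnings_log
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(field_features, file.path(out_dir, "field_features.csv"),
              row.names = FALSE)
    write.csv(patient_features, file.path(out_dir, "patient_features.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      c(manifest[c("config_hash", "package_version", "n_fields")],
        list(field_log = manifest$field_log, warnings = manifest$warnings)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
  }
  list(field_features = field_features, patient_features = patient_features,
       manifest = manifest)
}

#' Simulate a synthetic dataset on disk
#'
#' Writes `n_patients * fields_per_patient` synthetic fields with ground
#' truth (see [generate_field()]) plus a `survival.csv` in which patients
#' whose planted LVI totals exceed the cohort median carry an elevated
#' hazard. Deterministic given `seed`.
#'
#' @param dir Output directory.
#' @param n_patients,fields_per_patient Cohort shape.
#' @param seed Integer seed.
#' @param width_px,height_px,pixel_size_um,noise_sd Field geometry passed to
#'   [field_spec()].
#' @param log_hr,baseline_rate,censoring_rate Survival model: log-hazard
#'   increment of the above-median-LVI group, baseline exponential event
#'   rate, target censoring fraction.
#' @return A list with the field sidecar paths, the survival-table path and
#'   the per-patient planted totals, invisibly.
#' @export
simulate_dataset <- function(dir, n_patients = 2L, fields_per_patient = 15L,
                             seed = 1L, width_px = 512L, height_px = 512L,
                             pixel_size_um = 0.5, noise_sd = 0.05,
                             log_hr = log(3), baseline_rate = 0.08,
                             censoring_rate = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_fields <- n_patients * fields_per_patient
  seeds <- derive_seeds(seed, n_fields + 1L)
  paths <- character()
  planted <- list()
  fi <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (f in seq_len(fields_per_patient)) {
      fi <- fi + 1L
      spec <- with_seed(seeds[fi], {
        tb_k <- stats::rpois(5, c(0.8, 0.8, 0.5, 0.3, 0.2))
        lg_k <- stats::rpois(2, c(0.15, 0.1))
        counts <- c(tb_k, lg_k)
        names(counts) <- c(1:5, 6:7)
        counts <- counts[counts > 0]
        n_vessels <- 1L + stats::rpois(1, 1.2)
        n_small <- sum(tb_k)
        n_lvi <- stats::rbinom(1, min(n_small, n_vessels), 0.3)
        field_spec(width_px = width_px, height_px = height_px,
                   pixel_size_um = pixel_size_um,
                   n_buds_by_nucleus_count = counts,
                   n_vessels = n_vessels, n_lvi_events = n_lvi,
                   n_debris_nuclei = stats::rpois(1, 2),
                   noise_sd = noise_sd, seed = seeds[fi])
      })
      # a crowded draw can be geometrically infeasible at this field size;
      # re-seed the placement (not the plan) a bounded number of times
      out <- NULL
      for (attempt in 0:9) {
        spec_try <- spec
        spec_try$seed <- as.integer((as.numeric(spec$seed) +
                                       attempt * 9973) %% 2147483647)
        out <- tryCatch(
          generate_field(spec_try, field_id = sprintf("F%03d", f),
                         patient_id = pid),
          budquant_placement_error = function(e) NULL)
        if (!is.null(out)) break
      }
      if (is.null(out)) {
        abort("Field plan could not be placed after 10 re-seeds; reduce object counts or enlarge the field.",
              class = "budquant_placement_error")
      }
      paths <- c(paths, write_field(out$field, dir, out$truth))
      planted[[fi]] <- tibble::tibble(
        patient_id = pid,
        tb = sum(out$truth$bud_table$n_nuclei <= 5 &
                   out$truth$bud_table$n_nuclei >= 1),
        lvi = nrow(out$truth$lvi_pairs))
    }
  }
  totals <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(planted), .data$patient_id),
    tb_total = sum(.data$tb), lvi_total = sum(.data$lvi), .groups = "drop")
  surv <- with_seed(seeds[n_fields + 1L], {
    above <- totals$lvi_total > median(totals$lvi_total)
    rate <- baseline_rate * exp(log_hr * above)
    t_event <- rexp(nrow(totals), rate)
    t_cens <- if (censoring_rate > 0) {
      rexp(nrow(totals), baseline_rate * censoring_rate / (1 - censoring_rate))
    } else rep(Inf, nrow(totals))
    tibble::tibble(patient_id = totals$patient_id,
                   time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
  })
  surv_path <- file.path(dir, "survival.csv")
  write.csv(surv, surv_path, row.names = FALSE)
  invisible(list(sidecars = paths, survival = surv_path,
                 planted_totals = totals))
}

#' Full survival-statistics bundle for a quantified cohort
#'
#' Joins patient features to survival records and, for each requested
#' feature: derives the minimum-p cut-point, corrects it by Monte Carlo
#' permutation, dichotomises the cohort, and computes the Kaplan-Meier
#' curves and log-rank test. Log-rank p-values across features are
#' FDR-corrected (Benjamini-Hochberg). Cox regression is run per feature
#' group (univariate) and jointly (multivariable), and pairwise Pearson
#' correlations between the features are Bonferroni-adjusted.
#'
#' Cut-offs are derived on the full supplied cohort; to apply them to a
#' subpopulation (e.g. an intermediate-stage subgroup), call
#' [dichotomise()] on the subgroup with the returned cut-offs.
#'
#' @param features Patient feature tibble (see [aggregate_patient()]).
#' @param survival_records Tibble with `patient_id`, `time`, `event`.
#' @param variables Feature columns to analyse.
#' @param n_sim Monte Carlo permutations.
#' @param seed Integer seed.
#' @param horizon Optional restriction horizon (e.g. 5 for 5-year analyses).
#' @param min_group_frac Cut-point group-size floor.
#' @return A list: `cutpoints` (tibble), `logrank` (tibble with `p_fdr`),
#'   `km` (named list of [km_estimate()] fits), `cox_univariate`,
#'   `cox_multivariable`, `correlations`, `data` (the joined, dichotomised
#'   table).
#' @export
survival_analysis <- function(features, survival_records,
                              variables = c("tb_total", "lvi_total",
                                            "lvd_mean_percent"),
                              n_sim = 1000L, seed = 1L, horizon = NULL,
                              min_group_frac = 0.1) {
  missing_ids <- setdiff(features$patient_id, survival_records$patient_id)
  if (length(missing_ids)) {
    abort(paste0("No survival record for patient(s): ",
                 paste(missing_ids, collapse = ", "), "."),
          class = "budquant_survival_error")
  }
  dat <- dplyr::left_join(features, survival_records, by = "patient_id")
  if (sum(dat$event) < 1) {
    abort("The cohort contains no events.", class = "budquant_survival_error")
  }
  seeds <- derive_seeds(seed, length(variables))
  cutpoints <- list(); lr_rows <- list(); km_fits <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    cp <- find_optimal_cutpoint(dat, v, min_group_frac = min_group_frac,
                                horizon = horizon)
    cp <- monte_carlo_corrected_p(dat, v, n_sim = n_sim, seed = seeds[i],
                                  min_group_frac = min_group_frac,
                                  horizon = horizon, result = cp)
    grp <- dichotomise(dat, v, cp$cutoff)
    dat[[paste0(v, "_group")]] <- factor(
      ifelse(dat[[v]] > cp$cutoff, "above", "below"),
      levels = c("below", "above"))
    lr <- logrank_test(grp, "group", horizon = horizon)
    km_fits[[v]] <- km_estimate(grp, "group", horizon = horizon)
    cutpoints[[v]] <- glance(cp)
    lr_rows[[v]] <- dplyr::mutate(lr, variable = v)
  }
  logrank <- dplyr::bind_rows(lr_rows)
  logrank$p_fdr <- bh_fdr(logrank$p_value)
  group_vars <- paste0(variables, "_group")
  cox_uni <- cox_regression(dat, group_vars, "univariate", horizon = horizon)
  cox_multi <- tryCatch(
    cox_regression(dat, group_vars, "multivariable", horizon = horizon),
    budquant_survival_error = function(e) {
      warn(paste0("Multivariable model not estimable: ", conditionMessage(e)))
      NULL
    })
  pairs <- utils::combn(variables, 2)
  correlations <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    pr <- pearson_bonferroni(dat[[pairs[1, j]]], dat[[pairs[2, j]]],
                             n_tests = ncol(pairs))
    dplyr::mutate(pr, var_x = pairs[1, j], var_y = pairs[2, j])
  }))
  list(cutpoints = dplyr::bind_rows(cutpoints), logrank = logrank,
       km = km_fits, cox_univariate = cox_uni,
       cox_multivariable = cox_multi, correlations = correlations,
       data = dat)
}
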