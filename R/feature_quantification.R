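#' Quantify one field: bud counts, LVI count and lymphatic vessel density
#'
#' Counts retained objects only (edge-effect, non-specific and non-stromal
#' objects never reach the bud / vessel sets) and computes the lymphatic
#' vessel density as the vessel area expressed as a percentage of the
#' stromal area. The stromal denominator is the full Stroma-labelled area
#' of the field, including the vessel pixels it contains; set
#' `exclusive_stroma = TRUE` to subtract the vessel area from the
#' denominator instead.
#'
#' @param buds A [classify_buds()] result.
#' @param lvi_events A [detect_lvi()] result.
#' @param vessels A [build_vessels()] result.
#' @param region_map Integer region matrix per [region_levels()].
#' @param pixel_size_um Pixel edge in micrometres.
#' @param patient_id,field_id Identifiers carried into the row.
#' @param exclusive_stroma Exclude vessel pixels from the LVD denominator.
#' @return A one-row tibble of field features: `tb_count` (tumour buds, 1-5
#'   nuclei), `small_bud_count` (1-2 nuclei), `large_bud_count` (>5),
#'   `lvi_count`, `vessel_area_um2`, `stroma_area_um2` and `lvd_percent`
#'   (`NA` with a warning when the field has no stroma).
#' @export
quantify_field <- function(buds, lvi_events, vessels, region_map,
                           pixel_size_um, patient_id = "patient_1",
                           field_id = "field_1", exclusive_stroma = FALSE) {
  stopifnot(inherits(buds, "bud_set"), inherits(vessels, "vessel_set"))
  b <- buds$buds
  tb <- sum(b$bud_class == "tumour_bud")
  small <- sum(b$bud_class == "tumour_bud" & b$n_true_nuclei <= 2L)
  large <- sum(b$bud_class == "large_bud")
  vessel_area <- sum(vessels$vessels$area_um2)
  stroma_area <- sum(region_map == 2L) * pixel_size_um^2
  denom <- if (exclusive_stroma) stroma_area - vessel_area else stroma_area
  if (denom <= 0) {
    warn(paste0("Field '", field_id, "' has no stromal area; LVD undefined."))
    lvd <- NA_real_
  } else {
    lvd <- 100 * vessel_area / denom
  }
  tibble::tibble(
    patient_id = patient_id, field_id = field_id,
    tb_count = as.integer(tb), small_bud_count = as.integer(small),
    large_bud_count = as.integer(large),
    lvi_count = as.integer(nrow(lvi_events)),
    vessel_area_um2 = vessel_area, stroma_area_um2 = stroma_area,
    lvd_percent = lvd
  )
}

#' Select the fields richest in LVI events
#'
#' Orders a patient's fields by `lvi_count` descending (ties broken by
#' `field_id` ascending, a stable documented rule) and keeps the first
#' `min(k, available)`. A shortfall below `k` is kept, with a warning, and
#' recorded downstream in `n_fields_used`.
#'
#' @param field_features Tibble of per-field rows (see [quantify_field()]).
#' @param k Number of fields to select (15 by convention: the capacity of
#'   the smallest section's invasive front).
#' @return The selected rows, in selection order.
#' @export
#' @examples
#' ff <- tibble::tibble(patient_id = "P1", field_id = sprintf("f%02d", 1:20),
#'                      lvi_count = 0:19)
#' select_fields(ff)$lvi_count
select_fields <- function(field_features, k = 15L) {
  if (nrow(field_features) < 1) {
    abort("At least one field is required.", class = "budquant_feature_error")
  }
  if (nrow(field_features) < k) {
    warn(sprintf("Only %d fields available (requested %d); using all.",
                 nrow(field_features), k))
  }
  out <- dplyr::arrange(field_features, dplyr::desc(.data$lvi_count),
                        .data$field_id)
  dplyr::slice_head(out, n = min(k, nrow(out)))
}

#' Aggregate selected fields into per-patient features
#'
#' Sums TB and LVI counts over exactly the selected fields and takes the
#' arithmetic mean of the defined per-field LVD values. Bud-size variant
#' totals (1-2 nuclei; >5 nuclei; 1-5 plus >5 summed) are computed the same
#' way, supporting bud-size sensitivity re-categorisation. A patient whose
#' selected fields all lack a defined LVD gets `lvd_mean_percent = NA`.
#'
#' @param selected Output of [select_fields()] for one patient.
#' @return A one-row tibble of patient features.
#' @export
aggregate_patient <- function(selected) {
  stopifnot(nrow(selected) >= 1)
  lvd <- selected$lvd_percent[!is.na(selected$lvd_percent)]
  if (!length(lvd)) {
    warn(paste0("Patient '", selected$patient_id[1],
                "' has no field with defined LVD; reporting NA."))
  }
  tibble::tibble(
    patient_id = selected$patient_id[1],
    n_fields_used = nrow(selected),
    tb_total = sum(selected$tb_count),
    small_bud_total = sum(selected$small_bud_count),
    large_bud_total = sum(selected$large_bud_count),
    all_bud_total = sum(selected$tb_count) + sum(selected$large_bud_count),
    lvi_total = sum(selected$lvi_count),
    lvd_mean_percent = if (length(lvd)) mean(lvd) else NA_real_
  )
}

#' Dichotomise patients at a cut-off
#'
#' Labels each patient `"above"` when the variable strictly exceeds the
#' cut-off and `"below"` otherwise (a value equal to the cut-off is below,
#' consistent with ">cut-off" group definitions). Patients with a missing
#' value are dropped with a message.
#'
#' @param patients Tibble of per-patient rows.
#' @param variable Column name to dichotomise.
#' @param cutoff Finite cut-off value.
#' @return The input rows with a `group` factor (`below`, `above`) appended;
#'   missing-value rows removed.
#' @export
#' @examples
#' p <- tibble::tibble(patient_id = c("a", "b"), tb_total = c(287L, 300L))
#' dichotomise(p, "tb_total", 287)$group
dichotomise <- function(patients, variable, cutoff) {
  if (!is.finite(cutoff)) {
    abort("cutoff must be finite.", class = "budquant_feature_error")
  }
  x <- patients[[variable]]
  if (is.null(x)) {
    abort(paste0("No column '", variable, "' in patients."),
          class = "budquant_feature_error")
  }
  miss <- is.na(x)
  if (any(miss)) {
    inform(sprintf("Excluding %d patient(s) with missing %s.",
                   sum(miss), variable))
  }
  out <- patients[!miss, , drop = FALSE]
  out$group <- factor(ifelse(out[[variable]] > cutoff, "above", "below"),
                      levels = c("below", "above"))
  out
}
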