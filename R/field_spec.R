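#' Specification of a synthetic multiplexed-IF field
#'
#' Describes one synthetic invasive-front field: image geometry and
#' calibration, the detached epithelial objects ("buds") to plant by
#' associated-nucleus count, lymphatic vessels, planted bud-in-vessel
#' (LVI) events, nuclear debris, and the staining artefacts the object
#' classifier must reject (tissue-edge staining, channel autofluorescence).
#'
#' @param width_px,height_px Image size in pixels (each at least 128).
#' @param pixel_size_um Physical pixel edge length in micrometres.
#' @param n_buds_by_nucleus_count Named integer vector mapping an
#'   associated-nucleus count (names `"1"`..`"12"`) to the number of buds
#'   planted with that many nuclei. Each planted nucleus is at least
#'   16 um^2 so it is never mistaken for debris.
#' @param n_vessels Number of lymphatic vessels (annular D2-40 walls with a
#'   dark lumen).
#' @param n_lvi_events Number of planted bud-in-vessel events; at most one
#'   per vessel, each using a bud with 1-5 nuclei.
#' @param n_debris_nuclei Number of planted DAPI blobs under 16 um^2.
#' @param edge_artifact If `TRUE`, non-specific marker staining is painted
#'   within 50 um of the no-tissue border.
#' @param autofluorescence_level Autofluorescence intensity in `[0, 1]`;
#'   0 disables the textured epithelial-channel streaks.
#' @param noise_sd Standard deviation of additive Gaussian noise applied to
#'   every channel (intensities live in `[0, 1]`).
#' @param tumour_mass If `TRUE` (default) a cohesive tumour region with an
#'   invasive front and a necrosis/lumen pocket is rendered; disabling it
#'   yields a stroma-only field, convenient for isolated segmentation tests.
#' @param seed Integer seed; all randomness in [generate_field()] flows from
#'   it.
#'
#' @return A `field_spec` object (validated list).
#' @seealso [generate_field()]
#' @export
#' @examples
#' spec <- field_spec(n_buds_by_nucleus_count = c("3" = 5), n_vessels = 2,
#'                    n_lvi_events = 1, seed = 7)
#' spec$n_vessels
field_spec <- function(width_px = 512L,
                       height_px = 512L,
                       pixel_size_um = 0.5,
                       n_buds_by_nucleus_count = c("3" = 3L),
                       n_vessels = 3L,
                       n_lvi_events = 1L,
                       n_debris_nuclei = 4L,
                       edge_artifact = FALSE,
                       autofluorescence_level = 0,
                       noise_sd = 0.05,
                       tumour_mass = TRUE,
                       seed = 1L) {
  if (width_px < 128 || height_px < 128) {
    abort("width_px and height_px must each be at least 128.",
          class = "budquant_spec_error")
  }
  if (pixel_size_um <= 0) {
    abort("pixel_size_um must be positive.", class = "budquant_spec_error")
  }
  nb <- n_buds_by_nucleus_count
  if (length(nb)) {
    if (is.null(names(nb)) || any(!names(nb) %in% as.character(1:12))) {
      abort("n_buds_by_nucleus_count must be named with nucleus counts 1..12.",
            class = "budquant_spec_error")
    }
    if (any(nb < 0)) {
      abort("Bud counts must be non-negative.", class = "budquant_spec_error")
    }
    nb <- nb[nb > 0]
  }
  total_buds <- if (length(nb)) sum(nb) else 0L
  small_buds <- if (length(nb)) sum(nb[as.integer(names(nb)) <= 5]) else 0L
  if (n_lvi_events > total_buds) {
    abort("n_lvi_events cannot exceed the total number of planted buds.",
          class = "budquant_spec_error")
  }
  if (n_lvi_events > n_vessels) {
    abort("n_lvi_events cannot exceed n_vessels (one bud per vessel).",
          class = "budquant_spec_error")
  }
  if (n_lvi_events > small_buds) {
    abort("n_lvi_events cannot exceed the number of buds with 1-5 nuclei (LVI uses tumour buds).",
          class = "budquant_spec_error")
  }
  if (autofluorescence_level < 0 || autofluorescence_level > 1) {
    abort("autofluorescence_level must lie in [0, 1].",
          class = "budquant_spec_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative.", class = "budquant_spec_error")
  }
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um,
      n_buds_by_nucleus_count = if (length(nb)) setNames(as.integer(nb), names(nb)) else integer(),
      n_vessels = as.integer(n_vessels),
      n_lvi_events = as.integer(n_lvi_events),
      n_debris_nuclei = as.integer(n_debris_nuclei),
      edge_artifact = isTRUE(edge_artifact),
      autofluorescence_level = autofluorescence_level,
      noise_sd = noise_sd,
      tumour_mass = isTRUE(tumour_mass),
      seed = as.integer(seed)
    ),
    class = "field_spec"
  )
}

#' A three-channel multiplexed-immunofluorescence field
#'
#' Container for one captured field: the DAPI (nuclei), Marker-1
#' (pan-cytokeratin epithelium) and Marker-2 (D2-40 lymphatic endothelium)
#' intensity rasters plus pixel calibration.
#'
#' @param dapi,marker1,marker2 Numeric matrices of identical dimensions with
#'   non-negative, finite intensities.
#' @param pixel_size_um Physical pixel edge length in micrometres.
#' @param field_id,patient_id Identifiers.
#'
#' @return A `multiplex_field` object.
#' @export
multiplex_field <- function(dapi, marker1, marker2, pixel_size_um,
                            field_id = "field_1", patient_id = "patient_1") {
  chans <- list(dapi = dapi, marker1 = marker1, marker2 = marker2)
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All channels must share dimensions.", class = "budquant_field_error")
  }
  for (nm in names(chans)) {
    if (any(!is.finite(chans[[nm]]))) {
      abort(paste0("Channel '", nm, "' contains non-finite values."),
            class = "budquant_field_error")
    }
    if (any(chans[[nm]] < 0)) {
      abort(paste0("Channel '", nm, "' contains negative intensities."),
            class = "budquant_field_error")
    }
  }
  if (pixel_size_um <= 0) {
    abort("pixel_size_um must be positive.", class = "budquant_field_error")
  }
  structure(
    list(channels = chans, pixel_size_um = pixel_size_um,
         field_id = field_id, patient_id = patient_id),
    class = "multiplex_field"
  )
}

#' @export
print.multiplex_field <- function(x, ...) {
  d <- dim(x$channels$dapi)
  cat("<multiplex_field> ", x$patient_id, "/", x$field_id, ": ",
      d[1], "x", d[2], " px @ ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> ", x$width_px, "x", x$height_px, " px @ ",
      x$pixel_size_um, " um/px; buds: ",
      if (length(x$n_buds_by_nucleus_count)) {
        paste(names(x$n_buds_by_nucleus_count), x$n_buds_by_nucleus_count,
              sep = "nuc x", collapse = ", ")
      } else "none",
      "; vessels: ", x$n_vessels, "; LVI: ", x$n_lvi_events,
      "; debris: ", x$n_debris_nuclei, "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
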