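#' Select an intensity threshold for a marker or DAPI channel
#'
#' Per-section threshold selection: a supplied manual value wins outright
#' (sections are assessed individually in practice because marker
#' fluorescence varies between patients); otherwise an automatic
#' bimodal-histogram (Otsu) threshold is computed over tissue pixels only
#' (every pixel not labelled NoTissue).
#'
#' @param channel Numeric intensity matrix.
#' @param region_map Integer region matrix per [region_levels()]; `NULL`
#'   uses all pixels.
#' @param method `"auto"` (Otsu over tissue pixels) or `"manual"`.
#' @param manual_value Threshold used when `method = "manual"`.
#' @return A numeric threshold carrying attributes `method` and `n_pixels`
#'   for audit.
#' @export
#' @examples
#' ch <- matrix(c(rep(0.1, 50), rep(0.8, 50)), 10, 10)
#' select_marker_threshold(ch)
select_marker_threshold <- function(channel, region_map = NULL,
                                    method = c("auto", "manual"),
                                    manual_value = NULL) {
  method <- match.arg(method)
  if (!is.null(manual_value)) method <- "manual"
  if (method == "manual") {
    if (is.null(manual_value)) {
      abort("method = 'manual' requires manual_value.",
            class = "budquant_threshold_error")
    }
    thr <- manual_value
    attr(thr, "method") <- "manual"
    attr(thr, "n_pixels") <- length(channel)
    return(thr)
  }
  x <- if (is.null(region_map)) as.vector(channel) else
    channel[region_map != 4L]
  thr <- otsu_threshold(x)
  attr(thr, "method") <- "auto_otsu"
  attr(thr, "n_pixels") <- length(x)
  thr
}

#' Segment marker-positive objects by intensity and area thresholds
#'
#' Thresholds the channel, labels 8-connected components of the
#' supra-threshold mask and discards components smaller than
#' `min_area_um2`. All returned objects have `status = "candidate"`; the
#' hierarchical classification downgrades artefacts downstream.
#'
#' @param channel Numeric intensity matrix.
#' @param threshold Intensity threshold (see [select_marker_threshold()]).
#' @param min_area_um2 Minimum retained object area in um^2.
#' @param pixel_size_um Pixel edge in micrometres (positive).
#' @param marker `"marker1"` (pan-cytokeratin) or `"marker2"` (D2-40).
#' @return A `marker_objects` list: `mask` (labelled integer matrix) and
#'   `objects` (tibble with `object_id`, `marker`, `area_px`, `area_um2`,
#'   centroid and `status`), plus `marker` and `pixel_size_um`.
#' @export
segment_marker <- function(channel, threshold, min_area_um2 = 5,
                           pixel_size_um, marker = c("marker1", "marker2")) {
  marker <- match.arg(marker)
  if (pixel_size_um <= 0) {
    abort("pixel_size_um must be positive.", class = "budquant_field_error")
  }
  mask <- channel > as.numeric(threshold)
  lab <- label_components(mask)
  tab <- label_table(lab, pixel_size_um)
  drop <- tab$object_id[tab$area_um2 < min_area_um2]
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    tab <- tab[!tab$object_id %in% drop, , drop = FALSE]
  }
  lab <- relabel_sequential(lab)
  tab$object_id <- seq_len(nrow(tab))
  objects <- tibble::as_tibble(tab)
  objects$marker <- marker
  objects$status <- rep("candidate", nrow(objects))
  structure(list(mask = lab, objects = objects, marker = marker,
                 pixel_size_um = pixel_size_um),
            class = "marker_objects")
}

#' @export
print.marker_objects <- function(x, ...) {
  cat("<marker_objects> ", x$marker, ": ", nrow(x$objects), " objects (",
      paste(names(table(x$objects$status)), table(x$objects$status),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Parameters for nucleus segmentation
#'
#' @param threshold `"auto"` or a numeric DAPI intensity threshold.
#' @param split_touching Apply a distance-transform watershed to split
#'   touching nuclei.
#' @param watershed_tolerance Minimum depth between watershed basins.
#' @param min_solidity Optional minimum solidity filter (`NULL` disables;
#'   a morphometric guard against ragged false objects).
#' @return A `nucleus_params` list.
#' @export
nucleus_params <- function(threshold = "auto", split_touching = TRUE,
                           watershed_tolerance = 1, min_solidity = NULL) {
  structure(list(threshold = threshold, split_touching = split_touching,
                 watershed_tolerance = watershed_tolerance,
                 min_solidity = min_solidity),
            class = "nucleus_params")
}

#' Segment nuclei from the DAPI channel
#'
#' Thresholds DAPI intensity, optionally splits touching nuclei with a
#' distance-transform watershed, and returns every component with
#' `status = "nucleus"`; debris reclassification by area happens downstream
#' in [flag_debris_nuclei()].
#'
#' @param dapi Numeric DAPI intensity matrix.
#' @param params A [nucleus_params()].
#' @param pixel_size_um Pixel edge in micrometres.
#' @param region_map Optional region map restricting the automatic threshold
#'   to tissue pixels.
#' @return A `nucleus_objects` list: `mask` (labelled matrix) and `objects`
#'   (tibble with `nucleus_id`, `area_px`, `area_um2`, centroid, `status`).
#' @export
segment_nuclei <- function(dapi, params = nucleus_params(), pixel_size_um,
                           region_map = NULL) {
  stopifnot(inherits(params, "nucleus_params"))
  if (pixel_size_um <= 0) {
    abort("pixel_size_um must be positive.", class = "budquant_field_error")
  }
  thr <- if (identical(params$threshold, "auto")) {
    if (all(dapi == dapi[1])) {
      # constant raster: nothing to segment
      return(empty_nuclei(dapi, pixel_size_um))
    }
    as.numeric(select_marker_threshold(dapi, region_map))
  } else as.numeric(params$threshold)
  mask <- dapi > thr
  if (!any(mask)) return(empty_nuclei(dapi, pixel_size_um))
  if (params$split_touching) {
    dm <- as.matrix(EBImage::distmap(EBImage::Image(mask)))
    lab <- as.matrix(EBImage::watershed(EBImage::Image(dm),
                                        tolerance = params$watershed_tolerance,
                                        ext = 1))
    storage.mode(lab) <- "integer"
  } else {
    lab <- label_components(mask)
  }
  lab <- relabel_sequential(lab)
  tab <- label_table(lab, pixel_size_um)
  if (!is.null(params$min_solidity)) {
    sol <- object_solidity(lab, tab$object_id)
    drop <- tab$object_id[sol < params$min_solidity]
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      tab <- tab[!tab$object_id %in% drop, , drop = FALSE]
      lab <- relabel_sequential(lab)
      tab$object_id <- seq_len(nrow(tab))
    }
  }
  objects <- tibble::as_tibble(tab)
  objects <- dplyr::rename(objects, nucleus_id = "object_id")
  objects$status <- rep("nucleus", nrow(objects))
  structure(list(mask = lab, objects = objects, pixel_size_um = pixel_size_um),
            class = "nucleus_objects")
}

empty_nuclei <- function(dapi, pixel_size_um) {
  structure(list(mask = matrix(0L, nrow(dapi), ncol(dapi)),
                 objects = tibble::tibble(
                   nucleus_id = integer(), area_px = integer(),
                   area_um2 = double(), centroid_row = double(),
                   centroid_col = double(), status = character()),
                 pixel_size_um = pixel_size_um),
            class = "nucleus_objects")
}

# Solidity = object area / filled-bounding-hull proxy (filled object area).
object_solidity <- function(lab, ids) {
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(lab)))
  vapply(ids, function(i) sum(lab == i) / max(sum(filled == i), 1L), numeric(1))
}

#' @export
print.nucleus_objects <- function(x, ...) {
  cat("<nucleus_objects> ", nrow(x$objects), " objects\n", sep = "")
  invisible(x)
}
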