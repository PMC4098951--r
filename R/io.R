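#' Write a field (and its ground truth) to disk
#'
#' Writes the field as a multipage 16-bit TIFF (page order DAPI, Marker 1,
#' Marker 2), a JSON sidecar carrying the pixel calibration, identifiers and
#' -- when supplied -- the ground-truth tables, and (with truth) a multipage
#' 16-bit label TIFF holding the region / nucleus / marker masks.
#'
#' @param field A [multiplex_field()].
#' @param dir Output directory (created if missing).
#' @param truth Optional ground truth from [generate_field()].
#' @return The sidecar path, invisibly.
#' @export
write_field <- function(field, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(field$patient_id, "_", field$field_id))
  tiff::writeTIFF(list(field$channels$dapi, field$channels$marker1,
                       field$channels$marker2),
                  paste0(base, ".tif"), bits.per.sample = 16L)
  side <- list(
    patient_id = field$patient_id,
    field_id = field$field_id,
    pixel_size_um = field$pixel_size_um,
    channel_order = c("dapi", "marker1", "marker2")
  )
  if (!is.null(truth)) {
    tiff::writeTIFF(
      lapply(list(truth$region_mask, truth$nucleus_mask,
                  truth$marker1_mask, truth$marker2_mask),
             function(m) m / 65535),
      paste0(base, "_masks.tif"), bits.per.sample = 16L)
    side$truth <- list(
      bud_table = truth$bud_table,
      nucleus_table = truth$nucleus_table,
      vessel_table = truth$vessel_table,
      lvi_pairs = truth$lvi_pairs,
      true_lvd_fraction = truth$true_lvd_fraction,
      mask_pages = c("region", "nucleus", "marker1", "marker2")
    )
  }
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paste0(base, ".json"))
}

#' Read a field (and any ground truth) written by [write_field()]
#'
#' @param sidecar Path to the `.json` sidecar.
#' @return A list with `field` and (when present on disk) `truth`.
#' @export
read_field <- function(sidecar) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  base <- sub("\\.json$", "", sidecar)
  pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
  field <- multiplex_field(pages[[1]], pages[[2]], pages[[3]],
                           pixel_size_um = side$pixel_size_um,
                           field_id = side$field_id,
                           patient_id = side$patient_id)
  out <- list(field = field)
  if (!is.null(side$truth)) {
    masks <- tiff::readTIFF(paste0(base, "_masks.tif"), all = TRUE)
    masks <- lapply(masks, function(m) {
      m <- round(m * 65535)
      storage.mode(m) <- "integer"
      m
    })
    tt <- side$truth
    out$truth <- structure(
      list(region_mask = masks[[1]], nucleus_mask = masks[[2]],
           marker1_mask = masks[[3]], marker2_mask = masks[[4]],
           bud_table = tibble::as_tibble(tt$bud_table),
           nucleus_table = tibble::as_tibble(tt$nucleus_table),
           vessel_table = tibble::as_tibble(tt$vessel_table),
           lvi_pairs = tibble::as_tibble(tt$lvi_pairs),
           true_lvd_fraction = tt$true_lvd_fraction),
      class = "field_truth")
  }
  out
}

#' Export / import region annotations as label-stroke JSON
#'
#' @param annotation A [region_annotation()].
#' @param path Output / input JSON path.
#' @return `write_annotations()`: the path, invisibly.
#'   `read_annotations()`: a `region_annotation`.
#' @export
write_annotations <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  jsonlite::write_json(
    list(field_id = annotation$field_id,
         strokes = lapply(annotation$strokes, function(s) {
           list(label = s$label, pixels = s$pixels)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  strokes <- lapply(seq_len(nrow(x$strokes)), function(i) {
    list(label = x$strokes$label[i],
         pixels = as.integer(x$strokes$pixels[[i]]))
  })
  region_annotation(x$field_id, strokes)
}

#' Write a region map as an 8-bit label TIFF
#'
#' Labels are stored as `code / 255` with the fixed code table of
#' [region_levels()] (1 = Tumour .. 4 = NoTissue).
#'
#' @param region_map Integer region matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_region_map <- function(region_map, path) {
  tiff::writeTIFF(region_map / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  m <- round(tiff::readTIFF(path) * 255)
  storage.mode(m) <- "integer"
  m
}
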