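#' Parameters of the hierarchical object classification
#'
#' Houses the constants of the object-optimisation step: nuclear objects
#' strictly under `debris_area_um2` become debris; marker objects within
#' `edge_distance_um` (inclusive) of no-tissue become edge effect;
#' neighbouring stromal markers merge across `merge_gap_um` (0 means
#' 8-connected touching); a nucleus is associated with a marker object when
#' more than `association_min_fraction` of its area lies inside it; LVI
#' requires at least `lvi_minimum_overlap_px` pixels of bud-vessel overlap.
#'
#' @param debris_area_um2 Debris-nucleus area bound in um^2 (strict `<`).
#' @param edge_distance_um Edge-effect distance in um (inclusive `<=`).
#' @param merge_gap_um Merge gap for neighbouring stromal markers, um.
#' @param association_min_fraction Majority-area fraction for
#'   nucleus-to-marker association (strict `>`).
#' @param lvi_minimum_overlap_px Minimum bud-vessel pixel overlap for LVI.
#' @param include_large_buds Count large buds (>5 nuclei) as LVI-capable;
#'   default restricts LVI to tumour buds (1-5 nuclei).
#' @param autofluorescence Settings of [suppress_autofluorescence()]:
#'   `enabled`, `intensity_range` (object mean-intensity window),
#'   `min_texture_var` (median local variance at/above which an object is
#'   non-specific), `window` (local-variance window, px).
#' @param false_nuclei Same structure, applied to DAPI objects (disabled by
#'   default; synthetic DAPI artefacts are rare).
#' @return A `classification_params` list.
#' @export
classification_params <- function(debris_area_um2 = 16,
                                  edge_distance_um = 50,
                                  merge_gap_um = 0,
                                  association_min_fraction = 0.5,
                                  lvi_minimum_overlap_px = 1L,
                                  include_large_buds = FALSE,
                                  autofluorescence = list(
                                    enabled = TRUE,
                                    intensity_range = c(0.2, 0.68),
                                    min_texture_var = 0.006,
                                    window = 5L
                                  ),
                                  false_nuclei = list(
                                    enabled = FALSE,
                                    intensity_range = c(0.2, 0.68),
                                    min_texture_var = 0.006,
                                    window = 5L
                                  )) {
  stopifnot(debris_area_um2 >= 0, edge_distance_um >= 0, merge_gap_um >= 0,
            association_min_fraction > 0, association_min_fraction < 1,
            lvi_minimum_overlap_px >= 1)
  structure(list(debris_area_um2 = debris_area_um2,
                 edge_distance_um = edge_distance_um,
                 merge_gap_um = merge_gap_um,
                 association_min_fraction = association_min_fraction,
                 lvi_minimum_overlap_px = as.integer(lvi_minimum_overlap_px),
                 include_large_buds = isTRUE(include_large_buds),
                 autofluorescence = autofluorescence,
                 false_nuclei = false_nuclei),
            class = "classification_params")
}

#' Reclassify under-sized nuclear objects as debris
#'
#' Every nucleus with area strictly under `debris_area_um2` (16 um^2 by
#' convention) gets `status = "debris"`; debris never counts as a true
#' nucleus in bud classification.
#'
#' @param nuclei A [segment_nuclei()] result.
#' @param debris_area_um2 Strict area bound in um^2.
#' @return The updated `nucleus_objects`.
#' @export
flag_debris_nuclei <- function(nuclei, debris_area_um2 = 16) {
  stopifnot(inherits(nuclei, "nucleus_objects"))
  st <- nuclei$objects$status
  hit <- st == "nucleus" & nuclei$objects$area_um2 < debris_area_um2
  nuclei$objects$status[hit] <- "debris"
  nuclei
}

#' Flag marker objects near the tissue edge
#'
#' Non-specific antibody staining concentrates near the tissue border.
#' Any marker object whose nearest pixel lies within `edge_distance_um`
#' (inclusive) of a NoTissue pixel, by Euclidean distance transform, is
#' flagged `edge_effect` and excluded downstream. Fields without NoTissue
#' pixels are returned unchanged.
#'
#' @param markers A [segment_marker()] result.
#' @param region_map Integer region matrix per [region_levels()].
#' @param edge_distance_um Inclusive distance bound in um.
#' @param pixel_size_um Pixel edge in micrometres.
#' @return The updated `marker_objects`.
#' @export
flag_edge_effect <- function(markers, region_map, edge_distance_um = 50,
                             pixel_size_um = markers$pixel_size_um) {
  stopifnot(inherits(markers, "marker_objects"))
  if (!any(region_map == 4L) || nrow(markers$objects) == 0) return(markers)
  d <- distance_to(region_map == 4L) * pixel_size_um
  dmin <- min_by_label(markers$mask, d)
  hit_ids <- as.integer(names(dmin))[dmin <= edge_distance_um]
  sel <- markers$objects$object_id %in% hit_ids &
    markers$objects$status == "candidate"
  markers$objects$status[sel] <- "edge_effect"
  markers
}

#' Suppress autofluorescent (non-specific) marker objects
#'
#' Muscle and similar structures autofluoresce in the epithelial channel as
#' mid-intensity, strongly textured objects. Candidates whose mean raw
#' intensity falls inside the configured window and whose median local
#' variance reaches `min_texture_var` are flagged `non_specific` and
#' excluded downstream. Objects under 4 px are left untouched (texture is
#' not computable). Disabled settings return the input unchanged.
#'
#' @param markers A [segment_marker()] result (or `nucleus_objects`; see
#'   [flag_false_nuclei()]).
#' @param channel The raw intensity raster the objects were segmented from.
#' @param settings The `autofluorescence` entry of [classification_params()].
#' @param status_label Status assigned to flagged objects.
#' @return The updated object set.
#' @export
suppress_autofluorescence <- function(markers, channel,
                                      settings = classification_params()$autofluorescence,
                                      status_label = "non_specific") {
  if (!isTRUE(settings$enabled)) return(markers)
  tab <- markers$objects
  if (nrow(tab) == 0) return(markers)
  lv <- local_variance(channel, settings$window %||% 5L)
  idx <- which(markers$mask > 0L)
  labs <- markers$mask[idx]
  mean_int <- tapply(channel[idx], labs, mean)
  med_var <- tapply(lv[idx], labs, median)
  id_col <- if ("object_id" %in% names(tab)) "object_id" else "nucleus_id"
  status_ok <- tab$status %in% c("candidate", "nucleus")
  ids <- as.character(tab[[id_col]])
  hit <- status_ok & tab$area_px >= 4L &
    mean_int[ids] >= settings$intensity_range[1] &
    mean_int[ids] <= settings$intensity_range[2] &
    med_var[ids] >= settings$min_texture_var
  hit[is.na(hit)] <- FALSE
  markers$objects$status[hit] <- status_label
  markers
}

#' @rdname suppress_autofluorescence
#' @param nuclei A [segment_nuclei()] result.
#' @param dapi Raw DAPI raster.
#' @export
flag_false_nuclei <- function(nuclei, dapi,
                              settings = classification_params()$false_nuclei) {
  suppress_autofluorescence(nuclei, dapi, settings,
                            status_label = "false_positive")
}

# Dominant region label under each object (pixel majority; ties resolved by
# the fixed priority Stroma > Tumour > NecrosisLumen > NoTissue).
region_context <- function(lab, region_map) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(character())
  labs <- lab[idx]
  regs <- region_map[idx]
  priority <- c(2L, 1L, 3L, 4L)
  ctx <- tapply(regs, labs, function(r) {
    tt <- table(r)
    codes <- as.integer(names(tt))[tt == max(tt)]
    codes[order(match(codes, priority))][1]
  })
  setNames(REGION_LEVELS[ctx], names(ctx))
}

#' Merge neighbouring stromal marker objects
#'
#' Computes each object's dominant region context; only unflagged candidates
#' whose context is Stroma participate (non-stromal marker pixels are
#' excluded from bud candidacy entirely). Participating objects whose pixel
#' sets lie within `merge_gap_um` of one another (0 means 8-connected
#' touching) are unioned into single merged objects.
#'
#' @param markers A [segment_marker()] result with edge/non-specific flags
#'   already applied.
#' @param region_map Integer region matrix per [region_levels()].
#' @param merge_gap_um Merge gap in um.
#' @return A `merged_markers` list: `mask` (labelled matrix of merged
#'   objects) and `objects` (tibble with `object_id`, areas, centroid,
#'   `n_components`), plus the annotated input table as `source_objects`.
#' @export
merge_stromal_markers <- function(markers, region_map, merge_gap_um = 0) {
  stopifnot(inherits(markers, "marker_objects"))
  ps <- markers$pixel_size_um
  tab <- markers$objects
  ctx <- region_context(markers$mask, region_map)
  tab$region_context <- unname(ctx[as.character(tab$object_id)])
  keep <- tab$status == "candidate" & tab$region_context == "Stroma"
  tab$status[tab$status == "candidate" & tab$region_context != "Stroma"] <-
    "non_stromal"
  part_ids <- tab$object_id[keep]
  base <- markers$mask
  base[!base %in% part_ids] <- 0L
  if (merge_gap_um > 0) {
    gap_px <- ceiling(merge_gap_um / ps / 2)
    grown <- dilate_mask(base, gap_px)
    comp <- label_components(grown)
    merged <- matrix(0L, nrow(base), ncol(base))
    merged[base > 0L] <- comp[base > 0L]
  } else {
    merged <- label_components(base)
  }
  merged <- relabel_sequential(merged)
  mtab <- label_table(merged, ps)
  # how many source objects each merged object unions
  if (nrow(mtab)) {
    idx <- which(base > 0L)
    n_comp <- tapply(base[idx], merged[idx], function(v) length(unique(v)))
    mtab$n_components <- as.integer(n_comp[as.character(mtab$object_id)])
  } else {
    mtab$n_components <- integer()
  }
  structure(list(mask = merged, objects = tibble::as_tibble(mtab),
                 source_objects = tab, marker = markers$marker,
                 pixel_size_um = ps),
            class = "merged_markers")
}

#' Associate nuclei with merged marker objects
#'
#' A nucleus is associated with a marker object when more than
#' `min_fraction` of its pixel area lies inside the object's pixel set (the
#' majority rule; a sliver of a stromal nucleus clipped by a bud is thereby
#' not associated). Counts are split into true nuclei and debris;
#' false-positive nuclei are ignored.
#'
#' @param merged A [merge_stromal_markers()] result.
#' @param nuclei A [flag_debris_nuclei()]-processed `nucleus_objects`.
#' @param min_fraction Strict majority fraction.
#' @return The merged-objects tibble with `n_true_nuclei`, `n_debris_nuclei`
#'   and `nucleus_ids` (list column) appended.
#' @export
associate_nuclei <- function(merged, nuclei, min_fraction = 0.5) {
  stopifnot(inherits(merged, "merged_markers"),
            inherits(nuclei, "nucleus_objects"))
  tab <- merged$objects
  out <- dplyr::mutate(tab, n_true_nuclei = 0L, n_debris_nuclei = 0L,
                       nucleus_ids = list(integer()))
  if (nrow(tab) == 0 || nrow(nuclei$objects) == 0) return(out)
  ov <- overlap_pairs(nuclei$mask, merged$mask)
  if (nrow(ov) == 0) return(out)
  nuc <- nuclei$objects
  ov$nucleus_area <- nuc$area_px[match(ov$id_a, nuc$nucleus_id)]
  ov$status <- nuc$status[match(ov$id_a, nuc$nucleus_id)]
  ov <- ov[ov$overlap_px / ov$nucleus_area > min_fraction &
             ov$status %in% c("nucleus", "debris"), , drop = FALSE]
  if (nrow(ov) == 0) return(out)
  for (i in seq_len(nrow(out))) {
    sub <- ov[ov$id_b == out$object_id[i], , drop = FALSE]
    out$n_true_nuclei[i] <- sum(sub$status == "nucleus")
    out$n_debris_nuclei[i] <- sum(sub$status == "debris")
    out$nucleus_ids[[i]] <- as.integer(sub$id_a)
  }
  out
}

# Pixel-overlap table between two label matrices: one row per (id_a, id_b)
# pair with positive overlap.
overlap_pairs <- function(lab_a, lab_b) {
  idx <- which(lab_a > 0L & lab_b > 0L)
  if (!length(idx)) {
    return(tibble::tibble(id_a = integer(), id_b = integer(),
                          overlap_px = integer()))
  }
  key <- paste(lab_a[idx], lab_b[idx])
  tt <- table(key)
  parts <- strsplit(names(tt), " ", fixed = TRUE)
  tibble::tibble(
    id_a = as.integer(vapply(parts, `[`, character(1), 1L)),
    id_b = as.integer(vapply(parts, `[`, character(1), 2L)),
    overlap_px = as.integer(tt)
  )
}

#' Hierarchically classify merged stromal epithelial objects into bud classes
#'
#' Applies the four-way hierarchy by associated nucleus counts:
#' `irrelevant_marker` (no associated nuclei at all),
#' `bud_with_debris_nucleus` (only debris nuclei associated), `tumour_bud`
#' (1-5 true nuclei) and `large_bud` (over 5 true nuclei). Every merged
#' object receives exactly one class.
#'
#' @param merged A [merge_stromal_markers()] result (epithelial marker).
#' @param nuclei A [flag_debris_nuclei()]-processed `nucleus_objects`.
#' @param min_fraction Association majority fraction.
#' @return A `bud_set` list: `mask` (labelled matrix, ids = `bud_id`) and
#'   `buds` (tibble with `bud_id`, areas, nucleus counts, `bud_class`).
#' @export
classify_buds <- function(merged, nuclei, min_fraction = 0.5) {
  assoc <- associate_nuclei(merged, nuclei, min_fraction)
  cls <- dplyr::case_when(
    assoc$n_true_nuclei == 0L & assoc$n_debris_nuclei == 0L ~ "irrelevant_marker",
    assoc$n_true_nuclei == 0L & assoc$n_debris_nuclei > 0L ~ "bud_with_debris_nucleus",
    assoc$n_true_nuclei >= 1L & assoc$n_true_nuclei <= 5L ~ "tumour_bud",
    TRUE ~ "large_bud"
  )
  buds <- dplyr::mutate(
    dplyr::rename(assoc, bud_id = "object_id"),
    bud_class = factor(cls, levels = BUD_CLASSES)
  )
  structure(list(mask = merged$mask, buds = buds,
                 pixel_size_um = merged$pixel_size_um),
            class = "bud_set")
}

#' @export
print.bud_set <- function(x, ...) {
  tt <- table(x$buds$bud_class)
  cat("<bud_set> ", nrow(x$buds), " objects: ",
      paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assemble lymphatic vessels from stromal D2-40 objects
#'
#' Merges neighbouring stromal Marker-2 objects exactly as for the
#' epithelial marker, then combines each merged wall with its enclosed lumen
#' by hole filling: the vessel's total pixel set is wall union lumen. Open
#' (unclosed) walls enclose no hole and keep an empty lumen.
#'
#' @param markers2 A [segment_marker()] result for the D2-40 channel with
#'   edge flags applied.
#' @param region_map Integer region matrix per [region_levels()].
#' @param merge_gap_um Merge gap in um.
#' @return A `vessel_set` list: `total_mask` and `wall_mask` (labelled
#'   matrices, ids = `vessel_id`) and `vessels` (tibble with wall / lumen /
#'   total pixel counts and `area_um2` of the total).
#' @export
build_vessels <- function(markers2, region_map, merge_gap_um = 0) {
  merged <- merge_stromal_markers(markers2, region_map, merge_gap_um)
  ps <- merged$pixel_size_um
  wall <- merged$mask
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(wall)))
  storage.mode(filled) <- "integer"
  ids <- sort(unique(wall[wall > 0L]))
  if (length(ids)) {
    wall_px <- tabulate(wall[wall > 0L], nbins = max(ids))[ids]
    tot_px <- tabulate(filled[filled > 0L], nbins = max(ids))[ids]
    vessels <- tibble::tibble(
      vessel_id = as.integer(ids),
      wall_px = as.integer(wall_px),
      lumen_px = as.integer(tot_px - wall_px),
      total_px = as.integer(tot_px),
      area_um2 = tot_px * ps^2
    )
  } else {
    vessels <- tibble::tibble(vessel_id = integer(), wall_px = integer(),
                              lumen_px = integer(), total_px = integer(),
                              area_um2 = double())
  }
  structure(list(total_mask = filled, wall_mask = wall, vessels = vessels,
                 source_objects = merged$source_objects,
                 pixel_size_um = ps),
            class = "vessel_set")
}

#' @export
print.vessel_set <- function(x, ...) {
  cat("<vessel_set> ", nrow(x$vessels), " vessels, total area ",
      sprintf("%.1f", sum(x$vessels$area_um2)), " um^2\n", sep = "")
  invisible(x)
}

#' Detect lymphatic vessel invasion by bud-vessel co-localisation
#'
#' Emits one LVI event for every (tumour bud, vessel) pair whose pixel sets
#' overlap by at least `min_overlap_px` pixels (overlap is taken against the
#' vessel's wall-union-lumen set). By default only `tumour_bud` objects
#' (1-5 nuclei) qualify; `include_large_buds` extends candidacy to large
#' buds. A bud overlapping two vessels yields two events.
#'
#' @param buds A [classify_buds()] result.
#' @param vessels A [build_vessels()] result.
#' @param min_overlap_px Minimum pixel overlap (at least 1).
#' @param include_large_buds Also count `large_bud` objects.
#' @return A tibble of events: `event_id`, `bud_id`, `vessel_id`,
#'   `overlap_px`, `overlap_area_um2`.
#' @export
detect_lvi <- function(buds, vessels, min_overlap_px = 1L,
                       include_large_buds = FALSE) {
  stopifnot(inherits(buds, "bud_set"), inherits(vessels, "vessel_set"))
  classes <- "tumour_bud"
  if (include_large_buds) classes <- c(classes, "large_bud")
  ok_ids <- buds$buds$bud_id[buds$buds$bud_class %in% classes]
  empty <- tibble::tibble(event_id = integer(), bud_id = integer(),
                          vessel_id = integer(), overlap_px = integer(),
                          overlap_area_um2 = double())
  if (!length(ok_ids) || nrow(vessels$vessels) == 0) return(empty)
  bud_mask <- buds$mask
  bud_mask[!bud_mask %in% ok_ids] <- 0L
  ov <- overlap_pairs(bud_mask, vessels$total_mask)
  ov <- ov[ov$overlap_px >= min_overlap_px, , drop = FALSE]
  if (nrow(ov) == 0) return(empty)
  ov <- ov[order(ov$id_a, ov$id_b), , drop = FALSE]
  tibble::tibble(
    event_id = seq_len(nrow(ov)),
    bud_id = ov$id_a,
    vessel_id = ov$id_b,
    overlap_px = ov$overlap_px,
    overlap_area_um2 = ov$overlap_px * buds$pixel_size_um^2
  )
}
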