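# Shared fixtures.  Synthetic fields are expensive (~2-3 s each at 512 px),
# so generated fields are cached per test run keyed by their spec seed.

fixture_cache <- new.env(parent = emptyenv())

cached_field <- function(key, spec_fun) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, generate_field(spec_fun()), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# A representative clean field: mixed bud sizes, vessels, one LVI event.
clean_field <- function(seed) {
  cached_field(paste0("clean_", seed), function() {
    field_spec(
      n_buds_by_nucleus_count = c("1" = 1, "2" = 1, "3" = 2, "7" = 1),
      n_vessels = 3, n_lvi_events = 1, n_debris_nuclei = 3,
      noise_sd = 0, seed = seed
    )
  })
}

# Stroma-only field (no tumour mass): segmentation-level counts are exact.
plain_field <- function(seed, noise_sd = 0) {
  cached_field(paste0("plain_", seed, "_", noise_sd), function() {
    field_spec(
      n_buds_by_nucleus_count = c("2" = 2, "3" = 1),
      n_vessels = 2, n_lvi_events = 0, n_debris_nuclei = 2,
      noise_sd = noise_sd, tumour_mass = FALSE, seed = seed
    )
  })
}

# Draw a disk into an existing matrix (used to build tiny rasters directly).
paint_disk <- function(m, row, col, r, value) {
  s <- -r:r
  g <- expand.grid(dr = s, dc = s)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  rr <- g$dr + row; cc <- g$dc + col
  keep <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[keep], cc[keep])] <- value
  m
}

paint_annulus <- function(m, row, col, r_out, r_in, value) {
  s <- -r_out:r_out
  g <- expand.grid(dr = s, dc = s)
  d2 <- g$dr^2 + g$dc^2
  g <- g[d2 <= r_out^2 & d2 > r_in^2, ]
  rr <- g$dr + row; cc <- g$dc + col
  keep <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[keep], cc[keep])] <- value
  m
}

# Wrap a labelled matrix as the marker_objects structure the classification
# operations consume (areas in um^2 at the given pixel size).
as_marker_objects <- function(mask, pixel_size_um = 1, marker = "marker1") {
  ids <- sort(unique(mask[mask > 0]))
  if (!length(ids)) {
    return(structure(list(
      mask = mask,
      objects = tibble::tibble(object_id = integer(), area_px = integer(),
                               area_um2 = double(), centroid_row = double(),
                               centroid_col = double(), marker = character(),
                               status = character()),
      marker = marker, pixel_size_um = pixel_size_um),
      class = "marker_objects"))
  }
  idx <- which(mask > 0)
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  labs <- mask[idx]
  objects <- tibble::tibble(
    object_id = as.integer(ids),
    area_px = as.integer(tabulate(labs, nbins = max(ids))[ids]),
    area_um2 = tabulate(labs, nbins = max(ids))[ids] * pixel_size_um^2,
    centroid_row = as.vector(tapply(rows, labs, mean)[as.character(ids)]),
    centroid_col = as.vector(tapply(cols, labs, mean)[as.character(ids)]),
    marker = marker,
    status = "candidate"
  )
  structure(list(mask = mask, objects = objects, marker = marker,
                 pixel_size_um = pixel_size_um),
            class = "marker_objects")
}

as_nucleus_objects <- function(mask, pixel_size_um = 1) {
  mo <- as_marker_objects(mask, pixel_size_um)
  objects <- dplyr::rename(mo$objects, nucleus_id = "object_id")
  objects$marker <- NULL
  objects$status <- "nucleus"
  structure(list(mask = mask, objects = objects,
                 pixel_size_um = pixel_size_um),
            class = "nucleus_objects")
}

# Map each detected object id to the planted object id it most overlaps
# (NA when it overlaps nothing); used for precision/recall bookkeeping.
match_to_truth <- function(detected_mask, truth_mask, ids) {
  vapply(ids, function(i) {
    ov <- truth_mask[detected_mask == i]
    ov <- ov[ov > 0]
    if (!length(ov)) return(NA_integer_)
    as.integer(names(sort(table(ov), decreasing = TRUE))[1])
  }, integer(1))
}

# Small survival toy with hand-computable product-limit estimates.
toy_records <- function() {
  tibble::tibble(
    patient_id = paste0("p", 1:6),
    time = c(1, 2, 3, 4, 5, 6),
    event = c(1, 1, 0, 1, 0, 1)
  )
}
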