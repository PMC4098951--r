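#' Generate a synthetic multiplexed-IF field with exhaustive ground truth
#'
#' Renders a three-channel field (DAPI, pan-cytokeratin, D2-40) emulating a
#' colorectal invasive front: a no-tissue border, a stromal compartment, an
#' optional cohesive tumour mass with a necrosis/lumen pocket, detached
#' epithelial buds carrying known nucleus counts, annular lymphatic vessels
#' with dark lumina, planted bud-in-vessel events, sub-16-um^2 nuclear
#' debris, optional tissue-edge staining and textured autofluorescence
#' streaks. Every planted structure is recorded in labelled ground-truth
#' masks and tables, so downstream segmentation and classification stages
#' can be validated object-for-object.
#'
#' Object placement uses rejection sampling with a minimum 3-pixel
#' separation between distinct objects of the same mask, bounded at 1000
#' retries per object; geometric infeasibility raises a
#' `budquant_placement_error`. All randomness flows from `spec$seed` and the
#' function is deterministic given the spec.
#'
#' @param spec A [field_spec()].
#' @param field_id,patient_id Identifiers stored on the returned field.
#'
#' @return A list with elements `field` (a [multiplex_field()]) and `truth`,
#'   where `truth` contains `region_mask` (integer matrix coded per
#'   [region_levels()]), labelled `nucleus_mask`, `marker1_mask` and
#'   `marker2_mask`, tibbles `bud_table`, `nucleus_table`, `vessel_table`
#'   and `lvi_pairs`, and `true_lvd_fraction` (planted vessel area divided
#'   by stromal area).
#' @export
#' @examples
#' out <- generate_field(field_spec(width_px = 256, height_px = 256,
#'                                  n_buds_by_nucleus_count = c("2" = 2),
#'                                  n_vessels = 1, n_lvi_events = 0,
#'                                  n_debris_nuclei = 1, seed = 42))
#' nrow(out$truth$bud_table)
generate_field <- function(spec, field_id = "field_1", patient_id = "patient_1") {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, generate_field_impl(spec, field_id, patient_id))
}

generate_field_impl <- function(spec, field_id, patient_id) {
  H <- spec$height_px; W <- spec$width_px; ps <- spec$pixel_size_um

  region <- make_region_mask(H, W, spec$tumour_mass)
  stroma <- region == 2L

  # distance (px) of each pixel to the nearest non-stromal / no-tissue pixel
  d_core <- distance_to(region != 2L)
  d_nt <- distance_to(region == 4L)
  edge_clear_px <- ceiling(50 / ps) + 10   # objects stay clear of edge zone

  nucleus_mask <- matrix(0L, H, W)
  marker1_mask <- matrix(0L, H, W)
  marker2_mask <- matrix(0L, H, W)
  m1_zone <- matrix(FALSE, H, W)   # bud pixels + 3 px separation
  m2_zone <- matrix(FALSE, H, W)   # vessel total pixels + 3 px separation
  nuc_zone <- matrix(FALSE, H, W)  # nucleus pixels + 3 px separation

  sep_px <- 3L
  stroma_idx <- which(stroma)

  sample_centre <- function(r_need, clear_extra = 0, extra_ok = NULL) {
    # one random candidate centre deep enough in stroma and clear of the edge
    for (i in seq_len(1000L)) {
      idx <- stroma_idx[sample.int(length(stroma_idx), 1L)]
      row <- ((idx - 1L) %% H) + 1L
      col <- ((idx - 1L) %/% H) + 1L
      if (d_core[idx] < r_need + 4) next
      if (d_nt[idx] < edge_clear_px + r_need + clear_extra) next
      if (!is.null(extra_ok) && !extra_ok(row, col)) next
      return(c(row, col))
    }
    abort("Object placement failed after 1000 retries; the requested objects do not fit the field.",
          class = "budquant_placement_error")
  }

  free_at <- function(px, zones) {
    idx <- px_index(px, H)
    for (z in zones) if (any(z[idx])) return(FALSE)
    TRUE
  }

  claim <- function(zone, row, col, r) {
    px <- offsets_at(disk_offsets(r + sep_px), row, col, H, W, clip = TRUE)
    zone[px_index(px, H)] <- TRUE
    zone
  }

  # ---- expand the bud plan ------------------------------------------------
  nb <- spec$n_buds_by_nucleus_count
  bud_k <- if (length(nb)) rep(as.integer(names(nb)), nb) else integer()
  n_buds <- length(bud_k)
  # LVI buds must be tumour buds (1-5 nuclei); take the smallest-k candidates
  lvi_bud_ids <- integer()
  if (spec$n_lvi_events > 0L) {
    cand <- order(bud_k)[bud_k[order(bud_k)] <= 5L]
    lvi_bud_ids <- head(cand, spec$n_lvi_events)
  }

  # nucleus radii feasible at this calibration
  rn_range <- nucleus_radius_range(ps)
  rd_range <- debris_radius_range(ps)

  bud_geom <- lapply(bud_k, function(k) bud_layout(k, rn_range))

  # ---- vessels ------------------------------------------------------------
  vessel_rows <- list()
  vessel_centres <- matrix(0, nrow = max(spec$n_vessels, 1), ncol = 2)
  vessel_geom <- list()
  if (spec$n_vessels > 0L) {
    for (v in seq_len(spec$n_vessels)) {
      r_out <- sample(10:16, 1L)
      thick <- sample(2:4, 1L)
      # vessels receiving an LVI bud need room for the bud beside them
      extra <- if (v <= spec$n_lvi_events) {
        bud_geom[[lvi_bud_ids[v]]]$r_bud * 2 + 6
      } else 0
      repeat_placed <- FALSE
      for (try in seq_len(1000L)) {
        ctr <- sample_centre(r_out + extra)
        wall <- offsets_at(annulus_offsets(r_out, r_out - thick),
                           ctr[1], ctr[2], H, W)
        if (!in_bounds(wall, H, W)) next
        tot <- offsets_at(disk_offsets(r_out), ctr[1], ctr[2], H, W)
        if (!free_at(tot, list(m2_zone, m1_zone))) next
        marker2_mask[px_index(wall, H)] <- v
        m2_zone <- claim(m2_zone, ctr[1], ctr[2], r_out)
        vessel_centres[v, ] <- ctr
        vessel_geom[[v]] <- list(r_out = r_out, thick = thick)
        lumen_n <- nrow(disk_offsets(r_out - thick))
        vessel_rows[[v]] <- tibble::tibble(
          vessel_id = v, centre_row = ctr[1], centre_col = ctr[2],
          r_out_px = r_out, wall_thickness_px = thick,
          wall_px = nrow(wall), lumen_px = lumen_n,
          total_px = nrow(wall) + lumen_n
        )
        repeat_placed <- TRUE
        break
      }
      if (!repeat_placed) {
        abort("Vessel placement failed after 1000 retries.",
              class = "budquant_placement_error")
      }
    }
  }

  # ---- buds (LVI buds first, attached to their vessels) -------------------
  bud_rows <- list()
  nucleus_rows <- list()
  lvi_rows <- list()
  next_nucleus_id <- 0L
  bud_order <- c(lvi_bud_ids, setdiff(seq_len(n_buds), lvi_bud_ids))
  for (b in bud_order) {
    g <- bud_geom[[b]]
    is_lvi <- b %in% lvi_bud_ids
    placed <- FALSE
    for (try in seq_len(1000L)) {
      if (is_lvi) {
        v <- match(b, lvi_bud_ids)
        vc <- vessel_centres[v, ]
        ang <- runif(1, 0, 2 * pi)
        d <- vessel_geom[[v]]$r_out + g$r_bud - 3  # ~3 px overlap with wall
        ctr <- round(c(vc[1] + d * sin(ang), vc[2] + d * cos(ang)))
      } else {
        ctr <- sample_centre(g$r_bud)
      }
      px <- offsets_at(disk_offsets(g$r_bud), ctr[1], ctr[2], H, W)
      if (!in_bounds(px, H, W)) next
      idx <- px_index(px, H)
      if (any(region[idx] != 2L)) next
      if (any(d_nt[idx] <= ceiling(50 / ps) + 4)) next
      if (any(m1_zone[idx])) next
      if (is_lvi) {
        # may touch only its own vessel
        other <- m2_zone
        v <- match(b, lvi_bud_ids)
        own <- offsets_at(disk_offsets(vessel_geom[[v]]$r_out + sep_px),
                          vessel_centres[v, 1], vessel_centres[v, 2],
                          H, W, clip = TRUE)
        other[px_index(own, H)] <- FALSE
        if (any(other[idx])) next
        overlap <- sum(marker2_mask[idx] == v)
        if (overlap < 1L) next
      } else {
        if (any(m2_zone[idx])) next
      }
      # nuclei inside the bud
      nuc <- place_bud_nuclei(g, ctr, H, W, nuc_zone)
      if (is.null(nuc)) next
      marker1_mask[idx] <- b
      m1_zone <- claim(m1_zone, ctr[1], ctr[2], g$r_bud)
      for (j in seq_along(nuc$centres_row)) {
        next_nucleus_id <- next_nucleus_id + 1L
        npx <- offsets_at(disk_offsets(nuc$radii[j]),
                          nuc$centres_row[j], nuc$centres_col[j], H, W)
        nucleus_mask[px_index(npx, H)] <- next_nucleus_id
        nuc_zone <- claim(nuc_zone, nuc$centres_row[j], nuc$centres_col[j],
                          nuc$radii[j])
        nucleus_rows[[length(nucleus_rows) + 1L]] <- tibble::tibble(
          nucleus_id = next_nucleus_id, bud_id = b, type = "nucleus",
          area_px = nrow(npx), area_um2 = nrow(npx) * ps^2,
          centre_row = nuc$centres_row[j], centre_col = nuc$centres_col[j]
        )
      }
      bud_rows[[b]] <- tibble::tibble(
        bud_id = b, n_nuclei = g$k,
        planted_class = if (g$k <= 5L) "tumour_bud" else "large_bud",
        is_lvi = is_lvi, area_px = nrow(px),
        centre_row = ctr[1], centre_col = ctr[2], r_bud_px = g$r_bud
      )
      if (is_lvi) {
        v <- match(b, lvi_bud_ids)
        lvi_rows[[length(lvi_rows) + 1L]] <- tibble::tibble(
          bud_id = b, vessel_id = v
        )
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("Bud placement failed after 1000 retries.",
            class = "budquant_placement_error")
    }
  }

  # ---- debris nuclei ------------------------------------------------------
  if (spec$n_debris_nuclei > 0L) {
    for (dn in seq_len(spec$n_debris_nuclei)) {
      rd <- sample(rd_range, 1L)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        ctr <- sample_centre(rd)
        px <- offsets_at(disk_offsets(rd), ctr[1], ctr[2], H, W)
        if (!in_bounds(px, H, W)) next
        idx <- px_index(px, H)
        if (!free_at(px, list(nuc_zone, m1_zone, m2_zone))) next
        next_nucleus_id <- next_nucleus_id + 1L
        nucleus_mask[idx] <- next_nucleus_id
        nuc_zone <- claim(nuc_zone, ctr[1], ctr[2], rd)
        nucleus_rows[[length(nucleus_rows) + 1L]] <- tibble::tibble(
          nucleus_id = next_nucleus_id, bud_id = NA_integer_, type = "debris",
          area_px = nrow(px), area_um2 = nrow(px) * ps^2,
          centre_row = ctr[1], centre_col = ctr[2]
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("Debris placement failed after 1000 retries.",
              class = "budquant_placement_error")
      }
    }
  }

  # ---- render channels ----------------------------------------------------
  ch <- render_channels(region, nucleus_mask, marker1_mask, marker2_mask,
                        vessel_rows, vessel_centres, vessel_geom, spec,
                        d_nt, d_core, m1_zone, m2_zone, stroma_idx, H, W)

  field <- multiplex_field(ch$dapi, ch$marker1, ch$marker2, ps,
                           field_id = field_id, patient_id = patient_id)

  vessel_table <- if (length(vessel_rows)) dplyr::bind_rows(vessel_rows) else
    tibble::tibble(vessel_id = integer(), centre_row = double(),
                   centre_col = double(), r_out_px = integer(),
                   wall_thickness_px = integer(), wall_px = integer(),
                   lumen_px = integer(), total_px = integer())
  bud_table <- if (length(bud_rows)) dplyr::bind_rows(bud_rows) else
    tibble::tibble(bud_id = integer(), n_nuclei = integer(),
                   planted_class = character(), is_lvi = logical(),
                   area_px = integer(), centre_row = double(),
                   centre_col = double(), r_bud_px = integer())
  nucleus_table <- if (length(nucleus_rows)) dplyr::bind_rows(nucleus_rows) else
    tibble::tibble(nucleus_id = integer(), bud_id = integer(),
                   type = character(), area_px = integer(),
                   area_um2 = double(), centre_row = double(),
                   centre_col = double())
  lvi_pairs <- if (length(lvi_rows)) dplyr::bind_rows(lvi_rows) else
    tibble::tibble(bud_id = integer(), vessel_id = integer())

  stroma_px <- sum(region == 2L)
  true_lvd <- if (stroma_px > 0 && nrow(vessel_table)) {
    sum(vessel_table$total_px) / stroma_px
  } else 0

  truth <- structure(
    list(region_mask = region,
         nucleus_mask = nucleus_mask,
         marker1_mask = marker1_mask,
         marker2_mask = marker2_mask,
         bud_table = bud_table,
         nucleus_table = nucleus_table,
         vessel_table = vessel_table,
         lvi_pairs = lvi_pairs,
         true_lvd_fraction = true_lvd),
    class = "field_truth"
  )
  list(field = field, truth = truth)
}

# Region layout: no-tissue strip on the left with a wavy border, optional
# tumour mass on the right with a wavy invasive front and a necrosis pocket,
# stroma elsewhere.  Codes follow region_levels().
make_region_mask <- function(H, W, tumour_mass) {
  region <- matrix(2L, H, W)
  rows <- seq_len(H)
  nt_base <- round(0.09 * W)
  nt_edge <- pmax(4, nt_base + round(6 * sin(rows / H * 4 * pi)))
  for (r in rows) region[r, seq_len(nt_edge[r])] <- 4L
  if (tumour_mass) {
    tum_base <- round(0.73 * W)
    tum_edge <- pmin(W - 4, tum_base + round(10 * sin(rows / H * 3 * pi + 1)))
    for (r in rows) region[r, tum_edge[r]:W] <- 1L
    # necrosis/lumen pocket inside the tumour
    cr <- H / 2; cc <- (tum_base + W) / 2
    a <- 0.05 * W; b <- 0.12 * H
    px <- ellipse_offsets(a, b, 0)
    px <- offsets_at(px, round(cr), round(cc), H, W, clip = TRUE)
    idx <- px_index(px, H)
    idx <- idx[region[idx] == 1L]
    region[idx] <- 3L
  }
  region
}

# Radii (px) whose rasterised disk area lands in the true-nucleus /
# debris-nucleus area windows at this calibration.
nucleus_radius_range <- function(ps) {
  r <- 1:30
  areas <- vapply(r, function(x) nrow(disk_offsets(x)), numeric(1)) * ps^2
  ok <- r[areas >= 18 & areas <= 42]
  if (!length(ok)) {
    abort("No feasible nucleus radius at this pixel size.",
          class = "budquant_spec_error")
  }
  ok
}

debris_radius_range <- function(ps) {
  r <- 1:10
  areas <- vapply(r, function(x) nrow(disk_offsets(x)), numeric(1)) * ps^2
  ok <- r[areas <= 12]
  if (!length(ok)) {
    abort("No feasible debris radius at this pixel size.",
          class = "budquant_spec_error")
  }
  ok
}

# Sunflower (phyllotaxis) layout of k nucleus centres inside a bud, grown
# until pairwise separation is at least 2*r_nucleus_max + 3 px.  Deterministic
# apart from seeded radius draws and a whole-pattern rotation.
bud_layout <- function(k, rn_range) {
  rn <- sample(rn_range, k, replace = TRUE)
  rn_max <- max(rn_range)
  min_sep <- 2 * rn_max + 3
  if (k == 1L) {
    return(list(k = k, radii = rn, rel_row = 0, rel_col = 0,
                r_bud = rn_max + 6))
  }
  R_c <- min_sep * sqrt(k) / 1.8
  golden <- pi * (3 - sqrt(5))
  rot <- runif(1, 0, 2 * pi)
  repeat {
    rad <- R_c * sqrt((seq_len(k) - 0.5) / k)
    ang <- seq_len(k) * golden + rot
    y <- rad * sin(ang); x <- rad * cos(ang)
    dmin <- min(stats::dist(cbind(y, x)))
    if (dmin >= min_sep) break
    R_c <- R_c * 1.12
  }
  list(k = k, radii = rn, rel_row = y, rel_col = x,
       r_bud = ceiling(R_c + rn_max + 3))
}

# Concrete nucleus centres for one bud placement; NULL if any falls outside
# the image or collides with already-claimed nucleus pixels.
place_bud_nuclei <- function(g, ctr, H, W, nuc_zone) {
  rows <- round(ctr[1] + g$rel_row)
  cols <- round(ctr[2] + g$rel_col)
  for (j in seq_len(g$k)) {
    px <- offsets_at(disk_offsets(g$radii[j]), rows[j], cols[j], H, W)
    if (!in_bounds(px, H, W)) return(NULL)
    if (any(nuc_zone[px_index(px, H)])) return(NULL)
  }
  list(centres_row = rows, centres_col = cols, radii = g$radii)
}

# Paint the three channels: region base intensities, planted objects,
# artefacts, then additive noise.
render_channels <- function(region, nucleus_mask, marker1_mask, marker2_mask,
                            vessel_rows, vessel_centres, vessel_geom, spec,
                            d_nt, d_core, m1_zone, m2_zone, stroma_idx, H, W) {
  ps <- spec$pixel_size_um
  dapi <- matrix(0.01, H, W)
  m1 <- matrix(0.01, H, W)
  m2 <- matrix(0.01, H, W)

  st <- region == 2L
  dapi[st] <- 0.10; m1[st] <- 0.06; m2[st] <- 0.05
  tu <- region == 1L
  if (any(tu)) {
    n_tu <- sum(tu)
    dapi[tu] <- pmax(0.20 + rnorm(n_tu, 0, 0.02), 0)
    m1[tu] <- pmax(0.75 + rnorm(n_tu, 0, 0.03), 0)
    m2[tu] <- 0.06
  }
  ne <- region == 3L
  if (any(ne)) {
    n_ne <- sum(ne)
    dapi[ne] <- 0.05
    m1[ne] <- pmax(0.18 + runif(n_ne, -0.05, 0.05), 0)
    m2[ne] <- 0.05
  }

  # planted objects
  dapi[nucleus_mask > 0L] <- 0.9
  m1[marker1_mask > 0L] <- 0.85
  m2[marker2_mask > 0L] <- 0.9

  # tissue-edge staining artefact (painted, not a ground-truth object)
  if (spec$edge_artifact) {
    zone_max <- floor(42 / ps)
    cand <- which(st & d_nt > 8 & d_nt < zone_max & !m1_zone & !m2_zone)
    if (length(cand)) {
      n_blob <- 3L
      for (bidx in seq_len(n_blob)) {
        centre <- cand[sample.int(length(cand), 1L)]
        row <- ((centre - 1L) %% H) + 1L
        col <- ((centre - 1L) %/% H) + 1L
        r <- sample(4:7, 1L)
        px <- offsets_at(disk_offsets(r), row, col, H, W, clip = TRUE)
        idx <- px_index(px, H)
        idx <- idx[d_nt[idx] < floor(48 / ps)]
        if (bidx %% 2L == 1L) m1[idx] <- 0.6 else m2[idx] <- 0.6
      }
    }
  }

  # textured autofluorescence streaks in the epithelial channel
  if (spec$autofluorescence_level > 0) {
    n_streak <- max(1L, round(4 * spec$autofluorescence_level))
    for (s in seq_len(n_streak)) {
      a <- runif(1, 15, 28); b <- runif(1, 4, 8); th <- runif(1, 0, pi)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        idx0 <- stroma_idx[sample.int(length(stroma_idx), 1L)]
        if (d_core[idx0] < a + 4) next
        if (d_nt[idx0] < ceiling(50 / ps) + a + 10) next
        row <- ((idx0 - 1L) %% H) + 1L
        col <- ((idx0 - 1L) %/% H) + 1L
        px <- offsets_at(ellipse_offsets(a, b, th), row, col, H, W)
        if (!in_bounds(px, H, W)) next
        idx <- px_index(px, H)
        if (any(m1_zone[idx]) || any(m2_zone[idx])) next
        amp <- 0.18 * spec$autofluorescence_level
        m1[idx] <- pmin(pmax(0.5 + runif(length(idx), -amp, amp), 0), 1)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("Autofluorescence streak placement failed after 1000 retries.",
              class = "budquant_placement_error")
      }
    }
  }

  if (spec$noise_sd > 0) {
    n <- H * W
    dapi <- dapi + rnorm(n, 0, spec$noise_sd)
    m1 <- m1 + rnorm(n, 0, spec$noise_sd)
    m2 <- m2 + rnorm(n, 0, spec$noise_sd)
  }
  list(dapi = pmin(pmax(dapi, 0), 1),
       marker1 = pmin(pmax(m1, 0), 1),
       marker2 = pmin(pmax(m2, 0), 1))
}
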