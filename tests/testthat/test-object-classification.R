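test_that("the debris rule is a strict 16 um^2 bound", {
  mask <- matrix(0L, 32, 32)
  mask <- paint_disk(mask, 8, 8, 1, 1L)     # 5 px = 10 um^2 at sqrt(2) um/px
  mask[20:23, 20:23] <- 2L                  # 16 px = 32 um^2
  nuc <- as_nucleus_objects(mask, pixel_size_um = sqrt(2))
  nuc$objects$area_um2 <- c(10, 16)         # exact boundary probe
  out <- flag_debris_nuclei(nuc, 16)
  expect_identical(out$objects$status, c("debris", "nucleus"))
  empty <- as_nucleus_objects(matrix(0L, 8, 8))
  expect_identical(nrow(flag_debris_nuclei(empty)$objects), 0L)
})

test_that("the edge-effect rule is an inclusive 50 um distance bound", {
  # no-tissue strip in columns 1..10; 1 um/px
  region <- matrix(2L, 128, 128)
  region[, 1:10] <- 4L
  mask <- matrix(0L, 128, 128)
  mask <- paint_disk(mask, 64, 40, 3, 1L)   # nearest pixel 27 px from strip
  mask <- paint_disk(mask, 64, 73, 3, 2L)   # nearest pixel 60 px away
  mk <- as_marker_objects(mask, pixel_size_um = 1)
  out <- flag_edge_effect(mk, region, 50, 1)
  expect_identical(out$objects$status, c("edge_effect", "candidate"))
  # a field without no-tissue flags nothing
  out2 <- flag_edge_effect(mk, matrix(2L, 128, 128), 50, 1)
  expect_true(all(out2$objects$status == "candidate"))
})

test_that("textured autofluorescence is suppressed while true buds are
           retained", {
  out <- cached_field("af_field", function() {
    field_spec(n_buds_by_nucleus_count = c("3" = 2), n_vessels = 0,
               n_lvi_events = 0, n_debris_nuclei = 0,
               autofluorescence_level = 0.8, noise_sd = 0.05, seed = 91)
  })
  ps <- 0.5
  thr <- select_marker_threshold(out$field$channels$marker1,
                                 out$truth$region_mask)
  m1 <- segment_marker(out$field$channels$marker1, thr, 5, ps, "marker1")
  flagged <- suppress_autofluorescence(m1, out$field$channels$marker1)
  tab <- flagged$objects
  # every planted bud is retained as candidate
  planted <- match_to_truth(flagged$mask, out$truth$marker1_mask,
                            tab$object_id)
  expect_true(all(tab$status[!is.na(planted) & tab$area_px > 100] == "candidate"))
  # at least one sizeable streak object was flagged
  expect_true(any(tab$status == "non_specific" & tab$area_px >= 50))
  # and nothing but streaks was flagged
  expect_true(all(is.na(planted[tab$status == "non_specific"])))
  # disabled settings are the identity
  off <- suppress_autofluorescence(m1, out$field$channels$marker1,
                                   list(enabled = FALSE))
  expect_identical(off, m1)
})

test_that("stromal merging unions touching objects and drops non-stromal
           marker pixels", {
  region <- matrix(2L, 64, 64)
  region[, 1:20] <- 1L                       # tumour on the left
  mask <- matrix(0L, 64, 64)
  mask[30:34, 30:34] <- 1L
  mask[30:34, 35:39] <- 2L                   # touches object 1
  mask[50:54, 50:54] <- 3L                   # separate
  mask[28:36, 16:24] <- 4L                   # majority inside tumour
  mk <- as_marker_objects(mask, pixel_size_um = 1)
  merged <- merge_stromal_markers(mk, region, merge_gap_um = 0)
  expect_identical(nrow(merged$objects), 2L)
  expect_setequal(merged$objects$n_components, c(2L, 1L))
  expect_identical(
    merged$source_objects$status[merged$source_objects$object_id == 4L],
    "non_stromal")
  # a positive merge gap unions nearby but non-touching objects
  gap_mask <- matrix(0L, 64, 64)
  gap_mask[10:14, 10:14] <- 1L
  gap_mask[10:14, 18:22] <- 2L               # 3 px apart
  merged2 <- merge_stromal_markers(as_marker_objects(gap_mask, 1),
                                   matrix(2L, 64, 64), merge_gap_um = 4)
  expect_identical(nrow(merged2$objects), 1L)
  merged3 <- merge_stromal_markers(as_marker_objects(gap_mask, 1),
                                   matrix(2L, 64, 64), merge_gap_um = 0)
  expect_identical(nrow(merged3$objects), 2L)
})

test_that("nucleus association follows the majority-area rule", {
  region <- matrix(2L, 96, 96)
  bud <- matrix(0L, 96, 96)
  bud <- paint_disk(bud, 48, 48, 20, 1L)
  mk <- as_marker_objects(bud, pixel_size_um = 1)
  merged <- merge_stromal_markers(mk, region)
  nmask <- matrix(0L, 96, 96)
  nmask <- paint_disk(nmask, 44, 44, 4, 1L)  # fully inside
  nmask <- paint_disk(nmask, 52, 52, 4, 2L)  # fully inside
  nmask <- paint_disk(nmask, 40, 56, 4, 3L)  # fully inside
  nmask <- paint_disk(nmask, 48, 70, 5, 4L)  # ~10% sliver inside
  nmask <- paint_disk(nmask, 56, 44, 2, 5L)  # small: debris, inside
  nuc <- as_nucleus_objects(nmask, pixel_size_um = 1)
  nuc$objects$status[5] <- "debris"
  res <- associate_nuclei(merged, nuc)
  expect_identical(res$n_true_nuclei, 3L)
  expect_identical(res$n_debris_nuclei, 1L)
  expect_setequal(res$nucleus_ids[[1]], c(1L, 2L, 3L, 5L))
})

test_that("bud classes follow the four-way nucleus-count hierarchy", {
  region <- matrix(2L, 200, 200)
  bud <- matrix(0L, 200, 200)
  centres <- list(c(30, 30), c(30, 100), c(100, 30), c(110, 120))
  for (i in seq_along(centres)) {
    bud <- paint_disk(bud, centres[[i]][1], centres[[i]][2], 24, i)
  }
  nmask <- matrix(0L, 200, 200)
  nid <- 0L
  add_nuc <- function(m, row, col, r) {
    nid <<- nid + 1L
    paint_disk(m, row, col, r, nid)
  }
  # object 2: 3 true nuclei -> tumour_bud
  nmask <- add_nuc(nmask, 22, 95, 3); nmask <- add_nuc(nmask, 34, 92, 3)
  nmask <- add_nuc(nmask, 30, 108, 3)
  # object 3: 2 debris only -> bud_with_debris_nucleus
  nmask <- add_nuc(nmask, 95, 25, 1); nmask <- add_nuc(nmask, 104, 36, 1)
  # object 4: 7 true nuclei on a wide ring -> large_bud
  for (k in 1:7) {
    nmask <- add_nuc(nmask, 110 + round(12 * sin(2 * pi * k / 7)),
                     120 + round(12 * cos(2 * pi * k / 7)), 2)
  }
  nuc <- as_nucleus_objects(nmask, pixel_size_um = 3)  # 9 um^2/px
  nuc$objects$status <- "nucleus"
  nuc$objects$status[4:5] <- "debris"                  # the two in bud 3
  merged <- merge_stromal_markers(as_marker_objects(bud, 3), region)
  buds <- classify_buds(merged, nuc)
  # map merged ids back to the planted centres (relabelling reorders ids)
  class_at <- function(centre) {
    d <- (buds$buds$centroid_row - centre[1])^2 +
      (buds$buds$centroid_col - centre[2])^2
    as.character(buds$buds$bud_class[which.min(d)])
  }
  expect_identical(class_at(centres[[1]]), "irrelevant_marker")
  expect_identical(class_at(centres[[2]]), "tumour_bud")
  expect_identical(class_at(centres[[3]]), "bud_with_debris_nucleus")
  expect_identical(class_at(centres[[4]]), "large_bud")
  # partition: every object classified exactly once
  expect_identical(sum(table(buds$buds$bud_class)), nrow(merged$objects))
})

test_that("vessel assembly fills enclosed lumina and leaves open walls
           empty", {
  region <- matrix(2L, 128, 128)
  m <- matrix(0L, 128, 128)
  m <- paint_annulus(m, 40, 40, 12, 9, 1L)   # closed ring
  m <- paint_disk(m, 40, 90, 6, 2L)          # solid blob
  # open C: remove a chord of the ring
  m2 <- paint_annulus(matrix(0L, 128, 128), 90, 64, 12, 9, 1L)
  m2[86:94, 64:78] <- 0L
  m[m2 > 0] <- 3L
  mk <- as_marker_objects(m, pixel_size_um = 1, marker = "marker2")
  vs <- build_vessels(mk, region)
  v <- vs$vessels[order(vs$vessels$vessel_id), ]
  ring_wall <- sum(m == 1L)
  lumen_expect <- nrow(budquant:::disk_offsets(9))
  ring <- v[which.max(v$lumen_px), ]
  expect_identical(ring$wall_px, as.integer(ring_wall))
  expect_identical(ring$lumen_px, as.integer(lumen_expect))
  expect_identical(ring$total_px, as.integer(ring_wall + lumen_expect))
  others <- v$lumen_px[-which.max(v$lumen_px)]
  expect_true(all(others == 0L))             # solid blob and open C
})

test_that("LVI events are pair-wise pixel co-localisations of tumour buds
           and vessels", {
  region <- matrix(2L, 128, 128)
  bud_mask <- matrix(0L, 128, 128)
  bud_mask <- paint_disk(bud_mask, 64, 60, 10, 1L)    # spans two vessels
  bud_mask <- paint_disk(bud_mask, 20, 20, 6, 2L)     # disjoint from vessels
  nmask <- matrix(0L, 128, 128)
  nmask <- paint_disk(nmask, 64, 60, 3, 1L)
  nmask <- paint_disk(nmask, 20, 20, 3, 2L)
  nuc <- as_nucleus_objects(nmask, pixel_size_um = 5)  # 25 um^2 per px: true
  vmask <- matrix(0L, 128, 128)
  vmask <- paint_annulus(vmask, 64, 45, 10, 7, 1L)
  vmask <- paint_annulus(vmask, 64, 76, 10, 7, 2L)
  merged <- merge_stromal_markers(as_marker_objects(bud_mask, 1), region)
  buds <- classify_buds(merged, nuc)
  vessels <- build_vessels(as_marker_objects(vmask, 1, "marker2"), region)
  ev <- detect_lvi(buds, vessels)
  expect_identical(nrow(ev), 2L)
  expect_identical(length(unique(ev$vessel_id)), 2L)
  expect_true(all(ev$overlap_px >= 1))
  spanning_id <- buds$buds$bud_id[which.min(abs(buds$buds$centroid_col - 60))]
  disjoint_id <- buds$buds$bud_id[which.min(abs(buds$buds$centroid_col - 20))]
  expect_true(all(ev$bud_id == spanning_id))
  # the disjoint bud is a tumour bud yet generates no event
  expect_identical(as.character(
    buds$buds$bud_class[buds$buds$bud_id == disjoint_id]), "tumour_bud")
  expect_false(disjoint_id %in% ev$bud_id)
})

test_that("planted fields recover their LVI pairs exactly", {
  out <- clean_field(2)
  res <- process_field(out$field, out$truth$region_mask)
  expect_identical(nrow(res$lvi_events), nrow(out$truth$lvi_pairs))
  # the detected pair maps back to the planted pair through the masks
  if (nrow(res$lvi_events)) {
    b_map <- match_to_truth(res$buds$mask, out$truth$marker1_mask,
                            res$lvi_events$bud_id)
    v_map <- match_to_truth(res$vessels$wall_mask, out$truth$marker2_mask,
                            res$lvi_events$vessel_id)
    expect_setequal(paste(b_map, v_map),
                    paste(out$truth$lvi_pairs$bud_id,
                          out$truth$lvi_pairs$vessel_id))
  }
})

test_that("debris and edge filters agree with brute-force re-checks on
           randomised object sets", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 40; ps <- runif(1, 0.4, 1.2)
    mask <- matrix(0L, n, n)
    k <- sample(2:5, 1)
    for (i in seq_len(k)) {
      r <- sample(1:3, 1)
      mask <- paint_disk(mask, sample(5:(n - 5), 1), sample(5:(n - 5), 1),
                         r, i)
    }
    present <- sort(unique(mask[mask > 0]))
    mask[] <- match(mask, c(0L, present), nomatch = 1L) - 1L
    region <- matrix(2L, n, n)
    region[, 1:sample(2:6, 1)] <- 4L
    nuc <- as_nucleus_objects(mask, ps)
    got <- flag_debris_nuclei(nuc, 16)$objects$status
    want <- ifelse(nuc$objects$area_px * ps^2 < 16, "debris", "nucleus")
    expect_identical(got, want)
    mk <- as_marker_objects(mask, ps)
    got_e <- flag_edge_effect(mk, region, 50, ps)$objects$status
    nt <- which(region == 4L)
    nt_rc <- cbind(((nt - 1) %% n) + 1, ((nt - 1) %/% n) + 1)
    want_e <- vapply(mk$objects$object_id, function(id) {
      px <- which(mask == id)
      rc <- cbind(((px - 1) %% n) + 1, ((px - 1) %/% n) + 1)
      dmin <- min(sqrt(outer(rc[, 1], nt_rc[, 1], "-")^2 +
                         outer(rc[, 2], nt_rc[, 2], "-")^2))
      if (dmin * ps <= 50) "edge_effect" else "candidate"
    }, character(1))
    expect_identical(got_e, want_e)
  }
})
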