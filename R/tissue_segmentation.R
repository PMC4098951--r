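#' Default per-pixel feature configuration
#'
#' Features computed per pixel and channel: the raw intensity, Gaussian-
#' smoothed intensities at each `sigma`, and local variance in a square
#' window (a texture cue). Feature order is channels (dapi, marker1,
#' marker2) x statistics (raw, smooth at each sigma, variance) and is stable
#' across calls.
#'
#' @param sigmas Gaussian smoothing scales in pixels (at least one).
#' @param variance_window Odd window edge (px) for the local-variance texture
#'   feature.
#' @return A `pixel_feature_config` list.
#' @export
pixel_feature_config <- function(sigmas = c(2, 4), variance_window = 5L) {
  stopifnot(length(sigmas) >= 1, all(sigmas > 0),
            variance_window >= 3, variance_window %% 2 == 1)
  structure(list(sigmas = sigmas, variance_window = as.integer(variance_window)),
            class = "pixel_feature_config")
}

feature_names <- function(config) {
  chans <- c("dapi", "marker1", "marker2")
  unlist(lapply(chans, function(ch) {
    c(ch,
      paste0(ch, "_s", config$sigmas),
      paste0(ch, "_var"))
  }))
}

#' Extract per-pixel features from a field
#'
#' Builds the fixed-length feature vector used by the tissue-region
#' classifier: per channel, the raw intensity, Gaussian-smoothed intensities
#' at two or more scales, and a local-variance texture statistic.
#'
#' @param field A [multiplex_field()].
#' @param config A [pixel_feature_config()].
#' @return A numeric matrix with one row per pixel (column-major pixel
#'   order) and one named column per feature.
#' @export
#' @examples
#' f <- multiplex_field(matrix(0.5, 128, 128), matrix(0.2, 128, 128),
#'                      matrix(0.1, 128, 128), pixel_size_um = 0.5)
#' dim(extract_pixel_features(f))
extract_pixel_features <- function(field, config = pixel_feature_config()) {
  stopifnot(inherits(field, "multiplex_field"))
  cols <- list()
  for (ch in c("dapi", "marker1", "marker2")) {
    m <- field$channels[[ch]]
    if (any(!is.finite(m))) {
      abort(paste0("Channel '", ch, "' contains non-finite pixel values."),
            class = "budquant_field_error")
    }
    cols[[ch]] <- as.vector(m)
    for (s in config$sigmas) {
      sm <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = s))
      cols[[paste0(ch, "_s", s)]] <- as.vector(sm)
    }
    cols[[paste0(ch, "_var")]] <- as.vector(local_variance(m, config$variance_window))
  }
  out <- do.call(cbind, cols)
  colnames(out) <- feature_names(config)
  out
}

#' Sparse manual region annotations for classifier training
#'
#' A set of annotation strokes, each a pixel set carrying one of the four
#' region labels. [sample_region_annotations()] builds such annotations from
#' a synthetic ground-truth region mask, emulating a pathologist marking up
#' representative areas.
#'
#' @param field_id Field identifier the strokes refer to.
#' @param strokes A list of `list(label =, pixels =)` entries; `pixels` are
#'   linear (column-major) pixel indices, `label` one of [region_levels()].
#' @return A `region_annotation` object.
#' @export
region_annotation <- function(field_id, strokes) {
  for (s in strokes) {
    if (!s$label %in% REGION_LEVELS) {
      abort(paste0("Unknown region label '", s$label, "'."),
            class = "budquant_annotation_error")
    }
  }
  structure(list(field_id = field_id, strokes = strokes),
            class = "region_annotation")
}

#' @rdname region_annotation
#' @param region_mask Integer region mask coded per [region_levels()].
#' @param n_per_class Pixels sampled per present region class.
#' @param seed Integer seed for the pixel sampling.
#' @export
sample_region_annotations <- function(region_mask, field_id = "field_1",
                                      n_per_class = 500L, seed = 1L) {
  with_seed(seed, {
    strokes <- list()
    for (code in seq_along(REGION_LEVELS)) {
      idx <- which(region_mask == code)
      if (!length(idx)) next
      take <- sample(idx, min(n_per_class, length(idx)))
      strokes[[length(strokes) + 1L]] <-
        list(label = REGION_LEVELS[code], pixels = as.integer(take))
    }
    region_annotation(field_id, strokes)
  })
}

#' Train the supervised tissue-region classifier
#'
#' Fits a random-forest pixel classifier mapping per-pixel feature vectors to
#' the four region labels, from sparse annotation strokes on one or more
#' training fields. A stratified held-out split reports pixel accuracy.
#'
#' @param annotations A list of [region_annotation()] objects (or one).
#' @param fields A list of the matching [multiplex_field()] objects, in the
#'   same order.
#' @param config A [pixel_feature_config()].
#' @param seed Integer seed controlling the split and forest.
#' @param holdout_fraction Fraction of annotated pixels held out per class.
#' @param num_trees Trees in the forest.
#' @return A `region_classifier` with elements `model`, `config`, `levels`,
#'   `holdout_accuracy` and `version`.
#' @export
train_region_classifier <- function(annotations, fields,
                                    config = pixel_feature_config(),
                                    seed = 1L, holdout_fraction = 0.2,
                                    num_trees = 100L) {
  if (inherits(annotations, "region_annotation")) annotations <- list(annotations)
  if (inherits(fields, "multiplex_field")) fields <- list(fields)
  stopifnot(length(annotations) == length(fields))

  feats <- list(); labels <- list()
  for (i in seq_along(annotations)) {
    fm <- extract_pixel_features(fields[[i]], config)
    for (s in annotations[[i]]$strokes) {
      feats[[length(feats) + 1L]] <- fm[s$pixels, , drop = FALSE]
      labels[[length(labels) + 1L]] <- rep(s$label, length(s$pixels))
    }
  }
  x <- do.call(rbind, feats)
  y <- unlist(labels)
  missing <- setdiff(REGION_LEVELS, unique(y))
  if (length(missing)) {
    abort(paste0("No training pixels for region label(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "budquant_training_error")
  }
  counts <- table(y)
  if (any(counts < 100)) {
    warn(paste0("Fewer than 100 annotated pixels for: ",
                paste(names(counts)[counts < 100], collapse = ", "),
                "; training may be unstable."))
  }

  with_seed(seed, {
    holdout <- unlist(lapply(split(seq_along(y), y), function(ii) {
      sample(ii, max(1L, round(holdout_fraction * length(ii))))
    }))
    train_i <- setdiff(seq_along(y), holdout)
    df <- as.data.frame(x)
    df$.label <- factor(y, levels = REGION_LEVELS)
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = df[train_i, ],
      num.trees = num_trees, seed = seed, num.threads = 1L,
      verbose = FALSE
    )
    pred <- predict(fit, data = df[holdout, , drop = FALSE],
                    num.threads = 1L, verbose = FALSE)$predictions
    acc <- mean(pred == df$.label[holdout])
    if (acc < 0.5 + 1 / length(REGION_LEVELS)) {
      warn(sprintf("Held-out pixel accuracy is only %.2f; some labels may be inseparable.", acc))
    }
    structure(
      list(model = fit, config = config, levels = REGION_LEVELS,
           holdout_accuracy = acc, version = "budquant-rf-1"),
      class = "region_classifier"
    )
  })
}

#' @export
print.region_classifier <- function(x, ...) {
  cat("<region_classifier> ", x$version, "; held-out pixel accuracy ",
      sprintf("%.3f", x$holdout_accuracy), "\n", sep = "")
  invisible(x)
}

#' Segment a field into the four tissue regions
#'
#' Applies a trained [region_classifier] per pixel, then removes connected
#' label regions smaller than `min_region_area_um2`, absorbing each into the
#' label of the largest adjacent region (ties broken by the fixed label
#' priority Stroma > Tumour > NecrosisLumen > NoTissue). Every pixel
#' receives exactly one label.
#'
#' @param field A [multiplex_field()].
#' @param classifier A [train_region_classifier()] result.
#' @param min_region_area_um2 Minimum connected-region area retained; 0
#'   disables clean-up.
#' @return An integer region matrix coded per [region_levels()], with
#'   attributes `provenance` (classifier version) and `pixel_size_um`.
#' @export
segment_tissue <- function(field, classifier, min_region_area_um2 = 100) {
  stopifnot(inherits(field, "multiplex_field"),
            inherits(classifier, "region_classifier"))
  fm <- extract_pixel_features(field, classifier$config)
  pred <- predict(classifier$model, data = as.data.frame(fm),
                  num.threads = 1L, verbose = FALSE)$predictions
  dims <- dim(field$channels$dapi)
  lab <- matrix(match(as.character(pred), REGION_LEVELS), dims[1], dims[2])
  lab <- cleanup_region_map(lab, min_region_area_um2, field$pixel_size_um)
  attr(lab, "provenance") <- classifier$version
  attr(lab, "pixel_size_um") <- field$pixel_size_um
  lab
}

# Absorb connected label regions smaller than the minimum area into the
# label of the largest adjacent region.  Small regions are processed
# smallest-first within a pass; passes repeat until no under-sized region
# remains (absorption can merge regions across passes).
cleanup_region_map <- function(lab, min_region_area_um2, pixel_size_um) {
  if (min_region_area_um2 <= 0) return(lab)
  min_px <- min_region_area_um2 / pixel_size_um^2
  priority <- c(2L, 1L, 3L, 4L)  # Stroma > Tumour > NecrosisLumen > NoTissue
  H <- nrow(lab); W <- ncol(lab)
  n8 <- expand.grid(dr = -1:1, dc = -1:1)
  n8 <- n8[!(n8$dr == 0 & n8$dc == 0), ]
  for (pass in seq_len(20L)) {
    comp <- label_components_multiclass(lab)
    ncomp <- max(comp)
    sizes <- tabulate(comp, nbins = ncomp)
    if (!any(sizes > 0 & sizes < min_px)) break
    idx_all <- which(comp > 0L)
    comp_label <- integer(ncomp)
    comp_label[comp[idx_all]] <- lab[idx_all]
    px_by_comp <- split(idx_all, comp[idx_all])
    small <- which(sizes > 0 & sizes < min_px)
    for (cid in small[order(sizes[small])]) {
      if (sizes[cid] >= min_px) next  # grew by earlier absorption
      px <- px_by_comp[[as.character(cid)]]
      rows <- ((px - 1L) %% H) + 1L
      cols <- ((px - 1L) %/% H) + 1L
      nr <- outer(rows, n8$dr, `+`); nc <- outer(cols, n8$dc, `+`)
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      nidx <- (nc[ok] - 1L) * H + nr[ok]
      neigh <- unique(comp[nidx])
      neigh <- neigh[neigh > 0 & neigh != cid]
      if (!length(neigh)) next
      best <- neigh[sizes[neigh] == max(sizes[neigh])]
      if (length(best) > 1) {
        best <- best[order(match(comp_label[best], priority))]
      }
      target <- best[1]
      lab[px] <- comp_label[target]
      comp[px] <- target
      sizes[target] <- sizes[target] + sizes[cid]
      px_by_comp[[as.character(target)]] <-
        c(px_by_comp[[as.character(target)]], px)
      sizes[cid] <- 0L
    }
  }
  lab
}

# Connected components of a label map where components never span different
# labels.
label_components_multiclass <- function(lab) {
  comp <- matrix(0L, nrow(lab), ncol(lab))
  offset <- 0L
  for (code in sort(unique(as.vector(lab)))) {
    cc <- label_components(lab == code)
    comp[cc > 0L] <- cc[cc > 0L] + offset
    offset <- offset + max(cc)
  }
  comp
}

# Number of connected label regions in a region map (used by tests).
count_label_regions <- function(lab) {
  max(label_components_multiclass(lab))
}
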