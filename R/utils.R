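# Internal raster helpers.  All rasters are plain numeric/integer matrices
# (rows = image rows); EBImage results are coerced back with as.matrix().

# Pixel offsets of a rasterised disk of radius r (centre included when r >= 0).
disk_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Pixel offsets of an annulus with outer radius r_out and inner radius r_in
# (wall pixels only: r_in < d <= r_out).
annulus_offsets <- function(r_out, r_in) {
  s <- -r_out:r_out
  g <- expand.grid(dr = s, dc = s)
  d2 <- g$dr^2 + g$dc^2
  g[d2 <= r_out^2 & d2 > r_in^2, , drop = FALSE]
}

# Offsets of an axis-rotated ellipse (used for autofluorescence streaks).
ellipse_offsets <- function(a, b, theta) {
  r <- ceiling(max(a, b))
  s <- -r:r
  g <- expand.grid(dr = s, dc = s)
  ct <- cos(theta); st <- sin(theta)
  u <- g$dc * ct + g$dr * st
  v <- -g$dc * st + g$dr * ct
  g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

# Clamp offsets+centre to image bounds; returns matrix of (row, col).
offsets_at <- function(offsets, row, col, nrow, ncol, clip = FALSE) {
  r <- offsets$dr + row
  c <- offsets$dc + col
  if (clip) {
    keep <- r >= 1 & r <= nrow & c >= 1 & c <= ncol
    r <- r[keep]; c <- c[keep]
  }
  cbind(r, c)
}

in_bounds <- function(px, nrow, ncol) {
  all(px[, 1] >= 1 & px[, 1] <= nrow & px[, 2] >= 1 & px[, 2] <= ncol)
}

px_index <- function(px, nrow) (px[, 2] - 1L) * nrow + px[, 1]

# Binary dilation by a disk of radius r, returning a logical matrix.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask > 0)
  kern <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  as.matrix(EBImage::dilate(EBImage::Image(mask > 0), kern)) > 0
}

# 8-connected labelling of a binary mask -> integer matrix of labels.
label_components <- function(mask) {
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask > 0)))
  storage.mode(lab) <- "integer"
  lab
}

# Euclidean distance (in pixels) from each pixel to the nearest pixel where
# `target` is TRUE.  Returns Inf everywhere when target is empty.
distance_to <- function(target) {
  if (!any(target)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  # distmap measures distance to the nearest zero pixel
  as.matrix(EBImage::distmap(EBImage::Image(!target)))
}

# Local (windowed) variance of a raster via box filtering.
local_variance <- function(m, window = 5L) {
  k <- matrix(1 / (window * window), window, window)
  img <- EBImage::Image(m)
  mu <- as.matrix(EBImage::filter2(img, k))
  mu2 <- as.matrix(EBImage::filter2(img * img, k))
  pmax(mu2 - mu * mu, 0)
}

# Per-object summary table from a label matrix.
label_table <- function(lab, pixel_size_um) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    return(tibble::tibble(
      object_id = integer(), area_px = integer(), area_um2 = double(),
      centroid_row = double(), centroid_col = double()
    ))
  }
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(labs, nbins = max(ids))[ids]
  tibble::tibble(
    object_id = as.integer(ids),
    area_px = as.integer(area),
    area_um2 = area * pixel_size_um^2,
    centroid_row = as.vector(tapply(rows, labs, mean)[as.character(ids)]),
    centroid_col = as.vector(tapply(cols, labs, mean)[as.character(ids)])
  )
}

# Relabel a label matrix so labels are 1..k in increasing old-label order.
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# Minimum of `values` per label of `lab` over pixels where lab > 0.
min_by_label <- function(lab, values) {
  idx <- which(lab > 0L)
  tapply(values[idx], lab[idx], min)
}

# Bimodal-histogram (Otsu) threshold of a numeric vector, with a robust
# background floor.  Plain Otsu mis-thresholds channels whose positive
# class is a tiny fraction of the pixels (sparse lymphatic vessels over a
# noise background): the between-class variance then peaks inside the
# dominant background mode.  Candidates are therefore restricted to lie
# above median + 3 * MAD-sigma of the pixel distribution -- outside the
# background mode -- before the Otsu criterion picks among them.
# Implemented on a vector (rather than an image) so it can be restricted to
# tissue pixels.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) {
    abort("Channel is constant; automatic thresholding impossible. Supply a manual threshold.",
          class = "budquant_constant_channel")
  }
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w0c <- w0[-n_bins]; muc <- mu[-n_bins]
  valid <- w0c > 0 & w0c < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0c[valid] - muc[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  floor_t <- median(x) + 3 * 1.4826 * stats::mad(x, constant = 1)
  above <- mids[-n_bins] >= floor_t
  if (any(above & valid)) bcv[!above] <- -Inf
  k <- which.max(bcv)
  rng[1] + k / n_bins * diff(rng)
}

# Deterministic child seeds derived from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
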