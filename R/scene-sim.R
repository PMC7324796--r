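#' Specify a synthetic wheat spike
#'
#' A spike is rendered as an oriented capsule (a segment swept by a disc)
#' filled with a periodic speckle texture, optionally with thin radiating
#' awns at the tip. The texture modulates all three colour channels by the
#' same grey offset, so the excess-green index of the spike body is exactly
#' that of `color_mean` -- the texture is visible to the wavelet/Laws stage
#' but invisible to the colour-index stage, mirroring the "same colour,
#' different texture" premise of spike detection.
#'
#' @param center Numeric `(x, y)` pixel position of the capsule centre
#'   (x = column, y = row).
#' @param length,width Capsule dimensions in pixels; `length > width > 0`.
#' @param angle Degrees clockwise from the vertical (0 = upright).
#' @param awned Render thin awn hairs at the tip?
#' @param texture_period Speckle period in full-scale pixels (>= 2; the
#'   default 6 survives the 2x wavelet downscaling and drives both the
#'   edge- and spot-type Laws masks on the approximation image).
#' @param texture_amp Grey-offset amplitude of the speckle in intensity
#'   units.
#' @param color_mean RGB triple in `[0, 1]`; must be green-dominant if the
#'   spike is to pass colour-index segmentation.
#' @return A `spike_spec` list.
#' @export
spike_spec <- function(center = c(96, 85), length = 70, width = 16,
                       angle = 10, awned = FALSE, texture_period = 6,
                       texture_amp = 0.22,
                       color_mean = c(0.24, 0.36, 0.26)) {
  if (!(length > width && width > 0)) abort("need length > width > 0")
  if (texture_period < 2) abort("texture_period must be >= 2 px")
  if (any(color_mean < 0 | color_mean > 1)) abort("colors must be in [0,1]")
  structure(list(center = center, length = length, width = width,
                 angle = angle, awned = awned,
                 texture_period = texture_period, texture_amp = texture_amp,
                 color_mean = color_mean),
            class = "spike_spec")
}

#' Specify a synthetic plant scene
#'
#' Describes one side-view image of a potted plant: curved ribbon-like
#' leaves emanating from the pot area (with a guaranteed minimum number of
#' pairwise leaf crossings), zero or more textured spikes, a desaturated
#' blue-grey chamber background, and additive Gaussian pixel noise.
#' Leaf-crossing regions are rendered brighter than single leaves, giving
#' them both the high texture energy and the bright-ridge signature that
#' make them the principal false-positive source for spike detection.
#'
#' @param width,height Frame size in pixels (>= 64).
#' @param n_leaves Number of leaf ribbons (>= 0).
#' @param leaf_width_range Min/max leaf ribbon width in pixels.
#' @param n_crossings_min Minimum number of distinct leaf-crossing regions
#'   required when `n_leaves >= 2` (leaf layout is re-drawn until met).
#' @param spikes List of [spike_spec()] objects (possibly empty).
#' @param background_color,leaf_color_mean RGB triples in `[0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param rng_seed Integer seed; the whole scene is a pure function of the
#'   spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 192, height = 192, n_leaves = 6,
                       leaf_width_range = c(6, 10), n_crossings_min = 2,
                       spikes = list(spike_spec(center = c(width * 0.5,
                                                           height * 0.44))),
                       background_color = c(0.30, 0.25, 0.40),
                       leaf_color_mean = c(0.15, 0.55, 0.15),
                       noise_sd = 0.01, rng_seed = 1L) {
  if (width < 64 || height < 64) abort("scene must be at least 64x64")
  if (n_leaves < 0) abort("n_leaves must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  cols <- c(background_color, leaf_color_mean)
  if (any(cols < 0 | cols > 1)) abort("colors must be in [0,1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_leaves = as.integer(n_leaves),
                 leaf_width_range = leaf_width_range,
                 n_crossings_min = as.integer(n_crossings_min),
                 spikes = spikes, background_color = background_color,
                 leaf_color_mean = leaf_color_mean, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Half-width of the anti-aliased soft edge, in pixels. Ground-truth masks
# threshold coverage at 0.5, i.e. at the nominal shape boundary.
AA_BAND <- 0.4

# Soft coverage in [0,1] from a distance field and a nominal half-width.
edge_cover <- function(dist, halfwidth) {
  clamp01((halfwidth + AA_BAND / 2 - dist) / AA_BAND)
}

# Quadratic Bezier polyline through P0, P1 (control), P2.
bezier_points <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(x, y)
}

# Distance of every pixel to a point set (x = col, y = row), via the
# Euclidean distance transform of the stamped point raster.
distance_to_points <- function(pts, h, w) {
  stamp <- matrix(1, h, w)
  r <- pmin(pmax(round(pts[, 2]), 1), h)
  c <- pmin(pmax(round(pts[, 1]), 1), w)
  stamp[cbind(r, c)] <- 0
  if (all(stamp == 1)) return(matrix(Inf, h, w))
  EBImage::distmap(stamp)
}

# Render one leaf ribbon; returns list(cover = [0,1] matrix, mask = logical).
render_leaf <- function(h, w, halfwidth) {
  x0 <- runif(1, 0.3 * w, 0.7 * w)
  y0 <- runif(1, 0.88 * h, 0.98 * h)
  theta <- runif(1, -65, 65) * pi / 180
  len <- runif(1, 0.55, 0.95) * h
  d <- c(sin(theta), -cos(theta))              # unit direction, upward
  perp <- c(-d[2], d[1])
  curv <- runif(1, -0.35, 0.35)
  p2 <- c(x0, y0) + len * d + curv * len * perp
  p1 <- c(x0, y0) + 0.5 * len * d + runif(1, -0.25, 0.25) * len * perp
  pts <- bezier_points(c(x0, y0), p1, p2, n = max(32L, ceiling(4 * len)))
  dist <- distance_to_points(pts, h, w)
  list(cover = edge_cover(dist, halfwidth), mask = dist <= halfwidth)
}

# Render one spike capsule; returns cover, mask and the per-pixel texture
# pattern in [-1, 1]. Coordinates: x = column, y = row.
render_spike <- function(sp, h, w) {
  cx <- sp$center[1]; cy <- sp$center[2]
  a <- sp$angle * pi / 180
  d <- c(sin(a), -cos(a)); perp <- c(-d[2], d[1])
  half_axis <- sp$length / 2 - sp$width / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  relx <- xs - cx; rely <- ys - cy
  u <- relx * d[1] + rely * d[2]
  v <- relx * perp[1] + rely * perp[2]
  du <- pmax(abs(u) - half_axis, 0)
  dist <- sqrt(du^2 + v^2)
  p <- sp$texture_period
  pattern <- sin(2 * pi * u / p) * sin(2 * pi * v / p)
  mask <- dist <= sp$width / 2
  awn_mask <- NULL
  if (isTRUE(sp$awned)) {
    tip <- c(cx, cy) + (half_axis + sp$width / 2) * d
    awn_pts <- do.call(rbind, lapply(seq_len(9), function(j) {
      off <- runif(1, -35, 35) * pi / 180
      da <- c(sin(a + off), -cos(a + off))
      t <- seq(0, runif(1, 0.8, 1.4) * sp$width, by = 0.5)
      cbind(tip[1] + t * da[1], tip[2] + t * da[2])
    }))
    adist <- distance_to_points(awn_pts, h, w)
    awn_mask <- adist <= 0.6
  }
  list(cover = edge_cover(dist, sp$width / 2), mask = mask,
       pattern = pattern, awn_mask = awn_mask)
}

#' Generate a synthetic plant scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: curved leaves (re-drawn
#' deterministically until at least `n_crossings_min` distinct crossing
#' regions exist, when `n_leaves >= 2`), brightened crossing regions,
#' textured spike capsules on top, then additive Gaussian noise. Ground
#' truth masks are the 0.5-coverage rasterisations; spike pixels are removed
#' from the leaf and crossing masks so the three classes are disjoint.
#' Bit-identical output for identical specs.
#'
#' @param spec A [scene_spec()].
#' @return Object of class `synthetic_scene`: list with `image`
#'   (H x W x 3 array), `spike_mask`, `leaf_mask`, `crossing_mask`
#'   (full-scale [binary_mask]s) and `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) abort("expected a scene_spec")
  h <- spec$height; w <- spec$width
  with_seed(spec$rng_seed, {
    # --- leaves, retried until the crossing quota is met ---------------------
    leaves <- list(); crossing <- matrix(FALSE, h, w)
    if (spec$n_leaves > 0) {
      for (attempt in seq_len(40L)) {
        widths <- runif(spec$n_leaves, spec$leaf_width_range[1],
                        spec$leaf_width_range[2])
        leaves <- lapply(widths / 2, function(hw) render_leaf(h, w, hw))
        masks <- lapply(leaves, `[[`, "mask")
        crossing <- matrix(FALSE, h, w)
        if (spec$n_leaves >= 2) {
          for (i in seq_len(spec$n_leaves - 1))
            for (j in (i + 1):spec$n_leaves)
              crossing <- crossing | (masks[[i]] & masks[[j]])
        }
        n_cross <- max(label_components(crossing))
        if (spec$n_leaves < 2 || n_cross >= spec$n_crossings_min) break
        if (attempt == 40L)
          abort("could not place leaves with the requested crossing count")
      }
    }
    # --- composite colours ---------------------------------------------------
    img <- array(rep(spec$background_color, each = h * w), c(h, w, 3))
    leaf_mask <- matrix(FALSE, h, w)
    for (lf in leaves) {
      jitter <- runif(1, -0.12, 0.12)
      col <- clamp01(spec$leaf_color_mean * (1 + jitter))
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - lf$cover) + col[ch] * lf$cover
      leaf_mask <- leaf_mask | lf$mask
    }
    if (any(crossing))                     # crossings reflect more light
      for (ch in 1:3)
        img[, , ch] <- clamp01(img[, , ch] + 0.18 * crossing)
    # --- spikes --------------------------------------------------------------
    spike_mask <- matrix(FALSE, h, w)
    for (k in seq_along(spec$spikes)) {
      sp <- spec$spikes[[k]]
      rs <- render_spike(sp, h, w)
      if (!any(rs$mask))
        abort(sprintf("spike %d lies fully outside the %dx%d frame", k, w, h))
      for (ch in 1:3) {
        scol <- clamp01(sp$color_mean[ch] + sp$texture_amp * rs$pattern)
        img[, , ch] <- img[, , ch] * (1 - rs$cover) + scol * rs$cover
      }
      spike_mask <- spike_mask | rs$mask
      if (!is.null(rs$awn_mask)) {
        acol <- clamp01(sp$color_mean * 0.9)
        for (ch in 1:3)
          img[, , ch] <- ifelse(rs$awn_mask, acol[ch], img[, , ch])
        spike_mask <- spike_mask | rs$awn_mask
      }
    }
    if (spec$noise_sd > 0)
      img <- clamp01(img + array(rnorm(h * w * 3, 0, spec$noise_sd),
                                 c(h, w, 3)))
    structure(list(
      image = img,
      spike_mask = binary_mask(spike_mask, "full"),
      leaf_mask = binary_mask(leaf_mask & !spike_mask, "full"),
      crossing_mask = binary_mask(crossing & !spike_mask, "full"),
      spec = spec
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %dx%d: %d spike px, %d leaf px, %d crossing px>\n",
              nrow(x$spike_mask), ncol(x$spike_mask),
              sum(x$spike_mask), sum(x$leaf_mask), sum(x$crossing_mask)))
  invisible(x)
}

# Analytic area of a capsule spike (used to size day-by-day growth).
capsule_area <- function(length, width) {
  width * (length - width) + pi * (width / 2)^2
}

# Capsule dimensions realising a target area at a roughly 3:1 aspect ratio
# (a capsule with length = 3w has area (2 + pi/4) w^2).
capsule_for_area <- function(area, width0 = NULL) {
  w <- max(4, sqrt(area / (2 + pi / 4)))
  list(width = w, length = w + (area - pi * w^2 / 4) / w)
}

#' Specify a synthetic imaging time series
#'
#' Emulates the daily imaging of one plant at several side-view orientations:
#' the leaf canopy of each orientation is fixed across days, the spike
#' emerges on `emergence_day` and its ground-truth area grows by
#' `growth_per_day` pixels per day, and each orientation-day is occluded
#' (spike entirely hidden) independently with probability `occlusion_prob`.
#'
#' @param n_days Number of imaging days (>= 1).
#' @param orientations Side-view angles in degrees.
#' @param emergence_day First day (1-based) the spike exists;
#'   `1 <= emergence_day <= n_days`.
#' @param growth_per_day Ground-truth spike area increment per day, pixels.
#' @param occlusion_prob Per orientation-day probability that leaves hide
#'   the spike completely.
#' @param rng_seed Integer seed.
#' @return A `series_spec` list.
#' @export
series_spec <- function(n_days = 8L, orientations = c(0, 45, 90),
                        emergence_day = 3L, growth_per_day = 600,
                        occlusion_prob = 0, rng_seed = 1L) {
  if (n_days < 1) abort("n_days must be >= 1")
  if (emergence_day < 1 || emergence_day > n_days)
    abort("emergence_day must lie in 1..n_days")
  if (growth_per_day < 0) abort("growth_per_day must be >= 0")
  if (occlusion_prob < 0 || occlusion_prob > 1)
    abort("occlusion_prob must be a probability")
  structure(list(n_days = as.integer(n_days), orientations = orientations,
                 emergence_day = as.integer(emergence_day),
                 growth_per_day = growth_per_day,
                 occlusion_prob = occlusion_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "series_spec")
}

#' Generate a plant's imaging time series
#'
#' For every day and orientation, renders a [generate_scene()] scene whose
#' leaf layout is fixed per orientation while the spike grows so its
#' analytic capsule area equals `(day - emergence_day + 1) * growth_per_day`
#' (absent before emergence and on occluded orientation-days). Fully
#' deterministic given the two specs.
#'
#' @param scene_spec A [scene_spec()] template (its first spike is the
#'   growth template; its `rng_seed` is ignored in favour of derived seeds).
#' @param series_spec A [series_spec()].
#' @param plant_id Identifier stored in the output rows.
#' @return Tibble of class `plant_series` with columns `plant_id`, `day`,
#'   `angle`, `scene` (list of `synthetic_scene`), `gt_area` (ground-truth
#'   spike pixels) and `occluded`.
#' @export
generate_series <- function(scene_spec, series_spec, plant_id = "plant01") {
  if (!inherits(scene_spec, "scene_spec")) abort("expected a scene_spec")
  if (!inherits(series_spec, "series_spec")) abort("expected a series_spec")
  template <- if (length(scene_spec$spikes)) scene_spec$spikes[[1]]
              else spike_spec(center = c(scene_spec$width / 2,
                                         scene_spec$height / 4))
  rows <- list()
  for (ai in seq_along(series_spec$orientations)) {
    angle <- series_spec$orientations[ai]
    leaf_seed <- derive_seed(series_spec$rng_seed, ai)
    for (d in seq_len(series_spec$n_days)) {
      occluded <- with_seed(derive_seed(series_spec$rng_seed, ai, d, 7L),
                            runif(1)) < series_spec$occlusion_prob
      grown <- d >= series_spec$emergence_day
      spikes <- list()
      if (grown && !occluded && series_spec$growth_per_day > 0) {
        a <- (d - series_spec$emergence_day + 1) * series_spec$growth_per_day
        dims <- capsule_for_area(a)
        sp <- template
        sp$width <- dims$width; sp$length <- dims$length
        # grow upward from the fixed bottom tip of the template capsule
        ar <- template$angle * pi / 180
        up <- c(sin(ar), -cos(ar))
        base <- template$center - (template$length / 2) * up
        sp$center <- base + (dims$length / 2) * up
        spikes <- list(sp)
      }
      day_spec <- scene_spec
      day_spec$spikes <- spikes
      day_spec$rng_seed <- leaf_seed     # same canopy every day
      sc <- generate_scene(day_spec)
      rows[[length(rows) + 1L]] <- tibble(
        plant_id = plant_id, day = d, angle = angle,
        scene = list(sc), gt_area = sum(sc$spike_mask),
        occluded = occluded)
    }
  }
  out <- dplyr::bind_rows(rows) %>% arrange(.data$day, .data$angle)
  class(out) <- c("plant_series", class(out))
  out
}

# Majority (>= min_count of 4) 2x2 block pooling of a full-scale mask.
downscale_pool <- function(mask, min_count = 1L) {
  m <- as_logical_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  if (h %% 2 == 1) m <- rbind(m, FALSE)
  if (w %% 2 == 1) m <- cbind(m, FALSE)
  ro <- seq(1, nrow(m), by = 2); co <- seq(1, ncol(m), by = 2)
  cnt <- m[ro, co] + m[ro + 1, co] + m[ro, co + 1] + m[ro + 1, co + 1]
  binary_mask(cnt >= min_count, "half")
}

#' Sample labelled training pixels from a scene
#'
#' Draws pixel coordinates on the half-resolution wavelet grid (where
#' classification happens): spike pixels from 2x2 blocks that are at least
#' 3/4 spike, non-spike pixels from leaf-or-crossing blocks containing no
#' spike pixel. If a class pool is smaller than requested, sampling falls
#' back to replacement with a warning. The defaults mirror a roughly 1:3.35
#' spike to non-spike class ratio.
#'
#' @param scene A `synthetic_scene`.
#' @param n_spike,n_nonspike Number of pixels per class.
#' @param rng_seed Integer seed.
#' @return Tibble with columns `row`, `col` (half-scale) and `label`
#'   (`"spike"`/`"nonspike"`).
#' @export
sample_labeled_pixels <- function(scene, n_spike = 200, n_nonspike = 670,
                                  rng_seed = 1L) {
  spike_half <- downscale_pool(scene$spike_mask, 3L)
  spike_any <- downscale_pool(scene$spike_mask, 1L)
  non_half <- downscale_pool(scene$leaf_mask | scene$crossing_mask, 3L)
  non_half <- binary_mask(as_logical_matrix(non_half) &
                            !as_logical_matrix(spike_any), "half")
  if (n_spike > 0 && !any(spike_half))
    abort("scene has no spike pixels to sample")
  draw <- function(mask, n, label) {
    idx <- which(as_logical_matrix(mask))
    if (n == 0) return(tibble(row = integer(), col = integer(),
                              label = character()))
    replace <- n > length(idx)
    if (replace) warn(sprintf("only %d %s pixels available; sampling %d with replacement",
                              length(idx), label, n))
    pick <- sample(idx, n, replace = replace)
    rc <- arrayInd(pick, dim(mask))
    tibble(row = rc[, 1], col = rc[, 2], label = label)
  }
  with_seed(rng_seed, {
    dplyr::bind_rows(draw(spike_half, n_spike, "spike"),
                     draw(non_half, n_nonspike, "nonspike"))
  })
}

#' Build a labelled pixel-feature table from scenes
#'
#' Runs each scene through the preprocessing chain (grayscale, Haar
#' approximation image, Laws features) and attaches the eight feature values
#' to pixels sampled by [sample_labeled_pixels()]. This synthesises the
#' classifier's training corpus.
#'
#' @param scenes List of `synthetic_scene` objects (or a single scene).
#' @param n_spike,n_nonspike Pixels per class per scene.
#' @param seed Integer seed.
#' @param window Laws normalisation window.
#' @return Tibble with columns `image_id`, `row`, `col`, `f1` ... `f8`,
#'   `label`.
#' @export
make_training_table <- function(scenes, n_spike = 200, n_nonspike = 670,
                                seed = 1L, window = 25L) {
  if (inherits(scenes, "synthetic_scene")) scenes <- list(scenes)
  masks <- laws_masks()
  purrr::imap_dfr(scenes, function(sc, i) {
    gray <- to_grayscale(sc$image)
    A <- dwt_haar(gray)$A
    stack <- laws_features(A, masks, window = window)
    px <- sample_labeled_pixels(sc, n_spike, n_nonspike,
                                rng_seed = derive_seed(seed, i))
    n <- dim(stack)[1] * dim(stack)[2]
    flat <- matrix(stack, nrow = n)
    idx <- (px$col - 1L) * dim(stack)[1] + px$row
    feats <- flat[idx, , drop = FALSE]
    colnames(feats) <- paste0("f", seq_len(ncol(feats)))
    dplyr::bind_cols(tibble(image_id = i, row = px$row, col = px$col),
                     as_tibble(feats), tibble(label = px$label))
  })
}

#' Write a plant series to disk with a manifest
#'
#' Writes `plantID_dayDDD_angleAAA.png` images plus `_gt-spike.png` ground
#' truth masks and a `manifest.csv` with columns `plant_id, day, angle,
#' image_path, gt_mask_path, gt_area`.
#'
#' @param series A `plant_series` from [generate_series()] (or several
#'   row-bound together).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly (also written as CSV).
#' @export
write_scene_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- purrr::pmap_dfr(
    list(series$plant_id, series$day, series$angle, series$scene,
         series$gt_area),
    function(pid, day, angle, sc, area) {
      stem <- sprintf("%s_day%03d_angle%03d", pid, day, angle)
      ipath <- file.path(dir, paste0(stem, ".png"))
      gpath <- file.path(dir, paste0(stem, "_gt-spike.png"))
      write_image(sc$image, ipath)
      write_image(sc$spike_mask, gpath)
      tibble(plant_id = pid, day = day, angle = angle,
             image_path = ipath, gt_mask_path = gpath, gt_area = area)
    })
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Simulate a multi-plant imaging experiment on disk
#'
#' Generates `n_plants` independent plants (distinct canopies and emergence
#' days cycling over `emergence_days`), writes every orientation-day image
#' and ground-truth mask via [write_scene_series()], and returns a manifest
#' with the true heading day in `gt_htp` -- ready for [run_experiment()].
#'
#' @param dir Output directory.
#' @param n_plants Number of plants.
#' @param n_days Imaging days per plant.
#' @param emergence_days Integer vector recycled over plants.
#' @param growth_per_day Ground-truth area increment, pixels/day.
#' @param occlusion_prob Per orientation-day occlusion probability.
#' @param seed Integer master seed.
#' @param scene Template [scene_spec()] (per-plant seeds are derived).
#' @return Manifest tibble with columns `plant_id, day, angle, image_path,
#'   gt_mask_path, gt_area, gt_htp`.
#' @export
simulate_experiment <- function(dir, n_plants = 10L, n_days = 8L,
                                emergence_days = 2:5, growth_per_day = 600,
                                occlusion_prob = 0, seed = 1L,
                                scene = scene_spec()) {
  mans <- lapply(seq_len(n_plants), function(p) {
    em <- emergence_days[(p - 1L) %% length(emergence_days) + 1L]
    sc <- scene
    sc$rng_seed <- derive_seed(seed, p, 1L)
    ser <- generate_series(
      sc,
      series_spec(n_days = n_days, emergence_day = em,
                  growth_per_day = growth_per_day,
                  occlusion_prob = occlusion_prob,
                  rng_seed = derive_seed(seed, p, 2L)),
      plant_id = sprintf("plant%03d", p))
    man <- write_scene_series(ser, file.path(dir, sprintf("plant%03d", p)))
    man$gt_htp <- em
    man
  })
  man <- dplyr::bind_rows(mans)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  man
}
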