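#' Pipeline configuration
#'
#' Collects the tunable parameters of the detection chain with their
#' defaults. All values are full-scale pixels unless noted.
#'
#' @param window Laws normalisation window, in A-image pixels (odd).
#' @param sigmas Frangi scale set.
#' @param beta,c,gamma Frangi sensitivity constants and Hessian
#'   normalisation exponent (`c = NULL` = data-driven per scale).
#' @param tau_rel Relative vessel-mask threshold.
#' @param overlap_frac Fraction of a candidate component inside the vessel
#'   mask above which the component is deleted.
#' @param open_radius Disc radius of the final morphological opening.
#' @param max_geodesic_iter Cap on geodesic dilation iterations during spike
#'   reconstruction (the main guard against flooding into touching leaves;
#'   each iteration grows the seeds by one pixel within the plant mask).
#' @return A `spike_config` list.
#' @export
spike_config <- function(window = 25L, sigmas = c(1, 3, 5, 7, 9), beta = 0.5,
                         c = NULL, gamma = 1, tau_rel = 0.25,
                         overlap_frac = 0.5, open_radius = 2L,
                         max_geodesic_iter = 5L) {
  structure(list(window = as.integer(window), sigmas = sigmas, beta = beta,
                 c = c, gamma = gamma, tau_rel = tau_rel,
                 overlap_frac = overlap_frac,
                 open_radius = as.integer(open_radius),
                 max_geodesic_iter = as.integer(max_geodesic_iter)),
            class = "spike_config")
}

# Per-component region summary of a label matrix.
region_table <- function(labels) {
  n <- max(labels)
  if (n == 0)
    return(tibble(label = integer(), pixel_count = integer(),
                  min_row = integer(), min_col = integer(),
                  max_row = integer(), max_col = integer(),
                  centroid_row = numeric(), centroid_col = numeric()))
  idx <- which(labels > 0)
  rc <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  tibble(label = lab, r = rc[, 1], c = rc[, 2]) %>%
    group_by(.data$label) %>%
    summarise(pixel_count = dplyr::n(),
              min_row = min(.data$r), min_col = min(.data$c),
              max_row = max(.data$r), max_col = max(.data$c),
              centroid_row = mean(.data$r), centroid_col = mean(.data$c),
              .groups = "drop") %>%
    arrange(.data$label)
}

#' Suppress leaf-crossing artefacts in a candidate spike mask
#'
#' Deletes every 8-connected component of the candidate mask whose fraction
#' of pixels inside the vessel mask strictly exceeds `overlap_frac`; all
#' other components are kept intact. The output is always a subset of the
#' input.
#'
#' @param nn_full Full-scale candidate [binary_mask] (upscaled classifier
#'   output).
#' @param vessels Full-scale vessel [binary_mask].
#' @param overlap_frac Deletion threshold in `[0, 1]`.
#' @return Full-scale [binary_mask].
#' @export
suppress_crossings <- function(nn_full, vessels, overlap_frac = 0.5) {
  if (!all(dim(nn_full) == dim(vessels)))
    stop_shape(nn_full, vessels, "candidate and vessel masks")
  labels <- label_components(nn_full)
  n <- max(labels)
  if (n == 0) return(binary_mask(as_logical_matrix(nn_full), "full"))
  size <- tabulate(labels[labels > 0], nbins = n)
  inside <- tabulate(labels[labels > 0 & as_logical_matrix(vessels)],
                     nbins = n)
  drop <- which(inside / size > overlap_frac)
  keep <- as_logical_matrix(nn_full)
  keep[labels %in% drop] <- FALSE
  binary_mask(keep, "full")
}

#' Reconstruct whole spike regions inside the plant mask
#'
#' Seeds the reconstruction with `cleaned AND cis`, applies an opening
#' (erosion followed by dilation) with a disc of radius `open_radius` to
#' erase residual speckle seeds, grows the surviving seeds by geodesic
#' dilation constrained to the plant (CIS) mask for at most
#' `max_geodesic_iter` iterations (a bounded morphological reconstruction:
#' unbounded growth would flood through any leaf touching a spike), opens
#' again to trim thin tongues grown along leaves, and labels the surviving
#' 8-connected components as spike regions.
#'
#' @param cleaned Full-scale candidate [binary_mask] after suppression.
#' @param cis Full-scale plant [binary_mask].
#' @param open_radius Disc radius of the opening.
#' @param max_geodesic_iter Iteration cap of the geodesic dilation.
#' @return Object of class `spike_detection`: list with `final_mask`,
#'   `regions` (tibble of label, pixel_count, bbox, centroid),
#'   `total_spike_area` and an `intermediate` list.
#' @export
reconstruct_spikes <- function(cleaned, cis, open_radius = 2L,
                               max_geodesic_iter = 5L) {
  if (!all(dim(cleaned) == dim(cis)))
    stop_shape(cleaned, cis, "candidate and plant masks")
  plant <- as_logical_matrix(cis)
  open_mask <- function(m) {
    if (open_radius < 1 || !any(m)) return(m)
    EBImage::opening(m * 1, disc_brush(open_radius)) > 0.5
  }
  cur <- open_mask(as_logical_matrix(cleaned) & plant)
  if (any(cur)) {
    b3 <- EBImage::makeBrush(3, "box")
    for (i in seq_len(max_geodesic_iter)) {
      nxt <- mask_dilate(cur, b3) & plant
      if (identical(nxt, cur)) break
      cur <- nxt
    }
    cur <- open_mask(cur)
  }
  labels <- label_components(cur)
  regions <- region_table(labels)
  structure(list(
    final_mask = binary_mask(cur, "full"),
    regions = regions,
    total_spike_area = sum(regions$pixel_count),
    labels = labels,
    intermediate = list(cis = binary_mask(plant, "full"),
                        cleaned = cleaned)
  ), class = "spike_detection")
}

#' @export
print.spike_detection <- function(x, ...) {
  cat(sprintf("<spike_detection: %d region(s), total area %d px>\n",
              nrow(x$regions), x$total_spike_area))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Detect spikes in one RGB image
#'
#' Runs the full detection chain: colour-index plant segmentation; grayscale
#' conversion and single-level Haar decomposition; Laws texture features on
#' the approximation image; per-pixel 8-10-2 network classification within
#' the downscaled plant mask; upscaling to full resolution; multi-scale
#' Frangi vesselness on the L* channel and component-wise suppression of
#' leaf-crossing artefacts; bounded morphological reconstruction inside the
#' plant mask. All intermediates are retained for audit.
#'
#' @param img `H x W x 3` RGB array (or a path, which is loaded).
#' @param model A `spike_classifier`.
#' @param cfg A [spike_config()].
#' @return A `spike_detection` (see [reconstruct_spikes()]) whose
#'   `intermediate` list holds `cis`, `nn_half`, `nn_full`, `vesselness`,
#'   `vessel_mask` and `cleaned`.
#' @export
detect_spikes <- function(img, model, cfg = spike_config()) {
  if (is.character(img)) img <- load_image(img)
  check_rgb(img)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("[%s] %s", name, conditionMessage(e))))
  }
  cis <- stage("cis", color_index_segment(img))
  gray <- stage("grayscale", to_grayscale(img))
  A <- stage("dwt", dwt_haar(gray)$A)
  stack <- stage("laws", laws_features(A, laws_masks(), window = cfg$window))
  plant_half <- stage("downscale", downscale_mask(cis))
  nn_half <- stage("classify", classify_image(model, stack, plant_half))
  nn_full_raw <- stage("upscale", upscale_mask(nn_half, dim(cis)))
  nn_full <- binary_mask(as_logical_matrix(nn_full_raw) &
                           as_logical_matrix(cis), "full")
  L <- stage("lightness", lab_lightness(img))
  vmap <- stage("frangi", frangi_multiscale(L, sigmas = cfg$sigmas,
                                            beta = cfg$beta, c = cfg$c,
                                            gamma = cfg$gamma))
  vessels <- stage("vessel-mask", vessel_mask(vmap, cfg$tau_rel))
  cleaned <- stage("suppress",
                   suppress_crossings(nn_full, vessels, cfg$overlap_frac))
  res <- stage("reconstruct",
               reconstruct_spikes(cleaned, cis,
                                  open_radius = cfg$open_radius,
                                  max_geodesic_iter = cfg$max_geodesic_iter))
  res$intermediate <- list(cis = cis, nn_half = nn_half, nn_full = nn_full,
                           vesselness = vmap, vessel_mask = vessels,
                           cleaned = cleaned)
  res
}
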