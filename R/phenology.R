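#' Per-day spike presence rule
#'
#' A spike counts as present on an imaging day when at least
#' `min_orientations` of that day's side-view orientations show a total
#' detected spike area of at least `min_area` pixels (inclusive: exactly 500
#' pixels passes the default floor).
#'
#' @param areas Numeric vector of per-orientation total spike areas for one
#'   day.
#' @param min_area Minimum spike area in pixels.
#' @param min_orientations Minimum number of qualifying orientations.
#' @return Logical flag.
#' @export
spike_present <- function(areas, min_area = 500, min_orientations = 2L) {
  if (length(areas) < 1) abort("need at least one orientation")
  sum(areas >= min_area) >= min_orientations
}

check_series <- function(series) {
  need <- c("day", "angle", "area")
  if (!all(need %in% names(series)))
    abort("series must have columns day, angle, area")
  if (nrow(series) == 0) abort("empty time series")
  invisible(series)
}

# Presence flags per sorted unique day.
presence_flags <- function(series, min_area, min_orientations) {
  series %>%
    group_by(.data$day) %>%
    summarise(present = spike_present(.data$area, min_area,
                                      min_orientations),
              .groups = "drop") %>%
    arrange(.data$day)
}

#' Detect the heading time point (HTP) of a plant
#'
#' The HTP is the earliest imaging day from which the spike is present
#' (per [spike_present()]) on every subsequent observed day through the last
#' day, allowing at most `gap_tolerance` consecutive absent days; isolated
#' early detections are rejected as false emergence. When no day qualifies,
#' the HTP is reported as day 0 (`NOT_DETECTED`).
#'
#' @param series Tibble with columns `day`, `angle`, `area` (one plant;
#'   a `plant_id` column is carried through if present). Needs at least two
#'   distinct days.
#' @param min_area,min_orientations Presence rule parameters.
#' @param gap_tolerance Longest run of absent days allowed after the HTP.
#' @return One-row tibble: `plant_id`, `htp_day` (0 when not detected),
#'   `detected`, `n_days`, and the rule parameters used; the qualifying days
#'   as a list column.
#' @export
detect_htp <- function(series, min_area = 500, min_orientations = 2L,
                       gap_tolerance = 0L) {
  check_series(series)
  flags <- presence_flags(series, min_area, min_orientations)
  if (nrow(flags) < 2) abort("need at least two imaging days")
  pres <- flags$present
  n <- length(pres)
  htp <- 0
  for (i in seq_len(n)) {
    if (!pres[i]) next
    gaps <- rle(!pres[i:n])
    max_gap <- if (any(gaps$values)) max(gaps$lengths[gaps$values]) else 0L
    if (max_gap <= gap_tolerance && pres[n]) { htp <- flags$day[i]; break }
  }
  tibble(
    plant_id = if ("plant_id" %in% names(series))
      series$plant_id[1] else NA_character_,
    htp_day = htp, detected = htp > 0, n_days = n,
    min_area = min_area, min_orientations = min_orientations,
    gap_tolerance = gap_tolerance,
    qualifying_days = list(flags$day[pres]))
}

#' Per-day spike-area growth series
#'
#' From the heading day onward, the plant's spike area per day is the
#' maximum detected area among that day's orientations. The relative day
#' index starts at 1 on the emergence (HTP) day.
#'
#' @inheritParams detect_htp
#' @param htp Optional precomputed [detect_htp()] row; computed if `NULL`.
#' @return Tibble of class `growth_series` with columns `plant_id`, `day`,
#'   `rel_day`, `area`.
#' @export
growth_series <- function(series, min_area = 500, min_orientations = 2L,
                          gap_tolerance = 0L, htp = NULL) {
  check_series(series)
  if (is.null(htp))
    htp <- detect_htp(series, min_area, min_orientations, gap_tolerance)
  if (!htp$detected)
    abort("heading was not detected; no growth series is defined")
  out <- series %>%
    filter(.data$day >= htp$htp_day) %>%
    group_by(.data$day) %>%
    summarise(area = max(.data$area), .groups = "drop") %>%
    arrange(.data$day) %>%
    mutate(rel_day = dplyr::row_number(),
           plant_id = if ("plant_id" %in% names(series))
             series$plant_id[1] else NA_character_) %>%
    dplyr::select("plant_id", "day", "rel_day", "area")
  class(out) <- c("growth_series", class(out))
  out
}

#' Root-mean-square error
#'
#' `sqrt(mean((truth - pred)^2))` between two equal-length series.
#'
#' @param truth,pred Numeric vectors of equal length (at least 1).
#' @return Non-negative scalar; 0 iff the series are identical.
#' @export
rmse <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("series lengths differ")
  if (length(truth) < 1) abort("need at least one value")
  sqrt(mean((truth - pred)^2))
}

#' Coefficient of determination
#'
#' By default the squared Pearson correlation between truth and prediction
#' (the scatter-plot usage; note it is invariant to sign and affine changes
#' of the prediction). `method = "ss"` gives `1 - SS_res / SS_tot` instead.
#'
#' @param truth,pred Numeric vectors, length at least 2; `truth` must not be
#'   constant.
#' @param method `"pearson"` or `"ss"`.
#' @return Scalar.
#' @export
r_squared <- function(truth, pred, method = c("pearson", "ss")) {
  method <- match.arg(method)
  if (length(truth) != length(pred)) abort("series lengths differ")
  if (length(truth) < 2) abort("need at least two values")
  if (sd(truth) == 0) abort("R^2 undefined for constant truth")
  if (method == "pearson") {
    if (sd(pred) == 0) return(0)
    stats::cor(truth, pred)^2
  } else {
    1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  }
}

#' Run spike detection and phenology over an image manifest
#'
#' Applies [detect_spikes()] to every image of a manifest, assembles
#' per-plant time series, detects each plant's HTP and growth curve, and --
#' when ground-truth columns are present -- scores the predictions: RMSE and
#' R-squared of HTP days (`gt_htp`), and per-plant RMSE of spike areas from
#' the detected heading day (`gt_area`). Missing image files are reported
#' and skipped; the run continues.
#'
#' @param manifest Data frame (or CSV path) with columns `plant_id`, `day`,
#'   `angle`, `image_path` and optionally `gt_area`, `gt_htp`.
#' @param model A `spike_classifier`.
#' @param cfg A [spike_config()].
#' @param min_area,min_orientations,gap_tolerance HTP rule parameters.
#' @param out_dir Optional directory for `report.json` and `per_plant.csv`.
#' @return Object of class `htp_report`: list with tibbles `observations`
#'   (per image), `per_plant` (HTP and area scores) and `scores` (one row of
#'   experiment-level metrics, when ground truth is available).
#' @export
run_experiment <- function(manifest, model, cfg = spike_config(),
                           min_area = 500, min_orientations = 2L,
                           gap_tolerance = 0L, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- as_tibble(manifest)
  need <- c("plant_id", "day", "angle", "image_path")
  if (!all(need %in% names(manifest)))
    abort(paste("manifest must have columns", paste(need, collapse = ", ")))
  missing <- !file.exists(manifest$image_path)
  if (any(missing)) {
    warn(sprintf("skipping %d missing image file(s): %s", sum(missing),
                 paste(head(manifest$image_path[missing], 3), collapse = ", ")))
    manifest <- manifest[!missing, , drop = FALSE]
  }
  obs <- manifest %>%
    mutate(area = purrr::map_dbl(.data$image_path, function(p)
      detect_spikes(p, model, cfg)$total_spike_area))

  per_plant <- obs %>%
    group_by(.data$plant_id) %>%
    dplyr::group_modify(function(df, key) {
      htp <- detect_htp(df, min_area, min_orientations, gap_tolerance)
      row <- tibble(htp_day = htp$htp_day, detected = htp$detected,
                    n_days = htp$n_days)
      if ("gt_area" %in% names(df) && htp$detected) {
        gs_pred <- df %>% group_by(.data$day) %>%
          summarise(pred = max(.data$area), gt = max(.data$gt_area),
                    .groups = "drop") %>%
          filter(.data$day >= htp$htp_day)
        row$area_rmse <- rmse(gs_pred$gt, gs_pred$pred)
      }
      row
    }) %>% ungroup()

  scores <- NULL
  if ("gt_htp" %in% names(manifest)) {
    gt <- manifest %>% group_by(.data$plant_id) %>%
      summarise(gt_htp = .data$gt_htp[1], .groups = "drop")
    per_plant <- left_join(per_plant, gt, by = "plant_id")
    scores <- tibble(
      n_plants = nrow(per_plant),
      rmse_htp = rmse(per_plant$gt_htp, per_plant$htp_day),
      r2_htp = if (nrow(per_plant) >= 2 && sd(per_plant$gt_htp) > 0)
        r_squared(per_plant$gt_htp, per_plant$htp_day) else NA_real_,
      mean_area_rmse = if ("area_rmse" %in% names(per_plant))
        mean(per_plant$area_rmse, na.rm = TRUE) else NA_real_)
  }
  report <- structure(list(observations = obs, per_plant = per_plant,
                           scores = scores), class = "htp_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(per_plant[!vapply(per_plant, is.list, TRUE)],
              file.path(out_dir, "per_plant.csv"), row.names = FALSE)
    json <- list(per_plant = per_plant, scores = scores)
    writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                                na = "null"),
               file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.htp_report <- function(x, ...) {
  cat(sprintf("<htp_report: %d plants, %d observations>\n",
              nrow(x$per_plant), nrow(x$observations)))
  print(x$per_plant)
  if (!is.null(x$scores)) print(x$scores)
  invisible(x)
}
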