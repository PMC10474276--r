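#' Cumulative ROI volume curves along the scapula
#'
#' Expresses each region's cumulative volume (ml) as a function of percent
#' location along the predicted total scapula length, on the integer grid
#' p = 1..100. Depth is measured medially from the most lateral scapular
#' voxel; ROI volume lateral to that origin (possible for some muscle
#' insertions) is assigned to the first percent bin. Cumulative volume is
#' linear-interpolated between slice boundaries. Grid points beyond the
#' captured coverage are missing (`NA`), never extrapolated.
#'
#' @param vol A [label_volume()].
#' @param predicted_length_mm Total scapula length (mm), typically from
#'   [predict.scapula_length_model()]; must be at least the captured
#'   scapular extent.
#' @param rois Regions to accumulate (default: every region in the schema).
#' @return An object of class `volume_curve_set`: `cum_ml` (100 x ROI
#'   matrix, ml, `NA` beyond coverage), `boundary_depth_mm` /
#'   `boundary_ml` (exact cumulative values at slice boundaries, for
#'   auditing), `predicted_length_mm`, `coverage_percent`,
#'   `captured_extent_mm`.
#' @export
build_volume_curves <- function(vol, predicted_length_mm,
                                rois = names(vol$schema$labels)) {
  stopifnot(inherits(vol, "label_volume"))
  prof <- compute_csa_profile(vol)
  s <- vol$spacing[1]
  origin <- prof$lateral_origin_index
  extent_mm <- prof$last_scapula_index * s
  if (predicted_length_mm < extent_mm - 1e-9)
    stop(sprintf(paste0("predicted length (%.2f mm) is below the captured ",
                        "scapular extent (%.2f mm); clamp the prediction first"),
                 predicted_length_mm, extent_mm), call. = FALSE)
  n1 <- dim(vol$voxels)[1]
  K <- n1 - origin + 1L
  voxml <- voxel_volume_mm3(vol) / 1000
  boundary_ml <- matrix(0, nrow = K + 1L, ncol = length(rois),
                        dimnames = list(NULL, rois))
  for (r in rois) {
    cnt <- slice_counts(roi_mask(vol, r))
    folded <- cnt[origin:n1]
    if (origin > 1L) folded[1] <- folded[1] + sum(cnt[seq_len(origin - 1L)])
    boundary_ml[, r] <- c(0, cumsum(folded)) * voxml
  }
  depth <- (0:K) * s
  coverage <- extent_mm / predicted_length_mm * 100
  p_grid <- 1:100
  d_p <- p_grid / 100 * predicted_length_mm
  defined <- d_p <= extent_mm + 1e-9
  cum <- matrix(NA_real_, nrow = 100L, ncol = length(rois),
                dimnames = list(p_grid, rois))
  for (r in rois)
    cum[defined, r] <- stats::approx(depth, boundary_ml[, r],
                                     xout = d_p[defined], rule = 2)$y
  structure(list(cum_ml = cum,
                 boundary_depth_mm = depth,
                 boundary_ml = boundary_ml,
                 predicted_length_mm = predicted_length_mm,
                 coverage_percent = coverage,
                 captured_extent_mm = extent_mm,
                 schema = vol$schema),
            class = "volume_curve_set")
}

#' @export
print.volume_curve_set <- function(x, ...) {
  cat(sprintf(paste0("volume_curve_set: %d ROIs, predicted length %.1f mm, ",
                     "coverage %.1f%%\n"),
              ncol(x$cum_ml), x$predicted_length_mm, x$coverage_percent))
  invisible(x)
}

#' Percent grid locations with defined curve values
#'
#' @param curves A [build_volume_curves()] result.
#' @return Integer vector of defined p (1..100, up to coverage).
#' @export
defined_percents <- function(curves) {
  which(!is.na(curves$cum_ml[, 1]))
}

# cumulative ml of one ROI at integer percents p (error if beyond coverage)
curve_at <- function(curves, roi, p) {
  if (!roi %in% colnames(curves$cum_ml))
    stop("unknown ROI: ", roi, call. = FALSE)
  if (any(p < 1L | p > 100L | p != round(p)))
    stop("p must be integers in 1..100", call. = FALSE)
  v <- curves$cum_ml[p, roi]
  if (anyNA(v))
    stop("p beyond captured coverage (",
         sprintf("%.1f%%", curves$coverage_percent), ")", call. = FALSE)
  v
}

# combined muscle + paired intramuscular fat cumulative volume
boundary_at <- function(curves, muscle, p) {
  curve_at(curves, muscle, p) +
    curve_at(curves, fat_roi_of(curves$schema, muscle), p)
}

#' Normalized muscle size at percent location p
#'
#' The ratio of combined muscle-plus-intramuscular-fat cumulative volume to
#' cumulative scapula volume at percent location p — a dimensionless size
#' measure that normalizes for patient size.
#'
#' @param curves A [build_volume_curves()] result.
#' @param muscle One of [rc_muscles()].
#' @param p Integer percent location(s) in 1..coverage; default all defined.
#' @return Named numeric vector (names = p).
#' @export
normalized_muscle_size <- function(curves, muscle, p = defined_percents(curves)) {
  scap <- curve_at(curves, "scapula", p)
  if (any(scap <= 0))
    stop("zero scapula volume at requested p", call. = FALSE)
  stats::setNames(boundary_at(curves, muscle, p) / scap, p)
}

#' Relative contribution of one muscle to the rotator-cuff unit
#'
#' One muscle's share (%) of the total four-muscle rotator-cuff unit volume
#' (each muscle counted with its intramuscular fat) at percent location p.
#' The four contributions sum to 100 at every defined p.
#'
#' @inheritParams normalized_muscle_size
#' @return Named numeric vector of percents.
#' @export
relative_contribution <- function(curves, muscle, p = defined_percents(curves)) {
  total <- Reduce(`+`, lapply(rc_muscles(), boundary_at, curves = curves, p = p))
  if (any(total <= 0))
    stop("zero total rotator-cuff unit volume at requested p", call. = FALSE)
  stats::setNames(boundary_at(curves, muscle, p) / total * 100, p)
}

#' Fatty infiltration of one muscle at percent location p
#'
#' The ratio (%) of cumulative intramuscular fat volume to the muscle's
#' total boundary volume (muscle + fat) at percent location p.
#'
#' @inheritParams normalized_muscle_size
#' @return Named numeric vector of percents in `[0, 100]`.
#' @export
fat_infiltration <- function(curves, muscle, p = defined_percents(curves)) {
  bound <- boundary_at(curves, muscle, p)
  if (any(bound <= 0))
    stop("zero muscle boundary volume at requested p", call. = FALSE)
  fat <- curve_at(curves, fat_roi_of(curves$schema, muscle), p)
  stats::setNames(fat / bound * 100, p)
}

#' Full per-scan metric pipeline
#'
#' Runs the whole measurement chain on one labelled volume: lateral
#' morphometrics, predicted total scapula length (clamped to the captured
#' extent if needed), cumulative volume curves, and the three per-muscle
#' metrics (normalized size, relative contribution, fatty infiltration) at
#' every defined percent location.
#'
#' @param vol A [label_volume()].
#' @param model A fitted [fit_length_model()] (or one read from JSON).
#' @param coverage_threshold Scans whose coverage falls below this percent
#'   (default 30) are flagged `low_coverage`.
#' @param vertical_axis Passed to [measure_lateral_morphometrics()].
#' @return An object of class `scan_metrics`: long-format `metrics` data
#'   frame (`muscle`, `p`, `cumulative_ml`, `normalized_size`,
#'   `relative_contribution_pct`, `fat_infiltration_pct`), plus
#'   `morphometrics`, `predicted_length_mm`, `length_clamped`,
#'   `coverage_percent`, `low_coverage`, `missing_muscles` (muscles with no
#'   captured voxels; their metrics are `NA`), and the `curves`.
#' @export
compute_scan_metrics <- function(vol, model, coverage_threshold = 30,
                                 vertical_axis = "row") {
  morpho <- measure_lateral_morphometrics(vol, vertical_axis = vertical_axis)
  pred <- predict(model, morpho)
  clamped <- attr(pred, "clamped")
  curves <- build_volume_curves(vol, as.numeric(pred))
  pp <- defined_percents(curves)
  muscles <- rc_muscles()
  missing_muscles <- muscles[vapply(muscles, function(m)
    boundary_at(curves, m, pp[length(pp)]) <= 0, logical(1))]
  rows <- lapply(muscles, function(m) {
    cum <- boundary_at(curves, m, pp)
    if (m %in% missing_muscles) {
      data.frame(muscle = m, p = pp, cumulative_ml = cum,
                 normalized_size = NA_real_,
                 relative_contribution_pct = NA_real_,
                 fat_infiltration_pct = NA_real_)
    } else {
      data.frame(muscle = m, p = pp, cumulative_ml = cum,
                 normalized_size = as.numeric(normalized_muscle_size(curves, m, pp)),
                 relative_contribution_pct = as.numeric(relative_contribution(curves, m, pp)),
                 fat_infiltration_pct = ifelse(cum > 0,
                   as.numeric(curve_at(curves, fat_roi_of(curves$schema, m), pp)) / cum * 100,
                   NA_real_))
    }
  })
  structure(list(
    metrics = do.call(rbind, rows),
    morphometrics = morpho,
    predicted_length_mm = as.numeric(pred),
    length_clamped = isTRUE(any(clamped)),
    coverage_percent = curves$coverage_percent,
    low_coverage = curves$coverage_percent < coverage_threshold,
    coverage_threshold = coverage_threshold,
    curves = curves
  ), class = "scan_metrics")
}

#' @export
print.scan_metrics <- function(x, ...) {
  cat(sprintf("scan_metrics: predicted length %.1f mm%s, coverage %.1f%%%s\n",
              x$predicted_length_mm,
              if (x$length_clamped) " (clamped to captured extent)" else "",
              x$coverage_percent,
              if (x$low_coverage)
                sprintf(" [below %g%% analysis threshold]", x$coverage_threshold)
              else ""))
  pmax_def <- max(x$metrics$p)
  at <- x$metrics[x$metrics$p == min(pmax_def, 30), ]
  cat(sprintf("  at p = %d:\n", unique(at$p)))
  for (i in seq_len(nrow(at)))
    cat(sprintf("    %-14s size %.3f, contribution %.1f%%, FI %.1f%%\n",
                at$muscle[i], at$normalized_size[i],
                at$relative_contribution_pct[i], at$fat_infiltration_pct[i]))
  invisible(x)
}

#' Write per-scan metrics as long-format CSV
#'
#' @param x A [compute_scan_metrics()] result.
#' @param path Output CSV path.
#' @param scan_id Identifier written in the `scan_id` column.
#' @return `path`, invisibly.
#' @export
write_scan_metrics <- function(x, path, scan_id = "scan") {
  stopifnot(inherits(x, "scan_metrics"))
  df <- cbind(scan_id = scan_id, x$metrics,
              coverage_pct = x$coverage_percent)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
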