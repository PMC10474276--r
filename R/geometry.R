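#' Per-slice scapular cross-sectional-area profile
#'
#' Computes the scapula's cross-sectional area (CSA, mm^2) in every sagittal
#' slice, starting at the most lateral slice that contains scapula. The
#' profile runs medially to the end of the captured volume, so trailing
#' zero-area slices (captured but medial to the scapula) are retained.
#'
#' @param vol A [label_volume()] whose schema names a `scapula` region.
#' @return An object of class `csa_profile` with fields `areas` (mm^2, one
#'   per slice from the lateral scapular origin), `slice_spacing` (mm),
#'   `lateral_origin_index` (1-based slice index of the first scapular
#'   slice) and `last_scapula_index` (relative to the profile).
#' @export
compute_csa_profile <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  counts <- slice_counts(roi_mask(vol, "scapula"))
  nz <- which(counts > 0L)
  if (!length(nz)) stop("scapula ROI is empty", call. = FALSE)
  origin <- nz[1]
  areas <- counts[origin:length(counts)] * prod(vol$spacing[2:3])
  structure(list(areas = areas,
                 slice_spacing = vol$spacing[1],
                 lateral_origin_index = origin,
                 last_scapula_index = nz[length(nz)] - origin + 1L),
            class = "csa_profile")
}

#' Locate the peak cross-sectional area within the lateral window
#'
#' The peak CSA is searched only within the lateral portion of the captured
#' scapular extent (by default its first half): the scapula can exhibit a
#' second, more medial CSA maximum, but on partial-coverage clinical scans
#' only the lateral peak is a dependable landmark. Ties break to the most
#' lateral slice.
#'
#' @param profile A [compute_csa_profile()] result.
#' @param search_fraction Fraction of the profile searched from the lateral
#'   end (default 0.5).
#' @return 1-based index into `profile$areas` of the peak slice.
#' @export
find_peak_csa <- function(profile, search_fraction = 0.5) {
  stopifnot(inherits(profile, "csa_profile"))
  n <- length(profile$areas)
  if (n < 1L) stop("empty CSA profile", call. = FALSE)
  window <- max(1L, ceiling(search_fraction * n))
  which.max(profile$areas[seq_len(window)])
}

#' Lateral scapular morphometrics at the peak-CSA slice
#'
#' Measures the four predictors of total scapula length from the lateral
#' scapula: PD, the sagittal distance (mm) from the most lateral scapular
#' point to the peak-CSA slice; PC, the peak CSA itself (mm^2); and VB/HB,
#' the vertical and horizontal extents (mm) of the tight axis-aligned
#' bounding box of the scapula in the peak slice. Also reports the captured
#' scapular extent (mm, lateral origin through the most medial captured
#' scapular slice).
#'
#' @param vol A [label_volume()].
#' @param profile Optional precomputed [compute_csa_profile()]; computed if
#'   `NULL`.
#' @param peak_index Optional precomputed [find_peak_csa()] index.
#' @param vertical_axis Which in-plane array axis maps to "vertical":
#'   `"row"` (default) or `"column"`. The complementary axis is horizontal.
#' @return An object of class `lateral_morphometrics`: a list with
#'   `PD_mm`, `PC_mm2`, `VB_mm`, `HB_mm`, `captured_extent_mm`,
#'   `peak_index`.
#' @details Distances are measured slice-centre to slice-centre, so PD is
#'   `(peak_index - 1) * slice_spacing`; no sub-slice interpolation of the
#'   peak is attempted. The captured extent counts whole slices
#'   (`n_slices * spacing`).
#' @export
measure_lateral_morphometrics <- function(vol, profile = NULL,
                                          peak_index = NULL,
                                          vertical_axis = c("row", "column")) {
  vertical_axis <- match.arg(vertical_axis)
  if (is.null(profile)) profile <- compute_csa_profile(vol)
  if (is.null(peak_index)) peak_index <- find_peak_csa(profile)
  n <- length(profile$areas)
  if (peak_index < 1L || peak_index > n)
    stop("peak_index outside profile", call. = FALSE)
  slice <- profile$lateral_origin_index + peak_index - 1L
  m2d <- roi_mask(vol, "scapula")[slice, , ]
  if (!any(m2d)) stop("scapula empty at peak slice", call. = FALSE)
  rows <- range(which(apply(m2d, 1L, any)))
  cols <- range(which(apply(m2d, 2L, any)))
  row_extent <- (rows[2] - rows[1] + 1L) * vol$spacing[2]
  col_extent <- (cols[2] - cols[1] + 1L) * vol$spacing[3]
  vb <- if (vertical_axis == "row") row_extent else col_extent
  hb <- if (vertical_axis == "row") col_extent else row_extent
  structure(list(
    PD_mm = (peak_index - 1L) * profile$slice_spacing,
    PC_mm2 = profile$areas[peak_index],
    VB_mm = vb,
    HB_mm = hb,
    captured_extent_mm = profile$last_scapula_index * profile$slice_spacing,
    peak_index = peak_index
  ), class = "lateral_morphometrics")
}

#' @export
print.lateral_morphometrics <- function(x, ...) {
  cat(sprintf(paste0("lateral morphometrics: PD %.1f mm, PC %.1f mm^2, ",
                     "VB %.1f mm, HB %.1f mm (captured extent %.1f mm)\n"),
              x$PD_mm, x$PC_mm2, x$VB_mm, x$HB_mm, x$captured_extent_mm))
  invisible(x)
}

#' @export
as.data.frame.lateral_morphometrics <- function(x, ...) {
  data.frame(PD_mm = x$PD_mm, PC_mm2 = x$PC_mm2, VB_mm = x$VB_mm,
             HB_mm = x$HB_mm, captured_extent_mm = x$captured_extent_mm)
}
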