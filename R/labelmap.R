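#' Construct a labelled segmentation volume
#'
#' A `label_volume` is a 3-D integer voxel grid with physical spacing and a
#' fixed anatomical convention: the first array axis is the sagittal
#' (slice) axis and, after canonicalization, slice index 1 is the most
#' lateral captured slice with increasing index moving medially. Left
#' shoulders are mirrored along the sagittal axis at construction so that
#' left and right scans share one geometry and can be pooled.
#'
#' @param voxels 3-D integer array of region labels (0 = background).
#' @param spacing Numeric length-3, mm per voxel along (sagittal, row,
#'   column); strictly positive.
#' @param schema An [roi_schema()]; all nonzero voxel values must appear in
#'   it.
#' @param laterality `"right"` or `"left"`. Left volumes are flipped along
#'   the sagittal axis (and relabelled as canonical).
#' @param canonicalize Flip left volumes to the common convention
#'   (default `TRUE`).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing, schema = default_roi_schema(),
                         laterality = c("right", "left"),
                         canonicalize = TRUE) {
  laterality <- match.arg(laterality)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  storage.mode(voxels) <- "integer"
  dimnames(voxels) <- NULL
  dim(voxels) <- unname(dim(voxels))
  vals <- sort(unique(as.vector(voxels)))
  vals <- vals[vals != 0L]
  unknown <- setdiff(vals, unname(schema$labels))
  if (length(unknown))
    stop("voxel labels absent from schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mirrored <- FALSE
  if (laterality == "left" && canonicalize) {
    voxels <- voxels[dim(voxels)[1]:1, , , drop = FALSE]
    mirrored <- TRUE
  }
  structure(list(voxels = voxels, spacing = spacing, schema = schema,
                 laterality = laterality, mirrored = mirrored),
            class = "label_volume")
}

#' Read a labelled NIfTI segmentation volume
#'
#' Reads a NIfTI-1 file of integer labels, takes voxel spacing from the
#' header, validates labels against the schema, and canonicalizes
#' orientation (left shoulders mirrored along the sagittal axis). The first
#' array axis is treated as the sagittal axis.
#'
#' @inheritParams label_volume
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D integer
#'   volume.
#' @return A [label_volume()].
#' @details A warning (not an error) is raised when sagittal spacing
#'   exceeds 6 mm or in-plane spacing exceeds 1 mm, the usual quality floor
#'   for volumetric fat and muscle quantification on clinical scans.
#' @export
read_label_volume <- function(path, schema = default_roi_schema(),
                              laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in NIfTI header", call. = FALSE)
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("volume is not integer-labelled", call. = FALSE)
  if (spacing[1] > 6 || any(spacing[2:3] > 1))
    warning("voxel spacing coarser than 6 mm sagittal / 1 mm in-plane; ",
            "volumetric metrics may be unreliable", call. = FALSE)
  label_volume(round(arr), spacing, schema = schema, laterality = laterality)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary mask of one region of interest
#'
#' @param vol A [label_volume()].
#' @param roi_name Region name present in the volume's schema.
#' @return Logical 3-D array, `TRUE` exactly where the voxel carries the
#'   region's label.
#' @export
roi_mask <- function(vol, roi_name) {
  stopifnot(inherits(vol, "label_volume"))
  vol$voxels == roi_label(vol$schema, roi_name)
}

#' Mask of a muscle's full boundary (muscle plus intramuscular fat)
#'
#' The muscle boundary is the anatomical compartment: lean muscle voxels
#' plus the intramuscular fat labelled inside it.
#'
#' @inheritParams roi_mask
#' @param muscle One of [rc_muscles()].
#' @return Logical 3-D array.
#' @export
muscle_boundary_mask <- function(vol, muscle) {
  roi_mask(vol, muscle) | roi_mask(vol, fat_roi_of(vol$schema, muscle))
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  vals <- sort(unique(as.vector(x$voxels)))
  vals <- vals[vals != 0L]
  nm <- names(x$schema$labels)[match(vals, x$schema$labels)]
  cat("  regions present:", if (length(nm)) paste(nm, collapse = ", ") else "none", "\n")
  cat("  laterality:", x$laterality,
      if (isTRUE(x$mirrored)) "(mirrored to canonical)" else "", "\n")
  invisible(x)
}

# physical voxel volume in mm^3
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

# per-slice voxel counts of a logical mask along the sagittal axis
slice_counts <- function(mask) {
  apply(mask, 1L, sum)
}
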