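#' Names of the four rotator-cuff muscles
#'
#' The four muscles of the rotator cuff in the order used throughout the
#' package: supraspinatus, infraspinatus, teres minor, subscapularis.
#'
#' @return Character vector of length 4.
#' @export
rc_muscles <- function() {
  c("supraspinatus", "infraspinatus", "teres_minor", "subscapularis")
}

#' Construct a region-of-interest labelling schema
#'
#' A schema maps anatomical region names to the positive integer labels used
#' in a segmentation volume, and pairs each rotator-cuff muscle with its
#' intramuscular-fat compartment. Background is always label 0 and is never
#' part of the schema.
#'
#' @param labels Named integer vector: region name -> positive label.
#' @param fat_pairs Named character vector: muscle name -> name of its paired
#'   intramuscular-fat region. Every rotator-cuff muscle present in `labels`
#'   must have exactly one fat pairing.
#' @return An object of class `roi_schema`.
#' @seealso [default_roi_schema()], [read_roi_schema()]
#' @export
roi_schema <- function(labels, fat_pairs) {
  labels <- vapply(labels, as.integer, integer(1))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("all labels must be named", call. = FALSE)
  if (any(labels <= 0L))
    stop("labels must be positive integers (0 is background)", call. = FALSE)
  if (anyDuplicated(labels))
    stop("labels must be unique", call. = FALSE)
  if (anyDuplicated(names(labels)))
    stop("region names must be unique", call. = FALSE)
  fat_pairs <- vapply(fat_pairs, as.character, character(1))
  muscles_here <- intersect(rc_muscles(), names(labels))
  missing_pair <- setdiff(muscles_here, names(fat_pairs))
  if (length(missing_pair))
    stop("muscles without a paired fat region: ",
         paste(missing_pair, collapse = ", "), call. = FALSE)
  bad <- setdiff(unname(fat_pairs), names(labels))
  if (length(bad))
    stop("fat_pairs refer to regions absent from labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, fat_pairs = fat_pairs),
            class = "roi_schema")
}

#' Default 11-region shoulder schema
#'
#' The standard labelling of a segmented shoulder: three bones (humerus,
#' scapula, clavicle), the four rotator-cuff muscles and their four
#' intramuscular-fat compartments, labelled 1 through 11.
#'
#' @return An `roi_schema` with 11 regions.
#' @export
default_roi_schema <- function() {
  roi_schema(
    labels = c(humerus = 1L, scapula = 2L, clavicle = 3L,
               supraspinatus = 4L, supraspinatus_fat = 5L,
               infraspinatus = 6L, infraspinatus_fat = 7L,
               teres_minor = 8L, teres_minor_fat = 9L,
               subscapularis = 10L, subscapularis_fat = 11L),
    fat_pairs = c(supraspinatus = "supraspinatus_fat",
                  infraspinatus = "infraspinatus_fat",
                  teres_minor = "teres_minor_fat",
                  subscapularis = "subscapularis_fat")
  )
}

#' Read or write a schema as a JSON sidecar
#'
#' The JSON layout is flat `{region_name: label, ...}` plus a reserved
#' `"fat_pairs"` object `{muscle: fat_region, ...}`, so third-party
#' segmentations can declare their own labelling.
#'
#' @param path Path to a JSON file.
#' @return `read_roi_schema()` returns an `roi_schema`;
#'   `write_roi_schema()` returns `path` invisibly.
#' @export
read_roi_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- x[["fat_pairs"]]
  x[["fat_pairs"]] <- NULL
  roi_schema(labels = unlist(x), fat_pairs = unlist(fp))
}

#' @rdname read_roi_schema
#' @param schema An `roi_schema`.
#' @export
write_roi_schema <- function(schema, path) {
  stopifnot(inherits(schema, "roi_schema"))
  out <- as.list(schema$labels)
  out$fat_pairs <- as.list(schema$fat_pairs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.roi_schema <- function(x, ...) {
  cat("ROI schema:", length(x$labels), "regions\n")
  for (nm in names(x$labels)) cat(sprintf("  %2d  %s\n", x$labels[[nm]], nm))
  invisible(x)
}

roi_label <- function(schema, roi_name) {
  if (!roi_name %in% names(schema$labels))
    stop("unknown ROI name: ", roi_name, call. = FALSE)
  schema$labels[[roi_name]]
}

fat_roi_of <- function(schema, muscle) {
  if (!muscle %in% names(schema$fat_pairs))
    stop("no fat pairing for muscle: ", muscle, call. = FALSE)
  schema$fat_pairs[[muscle]]
}
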