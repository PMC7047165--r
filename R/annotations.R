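#' Annotation set for one radiograph
#'
#' Bundles the polygons and flags attached to one lateral radiograph:
#' the keel outline (traced up to the insertion of the trabecula
#' intermedia), an optional open deviation outline, exclusion regions
#' (callus, legs overlapping the keel), the human fracture score, and
#' the wedge/background ROIs used for calibration.
#'
#' @param keel_outline simple polygon (n x 2 matrix, 0-based pixel
#'   coordinates, >= 3 vertices).
#' @param deviation_outline optional open polyline along the deformed
#'   boundary (`NULL` when the keel is not deviated).
#' @param exclusion_regions list of polygons removed before density
#'   measurement; they may extend outside the keel.
#' @param fracture_flag 0, 1 or `NA` (`NA` marks a radiograph that could
#'   not be evaluated for fractures).
#' @param wedge_rois list of step ROI rectangles
#'   `c(xmin, ymin, xmax, ymax)`.
#' @param background_roi background ROI rectangle.
#' @param pixel_spacing physical pixel size, mm/pixel.
#' @return object of class `"annotation_set"`.
#' @export
annotation_set <- function(keel_outline, deviation_outline = NULL,
                           exclusion_regions = list(), fracture_flag = NA_integer_,
                           wedge_rois = NULL, background_roi = NULL,
                           pixel_spacing = 1) {
  keel_outline <- as_polygon(keel_outline)
  if (!is_simple_polygon(keel_outline)) stop("keel_outline is self-intersecting")
  if (!is.null(deviation_outline)) {
    deviation_outline <- as.matrix(deviation_outline)
    if (nrow(deviation_outline) < 3L)
      stop("deviation_outline needs at least 3 vertices")
  }
  if (!is.list(exclusion_regions)) stop("exclusion_regions must be a list")
  exclusion_regions <- lapply(exclusion_regions, as_polygon)
  if (!is.na(fracture_flag) && !fracture_flag %in% c(0L, 1L))
    stop("fracture_flag must be 0, 1 or NA (non-evaluable)")
  stopifnot(pixel_spacing > 0)
  structure(list(keel_outline = keel_outline,
                 deviation_outline = deviation_outline,
                 exclusion_regions = exclusion_regions,
                 fracture_flag = as.integer(fracture_flag),
                 wedge_rois = wedge_rois,
                 background_roi = background_roi,
                 pixel_spacing = pixel_spacing),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Radiograph annotations\n")
  cat(sprintf("  keel outline: %d vertices\n", nrow(x$keel_outline)))
  cat(sprintf("  deviation outline: %s\n",
              if (is.null(x$deviation_outline)) "none"
              else sprintf("%d vertices", nrow(x$deviation_outline))))
  cat(sprintf("  exclusion regions: %d\n", length(x$exclusion_regions)))
  cat(sprintf("  fracture flag: %s\n",
              if (is.na(x$fracture_flag)) "unknown" else x$fracture_flag))
  cat(sprintf("  pixel spacing: %g mm/px\n", x$pixel_spacing))
  invisible(x)
}

poly_to_list <- function(p) if (is.null(p)) NULL else unname(apply(p, 1L, as.numeric, simplify = FALSE))
list_to_poly <- function(l) if (is.null(l) || !length(l)) NULL else do.call(rbind, lapply(l, as.numeric))
roi_to_list <- function(r) if (is.null(r)) NULL else as.list(stats::setNames(as.numeric(r), c("xmin", "ymin", "xmax", "ymax")))
list_to_roi <- function(l) if (is.null(l)) NULL else c(xmin = l$xmin, ymin = l$ymin, xmax = l$xmax, ymax = l$ymax)

#' Write annotations to JSON
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  obj <- list(
    pixel_spacing = ann$pixel_spacing,
    fracture_flag = if (is.na(ann$fracture_flag)) "unknown" else ann$fracture_flag,
    keel_outline = poly_to_list(ann$keel_outline),
    deviation_outline = poly_to_list(ann$deviation_outline),
    exclusion_regions = lapply(ann$exclusion_regions, poly_to_list),
    wedge_rois = lapply(ann$wedge_rois, roi_to_list),
    background_roi = roi_to_list(ann$background_roi))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read annotations from JSON
#'
#' @param path JSON file written by [write_annotations()] (or by any
#'   annotation tool following the same schema).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ff <- obj$fracture_flag
  ff <- if (is.null(ff) || identical(ff, "unknown")) NA_integer_ else as.integer(ff)
  annotation_set(
    keel_outline = list_to_poly(obj$keel_outline),
    deviation_outline = list_to_poly(obj$deviation_outline),
    exclusion_regions = lapply(obj$exclusion_regions %||% list(), list_to_poly),
    fracture_flag = ff,
    wedge_rois = lapply(obj$wedge_rois %||% list(), list_to_roi),
    background_roi = list_to_roi(obj$background_roi),
    pixel_spacing = obj$pixel_spacing %||% 1)
}

#' Write a phantom (or any gray image) to disk
#'
#' 16-bit images go to TIFF, 8-bit images to PNG, both single-channel
#' grayscale.
#'
#' @param image integer-valued gray matrix.
#' @param path output file; extension `.tif`/`.tiff` or `.png`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bit_depth = 16L) {
  stopifnot(is.matrix(image), bit_depth %in% c(8L, 16L))
  cap <- 2^bit_depth - 1
  scaled <- pmin(pmax(image, 0), cap) / cap
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a grayscale radiograph
#'
#' @param path TIFF or PNG file.
#' @param bit_depth bit depth used to rescale the stored [0, 1] samples
#'   back to integer gray values.
#' @return numeric gray matrix.
#' @export
read_gray_image <- function(path, bit_depth = 16L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * (2^bit_depth - 1))
}
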