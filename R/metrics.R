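#' Proportion of deviated keel bone area (POD)
#'
#' POD expresses the severity of a keel deviation as the percentage of
#' the (assumed total) keel surface area taken up by the chord-closed
#' deviated area. The chord-closed deviation polygon may protrude beyond
#' the keel outline — it is an area *estimate*, so its full area is used
#' without clipping (clipping available via `clip = TRUE`).
#'
#' @param keel_outline keel polygon.
#' @param deviation_polygon closed deviation polygon (e.g. from
#'   [close_deviation_outline()]).
#' @param pixel_spacing mm/pixel (cancels in the ratio; accepted for
#'   interface symmetry).
#' @param clip if `TRUE`, intersect the deviation polygon with the
#'   keel's pixel mask before measuring (pixel-count approximation).
#' @return POD in percent.
#' @export
compute_pod <- function(keel_outline, deviation_polygon, pixel_spacing = 1,
                        clip = FALSE) {
  a_keel <- polygon_area(keel_outline, pixel_spacing)
  if (a_keel <= 0) stop("keel outline has zero area")
  if (!clip) {
    a_dev <- polygon_area(deviation_polygon, pixel_spacing)
    return(100 * a_dev / a_keel)
  }
  keel_outline <- as_polygon(keel_outline)
  deviation_polygon <- as_polygon(deviation_polygon)
  all_pts <- rbind(keel_outline, deviation_polygon)
  nr <- ceiling(max(all_pts[, 2L])) + 2L
  nc <- ceiling(max(all_pts[, 1L])) + 2L
  mk <- polygon_mask(keel_outline, nr, nc)
  md <- polygon_mask(deviation_polygon, nr, nc)
  100 * sum(mk & md) / sum(mk)
}

#' Radiographic density of the keel in mm Al eq
#'
#' Rasterizes the keel outline to a pixel mask (even-odd rule at pixel
#' centres), removes exclusion regions (callus, overlapping legs, which
#' would inflate the measure), averages the remaining gray values and
#' maps the mean through the step-wedge calibration.
#'
#' @param image gray matrix.
#' @param annotations an [annotation_set()].
#' @param curve a `"keel_calibration"`.
#' @return list with `density` (mm Al eq), `excluded_area_fraction`
#'   (share of keel pixels removed), `mean_gray` and `n_pixels`.
#' @export
radiographic_density <- function(image, annotations, curve) {
  stopifnot(is.matrix(image), inherits(annotations, "annotation_set"),
            inherits(curve, "keel_calibration"))
  nr <- nrow(image); nc <- ncol(image)
  mask <- polygon_mask(annotations$keel_outline, nr, nc)
  n_keel <- sum(mask)
  if (n_keel == 0L) stop("keel outline rasterizes to an empty mask")
  for (ex in annotations$exclusion_regions)
    mask <- mask & !polygon_mask(ex, nr, nc)
  n_left <- sum(mask)
  if (n_left == 0L) stop("keel fully excluded: no pixels left for density")
  mg <- mean(image[mask])
  dens <- gray_to_mm_al(curve, mg)
  list(density = as.numeric(dens),
       excluded_area_fraction = 1 - n_left / n_keel,
       mean_gray = mg, n_pixels = n_left)
}

#' Score one annotated radiograph
#'
#' Assembles the full per-radiograph metric set: the human fracture flag
#' (copied verbatim; `NA` marks a non-evaluable radiograph), deviation
#' presence, POD, areas and radiographic density.
#'
#' @param image gray matrix.
#' @param annotations an [annotation_set()].
#' @param curve a `"keel_calibration"`.
#' @return object of class `"keel_metrics"`: `fractured` (0/1/NA),
#'   `deviated`, `pod` (percent, `NA` when not deviated), `density`
#'   (mm Al eq), `area_keel` and `area_deviation` (mm^2),
#'   `excluded_area_fraction`.
#' @export
score_radiograph <- function(image, annotations, curve) {
  stopifnot(inherits(annotations, "annotation_set"))
  ps <- annotations$pixel_spacing
  area_keel <- polygon_area(annotations$keel_outline, ps)
  deviated <- !is.null(annotations$deviation_outline)
  pod <- NA_real_; area_dev <- NA_real_
  if (deviated) {
    devpoly <- close_deviation_outline(annotations$deviation_outline)
    area_dev <- polygon_area(devpoly, ps)
    pod <- compute_pod(annotations$keel_outline, devpoly, ps)
  }
  dens <- radiographic_density(image, annotations, curve)
  structure(list(fractured = annotations$fracture_flag,
                 deviated = deviated, pod = pod,
                 density = dens$density,
                 area_keel = area_keel, area_deviation = area_dev,
                 excluded_area_fraction = dens$excluded_area_fraction),
            class = "keel_metrics")
}

#' @export
print.keel_metrics <- function(x, ...) {
  cat("Keel bone metrics\n")
  cat(sprintf("  fractured: %s\n",
              if (is.na(x$fractured)) "not evaluable" else x$fractured))
  cat(sprintf("  deviated:  %s%s\n", x$deviated,
              if (x$deviated) sprintf("  (POD %.2f%%)", x$pod) else ""))
  cat(sprintf("  density:   %.3f mm Al eq  (%.1f%% of keel excluded)\n",
              x$density, 100 * x$excluded_area_fraction))
  cat(sprintf("  areas:     keel %.2f mm^2%s\n", x$area_keel,
              if (x$deviated) sprintf(", deviation %.2f mm^2", x$area_deviation) else ""))
  invisible(x)
}
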