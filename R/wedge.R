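#' Aluminium step-wedge specification
#'
#' Describes the calibration wedge radiographed next to each hen: a
#' staircase of aluminium steps of known, strictly increasing thickness.
#' The default is a 17-step wedge running from 0.5 to 4.5 mm in 0.25 mm
#' increments. Pixel ROIs for each step and for the unattenuated
#' background may be attached when the wedge position in the image is
#' known (the phantom generator fills them in).
#'
#' @param n_steps number of steps (at least 4, so that a cubic
#'   calibration is identifiable).
#' @param t_min thickness of the first step, mm.
#' @param increment thickness increment between consecutive steps, mm.
#' @param step_rois optional list of `n_steps` rectangles, each a named
#'   numeric vector `c(xmin, ymin, xmax, ymax)` in 0-based pixel indices
#'   (inclusive).
#' @param background_roi optional rectangle for the thickness-0
#'   background region, same format.
#' @return an object of class `"step_wedge_spec"`.
#' @export
step_wedge_spec <- function(n_steps = 17L, t_min = 0.5, increment = 0.25,
                            step_rois = NULL, background_roi = NULL) {
  n_steps <- as.integer(n_steps)
  stopifnot(length(n_steps) == 1L, length(t_min) == 1L, length(increment) == 1L)
  if (n_steps < 4L) stop("n_steps must be >= 4 for a cubic calibration")
  if (increment <= 0) stop("increment must be positive (thickness ladder strictly increasing)")
  if (t_min <= 0) stop("t_min must be positive")
  if (!is.null(step_rois) && length(step_rois) != n_steps)
    stop("step_rois must contain one rectangle per step")
  structure(list(n_steps = n_steps, t_min = t_min, increment = increment,
                 step_rois = step_rois, background_roi = background_roi),
            class = "step_wedge_spec")
}

#' @export
print.step_wedge_spec <- function(x, ...) {
  tt <- wedge_thicknesses(x)
  cat(sprintf("Aluminium step wedge: %d steps, %.2f to %.2f mm (increment %.2f mm)\n",
              x$n_steps, tt[1L], tt[x$n_steps], x$increment))
  cat(if (is.null(x$step_rois)) "ROIs: not set\n" else "ROIs: set\n")
  invisible(x)
}

#' Thickness ladder of a step wedge
#'
#' @param spec a [step_wedge_spec()].
#' @return numeric vector of step thicknesses in mm; element i equals
#'   `t_min + (i - 1) * increment`.
#' @export
#' @examples
#' wedge_thicknesses(step_wedge_spec())  # 0.5, 0.75, ..., 4.5
wedge_thicknesses <- function(spec) {
  stopifnot(inherits(spec, "step_wedge_spec"))
  spec$t_min + (seq_len(spec$n_steps) - 1L) * spec$increment
}

roi_pixels <- function(image, roi) {
  if (is.null(roi)) stop("ROI is not set")
  roi <- as.numeric(roi)
  if (length(roi) != 4L || anyNA(roi))
    stop("ROI must be c(xmin, ymin, xmax, ymax)")
  xmin <- roi[1L]; ymin <- roi[2L]; xmax <- roi[3L]; ymax <- roi[4L]
  if (xmin > xmax || ymin > ymax) stop("ROI has zero or negative extent")
  if (xmin < 0 || ymin < 0 || xmax > ncol(image) - 1L || ymax > nrow(image) - 1L)
    stop("ROI lies (partly) outside the image")
  image[(ymin:ymax) + 1L, (xmin:xmax) + 1L]
}

#' Measure background and step gray values
#'
#' Each value is the trimmed mean (central 80% of pixels) of its ROI, a
#' guard against dust and edge pixels.
#'
#' @param image a numeric gray-value matrix (rows = y, columns = x).
#' @param spec a [step_wedge_spec()] with `step_rois` and
#'   `background_roi` set.
#' @return list with `background_gray` and `step_grays` (length
#'   `n_steps`).
#' @export
measure_step_grays <- function(image, spec) {
  stopifnot(is.matrix(image), is.numeric(image), inherits(spec, "step_wedge_spec"))
  if (is.null(spec$step_rois) || is.null(spec$background_roi))
    stop("spec must carry step_rois and background_roi")
  bg <- mean(roi_pixels(image, spec$background_roi), trim = 0.1)
  sg <- vapply(spec$step_rois,
               function(r) mean(roi_pixels(image, r), trim = 0.1), numeric(1L))
  list(background_gray = bg, step_grays = unname(sg))
}

#' Fit a cubic step-wedge calibration curve
#'
#' Least-squares degree-3 polynomial expressing aluminium-equivalent
#' thickness as a function of gray value, fitted to the measured step
#' grays plus the background as a genuine (gray, 0 mm) point. The fit
#' direction (thickness-of-gray) makes later evaluation direct and works
#' for either detector polarity, as long as gray is strictly monotone in
#' thickness.
#'
#' @param background_gray mean gray of the unattenuated background.
#' @param step_grays mean grays of the steps, ordered by step.
#' @param thicknesses step thicknesses in mm (same order).
#' @return an object of class `"keel_calibration"`: coefficients (c0..c3
#'   of `t(g) = c0 + c1 g + c2 g^2 + c3 g^3`), `gray_range`,
#'   `fit_residual` (root-mean-square, mm), `direction` (+1 if gray
#'   increases with thickness), `monotone` (checked on a 256-point grid),
#'   and `background_mm` (fitted thickness at the background gray, which
#'   should sit within 0.1 mm of zero).
#' @export
fit_calibration <- function(background_gray, step_grays, thicknesses) {
  stopifnot(length(background_gray) == 1L, is.finite(background_gray))
  step_grays <- as.numeric(step_grays); thicknesses <- as.numeric(thicknesses)
  if (length(step_grays) != length(thicknesses))
    stop("step_grays and thicknesses must have equal length")
  if (length(step_grays) < 4L) stop("need at least 4 steps for a cubic fit")
  if (is.unsorted(thicknesses, strictly = TRUE))
    stop("thicknesses must be strictly increasing")

  g <- c(background_gray, step_grays)      # thickness 0 point included
  t <- c(0, thicknesses)
  dg <- diff(g)
  if (all(abs(dg) < .Machine$double.eps * max(abs(g), 1)))
    stop("degenerate calibration: gray values are constant")
  direction <- sign(sum(sign(dg)))
  bad <- which(sign(dg) != direction)
  if (length(bad))
    stop("step grays are not monotone in thickness; offending step(s): ",
         paste(bad, collapse = ", "),
         " (1 = background-to-first-step transition)")

  ## fit in a centred/scaled gray variable (raw 16-bit cubes are badly
  ## conditioned), then expand back to raw-gray coefficients exactly
  m <- mean(g); s <- stats::sd(g)
  u <- (g - m) / s
  fit <- stats::lm.fit(x = outer(u, 0:3, `^`), y = t)
  a <- fit$coefficients            # t = sum a_k u^k
  ## binomial expansion of ((g - m)/s)^k
  coefficients <- c(
    a[1L] - a[2L] * m / s + a[3L] * m^2 / s^2 - a[4L] * m^3 / s^3,
    a[2L] / s - 2 * a[3L] * m / s^2 + 3 * a[4L] * m^2 / s^3,
    a[3L] / s^2 - 3 * a[4L] * m / s^3,
    a[4L] / s^3)
  names(coefficients) <- paste0("c", 0:3)
  rmse <- sqrt(mean(fit$residuals^2))
  gray_range <- range(g)

  grid <- seq(gray_range[1L], gray_range[2L], length.out = 256L)
  tg <- drop(outer(grid, 0:3, `^`) %*% coefficients)
  slopes <- diff(tg) * direction
  monotone <- all(slopes >= -1e-9 * max(1, diff(range(tg))))
  background_mm <- drop(outer(background_gray, 0:3, `^`) %*% coefficients)

  out <- structure(list(coefficients = coefficients,
                        gray_range = gray_range,
                        fit_residual = rmse,
                        direction = direction,
                        monotone = monotone,
                        background_gray = background_gray,
                        background_mm = background_mm,
                        data = data.frame(gray = g, thickness_mm = t,
                                          fitted_mm = fit$fitted.values
                                            %||% (t - fit$residuals))),
                   class = "keel_calibration")
  if (!monotone)
    warning("fitted calibration curve is not monotone over its gray range")
  if (abs(background_mm) > 0.1)
    warning(sprintf("background maps to %.3f mm Al eq (expected within 0.1 mm of 0)",
                    background_mm))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert gray values to aluminium-equivalent thickness
#'
#' Evaluates the calibration polynomial. Cubic tails are unbounded, so
#' gray values outside the calibrated range are clamped to the range
#' endpoints and flagged rather than extrapolated.
#'
#' @param curve a `"keel_calibration"` from [fit_calibration()].
#' @param gray numeric vector of gray values.
#' @return numeric vector of thicknesses (mm Al eq) with a logical
#'   attribute `"clamped"` marking out-of-range inputs.
#' @export
gray_to_mm_al <- function(curve, gray) {
  stopifnot(inherits(curve, "keel_calibration"), is.numeric(gray))
  lo <- curve$gray_range[1L]; hi <- curve$gray_range[2L]
  clamped <- gray < lo | gray > hi
  g <- pmin(pmax(gray, lo), hi)
  mm <- drop(outer(g, 0:3, `^`) %*% curve$coefficients)
  attr(mm, "clamped") <- clamped
  mm
}

#' @export
predict.keel_calibration <- function(object, newdata, ...) {
  gray <- if (is.data.frame(newdata)) newdata$gray else newdata
  gray_to_mm_al(object, gray)
}

#' @export
coef.keel_calibration <- function(object, ...) object$coefficients

#' @export
residuals.keel_calibration <- function(object, ...) {
  object$data$thickness_mm - object$data$fitted_mm
}

#' @export
print.keel_calibration <- function(x, ...) {
  cat("Step-wedge calibration (cubic, thickness-of-gray)\n")
  cat("  coefficients:", paste(sprintf("%s=%.6g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  gray range: [%.6g, %.6g]  direction: %s\n",
              x$gray_range[1L], x$gray_range[2L],
              if (x$direction > 0) "gray increases with thickness"
              else "gray decreases with thickness"))
  cat(sprintf("  RMS residual: %.3g mm   background -> %.4f mm   monotone: %s\n",
              x$fit_residual, x$background_mm, x$monotone))
  invisible(x)
}

#' @export
plot.keel_calibration <- function(x, ...) {
  grid <- seq(x$gray_range[1L], x$gray_range[2L], length.out = 200L)
  plot(x$data$gray, x$data$thickness_mm, xlab = "gray value",
       ylab = "thickness (mm Al eq)", main = "Step-wedge calibration", ...)
  graphics::lines(grid, gray_to_mm_al(x, grid))
  invisible(x)
}

#' Serialize a calibration report to JSON
#'
#' @param curve a `"keel_calibration"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "keel_calibration"))
  rep <- list(coefficients = as.list(curve$coefficients),
              gray_range = curve$gray_range,
              fit_residual_mm = curve$fit_residual,
              direction = curve$direction,
              monotone = curve$monotone,
              background_gray = curve$background_gray,
              background_mm = curve$background_mm)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration report written by [write_calibration()]
#'
#' @param path JSON file.
#' @return a `"keel_calibration"` object (without the fitted data table).
#' @export
read_calibration <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(rep$coefficients),
                 gray_range = as.numeric(rep$gray_range),
                 fit_residual = rep$fit_residual_mm,
                 direction = rep$direction,
                 monotone = rep$monotone,
                 background_gray = rep$background_gray,
                 background_mm = rep$background_mm,
                 data = NULL),
            class = "keel_calibration")
}
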