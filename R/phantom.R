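#' Detector response models for phantom rendering
#'
#' Maps aluminium-equivalent thickness (mm) to detector gray value. Gray
#' increases monotonically with thickness (positive image) in all
#' variants. Three shapes are available:
#' \describe{
#'   \item{linear}{`g = a + b t`; the default and the shape under which
#'     the cubic calibration is exact.}
#'   \item{cubic}{a monotone response whose *inverse* is an exact
#'     degree-3 polynomial `t(g) = c0 + c1 g + c2 g^2 + c3 g^3`; the
#'     renderer inverts it numerically. This stresses the calibration
#'     while keeping its ground truth inside the cubic model space.}
#'   \item{saturating}{`g = g0 + gmax (1 - exp(-k t))`, an exponential
#'     approach to the detector cap; the cubic calibration can only
#'     approximate it (useful for robustness checks).}
#' }
#'
#' @param type response shape.
#' @param a,b linear intercept/slope (gray, gray per mm).
#' @param inv_coef length-4 coefficients of the inverse cubic
#'   (mm, mm/gray, mm/gray^2, mm/gray^3); must give a monotone
#'   increasing thickness over the used gray range.
#' @param g0,gmax,k saturating-response parameters.
#' @param bit_depth detector bit depth, 8 or 16; gray values are clipped
#'   to `[0, 2^bit_depth - 1]`.
#' @return an object of class `"detector_response"` with element
#'   `forward`, a vectorized function thickness -> gray.
#' @export
detector_response <- function(type = c("linear", "cubic", "saturating"),
                              a = NULL, b = NULL,
                              inv_coef = NULL,
                              g0 = NULL, gmax = NULL, k = NULL,
                              bit_depth = 16L) {
  type <- match.arg(type)
  stopifnot(bit_depth %in% c(8L, 16L))
  gcap <- 2^bit_depth - 1
  forward <- switch(type,
    linear = {
      if (is.null(a)) a <- if (bit_depth == 16L) 2000 else 10
      if (is.null(b)) b <- if (bit_depth == 16L) 12000 else 45
      if (b <= 0) stop("linear response must be increasing (b > 0)")
      local({ a0 <- a; b0 <- b; function(t) a0 + b0 * t })
    },
    cubic = {
      if (is.null(inv_coef))
        inv_coef <- if (bit_depth == 16L)
          c(-0.5, 3e-4, 1e-9, 1e-14) else c(-0.5, 0.028, 3e-5, 1.5e-7)
      stopifnot(length(inv_coef) == 4L)
      tfun <- function(g) inv_coef[1L] + inv_coef[2L] * g +
        inv_coef[3L] * g^2 + inv_coef[4L] * g^3
      dfun <- function(g) inv_coef[2L] + 2 * inv_coef[3L] * g +
        3 * inv_coef[4L] * g^2
      if (any(dfun(seq(0, gcap, length.out = 257L)) <= 0))
        stop("inverse cubic must be monotone increasing over the gray range")
      local({
        tf <- tfun; cap <- gcap
        function(t) vapply(t, function(ti)
          stats::uniroot(function(g) tf(g) - ti, lower = 0, upper = cap,
                         tol = 1e-10)$root, numeric(1L))
      })
    },
    saturating = {
      if (is.null(g0)) g0 <- if (bit_depth == 16L) 1500 else 8
      if (is.null(gmax)) gmax <- if (bit_depth == 16L) 58000 else 230
      if (is.null(k)) k <- 0.35
      if (gmax <= 0 || k <= 0) stop("saturating response must be increasing")
      local({ p0 <- g0; pm <- gmax; kk <- k
              function(t) p0 + pm * (1 - exp(-kk * t)) })
    })
  structure(list(type = type, forward = forward, bit_depth = bit_depth,
                 gray_cap = gcap,
                 params = list(a = a, b = b, inv_coef = inv_coef,
                               g0 = g0, gmax = gmax, k = k)),
            class = "detector_response")
}

#' Ground truth for one phantom radiograph
#'
#' Container of the quantities a phantom is built to embody, so the
#' downstream pipeline (calibration, density, POD, fracture flag) can be
#' checked against known values.
#'
#' @param true_density mean aluminium-equivalent thickness of the keel
#'   region, mm Al eq.
#' @param true_pod deviated-area percentage of the keel (0 when not
#'   deviated); must be positive exactly when `deviated` is `TRUE`.
#' @param deviated logical; is a deviation present?
#' @param fractured 0/1 fracture flag carried into the annotations.
#' @param response a [detector_response()] (or `NULL` for the default
#'   linear 16-bit response).
#' @param noise_sd additive Gaussian noise on gray values, in gray units.
#' @param pixel_spacing physical pixel size, mm/pixel.
#' @param seed integer seed making the phantom reproducible.
#' @return an object of class `"phantom_truth"`.
#' @export
phantom_truth <- function(true_density = 2.0, true_pod = 0, deviated = FALSE,
                          fractured = 0L, response = NULL, noise_sd = 0,
                          pixel_spacing = 0.1, seed = 1L) {
  if (is.null(response)) response <- detector_response("linear")
  stopifnot(inherits(response, "detector_response"))
  if (true_pod < 0 || true_pod > 100) stop("true_pod must lie in [0, 100]")
  if ((true_pod > 0) != isTRUE(deviated))
    stop("true_pod must be positive exactly when deviated = TRUE")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (!fractured %in% c(0L, 1L)) stop("fractured must be 0 or 1")
  if (true_density < 0) stop("true_density must be non-negative")
  structure(list(true_density = true_density, true_pod = true_pod,
                 deviated = isTRUE(deviated), fractured = as.integer(fractured),
                 response = response, noise_sd = noise_sd,
                 pixel_spacing = pixel_spacing, seed = as.integer(seed)),
            class = "phantom_truth")
}

## blade-like keel outline: two smooth arcs joined at the cranial and
## caudal tips, >= 12 vertices, traced clockwise in a y-down frame
keel_outline_polygon <- function(x0, y0, length_px, height_px,
                                 n_side = 14L, squash = 0.8) {
  s <- seq(0, 1, length.out = n_side + 1L)
  xs <- x0 + s * length_px
  top <- cbind(xs, y0 - 0.35 * height_px * sin(pi * s)^squash)
  bot <- cbind(rev(xs[-c(1L, n_side + 1L)]),
               y0 + 0.65 * height_px *
                 sin(pi * rev(s[-c(1L, n_side + 1L)]))^(squash + 0.2))
  rbind(top, bot)
}

## cut the keel with a vertical chord so the caudal piece holds an exact
## shoelace-area fraction; returns the open boundary arc (chord implied)
deviation_arc_for_fraction <- function(keel, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  total <- abs(signed_area(keel))
  xr <- range(keel[, 1L])
  frac_right <- function(cut) {
    cp <- clip_polygon_vertical(keel, cut, keep = "right")
    if (is.null(cp) || nrow(cp) < 3L) return(0)
    abs(signed_area(cp)) / total
  }
  cut <- stats::uniroot(function(c) frac_right(c) - fraction,
                        lower = xr[1L] + 1e-6, upper = xr[2L] - 1e-6,
                        tol = 1e-10)$root
  piece <- clip_polygon_vertical(keel, cut, keep = "right")
  ## the chord is the edge joining the two vertices on the cut line;
  ## rotate so the open polyline starts just after it and ends on it
  on_cut <- which(abs(piece[, 1L] - cut) < 1e-7)
  n <- nrow(piece)
  chord_start <- NULL
  for (i in on_cut) {
    j <- if (i == n) 1L else i + 1L
    if (j %in% on_cut) { chord_start <- i; break }
  }
  if (is.null(chord_start)) {  # cut line grazes a vertex; fall back
    chord_start <- on_cut[1L]
  }
  ord <- ((chord_start) %% n + seq_len(n) - 1L) %% n + 1L
  piece[ord, , drop = FALSE]
}

#' Generate a phantom radiograph with known ground truth
#'
#' Renders a synthetic lateral radiograph: a zero-thickness background,
#' one rectangular block per wedge step at its exact thickness, and a
#' blade-shaped keel region of uniform aluminium-equivalent thickness
#' equal to `truth$true_density`. If `truth$deviated`, a caudal
#' sub-region of the keel whose shoelace-area fraction equals
#' `truth$true_pod / 100` (to within root-finding tolerance) is carried
#' in the annotations as an open deviation outline. Thickness maps to
#' gray through the monotone detector response; when `noise_sd > 0`,
#' Gaussian noise is added and the result is rounded to the integer gray
#' grid, and all values are clipped to the bit range. Identical seeds
#' give bit-identical output.
#'
#' @param wedge_spec a [step_wedge_spec()]; its ROIs are ignored on
#'   input and replaced by the rendered wedge geometry.
#' @param truth a [phantom_truth()].
#' @param width,height image size in pixels.
#' @return list with `image` (numeric matrix, integer-valued grays),
#'   `annotations` (an [annotation_set()]), `truth`, and `wedge_spec`
#'   (the input spec with rendered ROIs attached).
#' @export
generate_phantom <- function(wedge_spec = step_wedge_spec(), truth = phantom_truth(),
                             width = 640L, height = 480L) {
  stopifnot(inherits(wedge_spec, "step_wedge_spec"), inherits(truth, "phantom_truth"))
  width <- as.integer(width); height <- as.integer(height)
  resp <- truth$response
  tt <- wedge_thicknesses(wedge_spec)

  ## layout: keel in the upper two thirds, wedge strip along the bottom
  wedge_top <- round(height * 0.82); wedge_bot <- height - 12L
  margin <- 10L
  step_w <- (width - 2L * margin) %/% (wedge_spec$n_steps + 1L)
  if (step_w < 4L) stop("image too narrow for the wedge")
  step_rois <- vector("list", wedge_spec$n_steps)
  for (i in seq_len(wedge_spec$n_steps)) {
    x0 <- margin + i * step_w
    step_rois[[i]] <- c(xmin = x0 + 1, ymin = wedge_top + 1,
                        xmax = x0 + step_w - 2, ymax = wedge_bot - 1)
  }
  background_roi <- c(xmin = margin, ymin = 2,
                      xmax = margin + step_w - 2, ymax = 20)

  keel <- keel_outline_polygon(x0 = width * 0.12, y0 = height * 0.42,
                               length_px = width * 0.62,
                               height_px = height * 0.38)
  ## wedge/keel overlap guard
  if (max(keel[, 2L]) >= wedge_top)
    stop("keel phantom overlaps the wedge strip")

  thickness <- matrix(0, height, width)
  for (i in seq_len(wedge_spec$n_steps)) {
    r <- step_rois[[i]]
    thickness[(r["ymin"]:r["ymax"]) + 1L, (r["xmin"]:r["xmax"]) + 1L] <- tt[i]
  }
  keel_mask <- polygon_mask(keel, height, width)
  thickness[keel_mask] <- truth$true_density

  dev_outline <- NULL
  if (truth$deviated)
    dev_outline <- deviation_arc_for_fraction(keel, truth$true_pod / 100)

  ## render: few unique thicknesses, so map through the response once each
  uq <- sort(unique(as.vector(thickness)))
  gval <- resp$forward(uq)
  image <- matrix(gval[match(thickness, uq)], height, width)

  set.seed(truth$seed)
  if (truth$noise_sd > 0) {
    ## noisy detectors sample on the integer gray grid; noise-free
    ## phantoms keep exact response values so calibration is exact
    image <- image + stats::rnorm(length(image), sd = truth$noise_sd)
    image <- round(image)
  }
  image <- pmin(pmax(image, 0), resp$gray_cap)

  wedge_spec$step_rois <- step_rois
  wedge_spec$background_roi <- background_roi
  ann <- annotation_set(keel_outline = keel,
                        deviation_outline = dev_outline,
                        exclusion_regions = list(),
                        fracture_flag = truth$fractured,
                        wedge_rois = step_rois,
                        background_roi = background_roi,
                        pixel_spacing = truth$pixel_spacing)
  list(image = image, annotations = ann, truth = truth, wedge_spec = wedge_spec)
}
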