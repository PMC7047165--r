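# Shared fixtures and independent oracles.

# Calibration fitted to exactly linear data g = 200 - 30 t (negative
# image: gray falls with thickness) over the default wedge ladder.
linear_calibration <- function() {
  tt <- wedge_thicknesses(step_wedge_spec())
  fit_calibration(background_gray = 200, step_grays = 200 - 30 * tt,
                  thicknesses = tt)
}

# Six-subject toy survival data: group B (x = 1) at times 2, 4, 6 and
# group A (x = 0) at times 1, 3, 5, all events observed, no ties.
toy_cox_data <- function() {
  data.frame(hen_id = paste0("h", 1:6),
             line = "G11",
             treatment = rep(c("A", "B"), each = 3),
             pen_id = paste0("p", 1:6),
             time = c(1, 3, 5, 2, 4, 6),
             event = 1L)
}

# Independent grid-search maximiser of the Cox partial likelihood for a
# single binary covariate with untied, fully observed event times.
toy_cox_grid_oracle <- function(time, x, grid = seq(-5, 5, by = 0.001)) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  n <- length(time)
  logpl <- vapply(grid, function(beta) {
    eta <- exp(beta * x)
    sum(vapply(seq_len(n), function(i) {
      risk <- time >= time[i]
      beta * x[i] - log(sum(eta[risk]))
    }, numeric(1L)))
  }, numeric(1L))
  grid[which.max(logpl)]
}

# Pixel-counting area oracle: rasterize at subpixel resolution `scale`
# and count covered pixel centres.
raster_area_oracle <- function(poly, scale = 100) {
  p <- poly * scale
  p[, 1] <- p[, 1] - min(p[, 1]) + 2
  p[, 2] <- p[, 2] - min(p[, 2]) + 2
  nr <- ceiling(max(p[, 2])) + 3L
  nc <- ceiling(max(p[, 1])) + 3L
  sum(polygon_mask(p, nr, nc)) / scale^2
}

# Small cohort design used across statistical tests.
small_design <- function(seed, hens = c(C = 3L, E = 3L, S = 3L, SE = 3L),
                         trajectories = default_trajectories(),
                         nonevaluable = 0, death = 0, ...) {
  cohort_design(hens_per_cell = hens, trajectory_params = trajectories,
                nonevaluable_fraction = nonevaluable, death_fraction = death,
                seed = seed, ...)
}

# Two-arm single-line design for hazard-ratio recovery studies.
two_arm_design <- function(seed, hens_per_arm_pen = 250L, hr_s = 0.2) {
  cohort_design(lines = "G11", treatments = c("C", "S"), pens_per_line = 2L,
                hens_per_cell = c(C = hens_per_arm_pen, S = hens_per_arm_pen),
                hr_treatment = c(C = 1, S = hr_s), hr_line = c(G11 = 1),
                nonevaluable_fraction = 0, death_fraction = 0, seed = seed)
}

table2_fixture_path <- function() {
  system.file("extdata", "fracture_prevalence_counts.csv", package = "keelbone",
              mustWork = TRUE)
}
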