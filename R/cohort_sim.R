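#' Lighting schedule used for activity recording
#'
#' Days of recording and lighting hours per day for each sampling
#' period: 14 recording days for periods 1-5, 13 for period 6 and 10
#' for period 7; the photoperiod ramps from 10 h/d early in rearing to
#' 14 h/d in lay.
#'
#' @return data frame with `period`, `days`, `hours_per_day`.
#' @export
lighting_schedule <- function() {
  data.frame(period = 1:7,
             days = c(14L, 14L, 14L, 14L, 14L, 13L, 10L),
             hours_per_day = c(10L, 12L, 14L, 14L, 14L, 14L, 14L))
}

#' Lighting windows for one sampling period
#'
#' One window per recording day, lights on at 06:00.
#'
#' @param period sampling period (1-7).
#' @param schedule a [lighting_schedule()].
#' @param start_date date the period's recording starts.
#' @return data frame with POSIXct `start` and `end` columns.
#' @export
activity_windows <- function(period, schedule = lighting_schedule(),
                             start_date = as.Date("2016-01-04") + (period - 1L) * 49L) {
  row <- schedule[schedule$period == period, ]
  if (nrow(row) != 1L) stop("unknown sampling period: ", period)
  starts <- as.POSIXct(paste(start_date + seq_len(row$days) - 1L, "06:00:00"),
                       tz = "UTC")
  data.frame(start = starts, end = starts + row$hours_per_day * 3600)
}

## group-wise mean trajectory array [line, treatment, period]
trajectory_array <- function(lines, treatments, base_by_line, period_curve,
                             treatment_shift = NULL) {
  n_p <- length(period_curve[[1L]])
  arr <- array(NA_real_, dim = c(length(lines), length(treatments), n_p),
               dimnames = list(lines, treatments, as.character(seq_len(n_p))))
  for (l in lines) for (tr in treatments) {
    curve <- period_curve[[tr]] %||% period_curve[["C"]]
    arr[l, tr, ] <- base_by_line[[l]] + curve +
      (if (is.null(treatment_shift)) 0 else treatment_shift[[tr]] %||% 0)
  }
  arr
}

#' Default group-wise outcome trajectories for simulated cohorts
#'
#' Mean curves per layer line, treatment and sampling period plus pen-,
#' hen- and residual-level variance components for body weight (g),
#' radiographic density (mm Al eq), estradiol-17ss (pg/ml, log-normal),
#' locomotor activity (crossings/h, log-normal) and POD (%, log-normal,
#' deviated hens only). The shapes emulate the study conditions: weight
#' and density rise to a plateau, egg-suppressed groups (S, SE) dip
#' after the third period and then overtake the egg-laying groups in
#' density, estradiol collapses under S and is raised by the E implant,
#' and activity declines in S and SE.
#'
#' @param treatment_effects if `FALSE`, every treatment group follows
#'   the control curve for every outcome — a null configuration for
#'   calibration studies of the treatment tests.
#' @return named list; each element has `mu` (array line x treatment x
#'   period), `sd_pen`, `sd_hen`, `sd_resid`, and `log` (whether the
#'   components act on the log scale).
#' @export
default_trajectories <- function(treatment_effects = TRUE) {
  lines <- c("G11", "WLA"); trts <- c("C", "E", "S", "SE")
  if (!treatment_effects) {
    tp <- default_trajectories(TRUE)
    for (nm in names(tp)) for (tr in trts) tp[[nm]]$mu[, tr, ] <- tp[[nm]]$mu[, "C", ]
    return(tp)
  }
  list(
    weight = list(
      mu = trajectory_array(lines, trts,
        base_by_line = list(G11 = 0, WLA = 150),
        period_curve = list(
          C  = c(1200, 1500, 1700, 1750, 1780, 1800, 1820),
          E  = c(1200, 1500, 1700, 1760, 1790, 1810, 1830),
          S  = c(1200, 1500, 1700, 1550, 1650, 1750, 1800),
          SE = c(1200, 1500, 1720, 1780, 1820, 1850, 1870))),
      sd_pen = 20, sd_hen = 80, sd_resid = 50, log = FALSE),
    density = list(
      mu = trajectory_array(lines, trts,
        base_by_line = list(G11 = 0, WLA = 0.2),
        period_curve = list(
          C  = c(1.2, 1.6, 2.0, 2.1, 2.05, 2.15, 2.2),
          E  = c(1.2, 1.6, 2.0, 2.15, 2.1, 2.2, 2.25),
          S  = c(1.2, 1.6, 2.0, 1.8, 2.2, 2.6, 2.8),
          SE = c(1.2, 1.65, 2.1, 2.3, 2.55, 2.85, 3.0))),
      sd_pen = 0.05, sd_hen = 0.15, sd_resid = 0.1, log = FALSE),
    estradiol = list(
      mu = trajectory_array(lines, trts,
        base_by_line = list(G11 = 0, WLA = 0),
        period_curve = list(
          C  = c(20, 60, 120, 125, 130, 135, 140),
          E  = c(25, 80, 160, 180, 200, 220, 240),
          S  = c(20, 55, 110, 35, 30, 30, 45),
          SE = c(22, 60, 115, 90, 110, 95, 120))),
      sd_pen = 0.05, sd_hen = 0.3, sd_resid = 0.25, log = TRUE),
    activity = list(
      mu = trajectory_array(lines, trts,
        base_by_line = list(G11 = 0.4, WLA = 0),
        period_curve = list(
          C  = c(3.0, 3.1, 3.0, 2.9, 3.0, 2.9, 2.8),
          E  = c(3.0, 3.1, 3.0, 3.0, 2.9, 2.9, 2.8),
          S  = c(3.0, 3.0, 2.5, 2.1, 1.8, 1.5, 1.3),
          SE = c(3.0, 3.1, 2.9, 2.4, 2.0, 1.7, 1.4))),
      sd_pen = 0.05, sd_hen = 0.3, sd_resid = 0.25, log = TRUE),
    pod = list(
      mu = trajectory_array(lines, trts,
        base_by_line = list(G11 = 0, WLA = 1),
        period_curve = list(
          C  = c(4, 5, 6, 7, 8, 9, 10),
          E  = c(4, 5, 6, 7, 8, 9, 10),
          S  = c(5, 7, 9, 10, 11, 12, 13),
          SE = c(4, 5, 6, 7, 8, 9, 10)),
        treatment_shift = NULL),
      sd_pen = 0.05, sd_hen = 0.4, sd_resid = 0.3, log = TRUE))
}

#' Design of a simulated hen cohort
#'
#' Encodes the factorial structure (two layer lines x four treatment
#' groups, hens nested in pens), the discrete per-period fracture and
#' deviation hazards with multiplicative treatment/line factors, the
#' outcome trajectories, and the rates of death and period-wise
#' non-evaluability that exercise the inclusion rules. Defaults mirror
#' the study conditions: 2 pens per line with 19 C, 6 E, 19 S and 6 SE
#' hens each; hazard factors equal to the fitted fracture hazard ratios
#' (E 1.17, S 0.20, SE 0.06, line WLA 1.66).
#'
#' @param lines,treatments factor levels.
#' @param pens_per_line pens per layer line.
#' @param hens_per_cell named vector: hens per treatment within one pen.
#' @param n_periods number of sampling periods.
#' @param period_hazards baseline per-period first-fracture hazards
#'   (control hens of the reference line), each in (0, 1).
#' @param hr_treatment,hr_line multiplicative hazard factors (> 0) for
#'   the fracture process, named by level.
#' @param deviation_hazards baseline per-period first-deviation hazards.
#' @param hr_treatment_dev,hr_line_dev hazard factors for the deviation
#'   process.
#' @param trajectory_params see [default_trajectories()].
#' @param nonevaluable_fraction probability a (hen, period) radiograph
#'   cannot be scored for fractures (missing at random).
#' @param death_fraction probability a hen dies before the end.
#' @param pen_frailty_sd standard deviation of a log-normal pen frailty
#'   multiplying the fracture hazard (0 = none).
#' @param seed integer seed.
#' @return object of class `"cohort_design"`.
#' @export
cohort_design <- function(lines = c("G11", "WLA"),
                          treatments = c("C", "E", "S", "SE"),
                          pens_per_line = 2L,
                          hens_per_cell = c(C = 19L, E = 6L, S = 19L, SE = 6L),
                          n_periods = 7L,
                          period_hazards = c(0.005, 0.005, 0.02, 0.13, 0.18, 0.12, 0.10),
                          hr_treatment = c(C = 1, E = 1.17, S = 0.20, SE = 0.06),
                          hr_line = c(G11 = 1, WLA = 1.66),
                          deviation_hazards = c(0.01, 0.12, 0.22, 0.15, 0.08, 0.06, 0.05),
                          hr_treatment_dev = c(C = 1, E = 1, S = 1, SE = 1),
                          hr_line_dev = c(G11 = 1, WLA = 1),
                          trajectory_params = default_trajectories(),
                          nonevaluable_fraction = 0.05,
                          death_fraction = 0.05,
                          pen_frailty_sd = 0,
                          seed = 1L) {
  stopifnot(length(lines) >= 1L, length(treatments) >= 1L, pens_per_line >= 1L)
  if (!all(treatments %in% names(hens_per_cell)))
    stop("hens_per_cell must name every treatment")
  if (any(hens_per_cell[treatments] < 1L))
    stop("empty design cell: every treatment needs at least 1 hen per pen")
  if (length(period_hazards) != n_periods || length(deviation_hazards) != n_periods)
    stop("need one baseline hazard per period")
  if (any(period_hazards <= 0 | period_hazards >= 1) ||
      any(deviation_hazards <= 0 | deviation_hazards >= 1))
    stop("baseline hazards must lie in (0, 1)")
  for (v in list(hr_treatment, hr_line, hr_treatment_dev, hr_line_dev))
    if (any(v <= 0)) stop("hazard factors must be positive")
  if (!all(treatments %in% names(hr_treatment)) || !all(lines %in% names(hr_line)))
    stop("hazard factors must name every treatment and line")
  stopifnot(nonevaluable_fraction >= 0, nonevaluable_fraction < 1,
            death_fraction >= 0, death_fraction < 1, pen_frailty_sd >= 0)
  structure(list(lines = lines, treatments = treatments,
                 pens_per_line = as.integer(pens_per_line),
                 hens_per_cell = hens_per_cell, n_periods = as.integer(n_periods),
                 period_hazards = period_hazards, hr_treatment = hr_treatment,
                 hr_line = hr_line, deviation_hazards = deviation_hazards,
                 hr_treatment_dev = hr_treatment_dev, hr_line_dev = hr_line_dev,
                 trajectory_params = trajectory_params,
                 nonevaluable_fraction = nonevaluable_fraction,
                 death_fraction = death_fraction,
                 pen_frailty_sd = pen_frailty_sd, seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  n_hens <- length(x$lines) * x$pens_per_line * sum(x$hens_per_cell[x$treatments])
  cat(sprintf("Cohort design: %d hens (%s x %s), %d pens/line, %d periods\n",
              n_hens, paste(x$lines, collapse = "/"),
              paste(x$treatments, collapse = "/"), x$pens_per_line, x$n_periods))
  cat("  fracture hazard factors:",
      paste(sprintf("%s=%.2f", names(x$hr_treatment), x$hr_treatment), collapse = " "),
      "|", paste(sprintf("%s=%.2f", names(x$hr_line), x$hr_line), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a hen cohort with known generative parameters
#'
#' Assigns hens to line/treatment/pen cells, draws the first-fracture
#' and first-deviation periods from discrete proportional-hazards
#' processes (`hazard_p = baseline_p x hr_treatment x hr_line`, times an
#' optional log-normal pen frailty), draws period-wise weight, density,
#' estradiol, activity and POD from the trajectory parameters with pen-
#' and hen-level random intercepts, and marks a configurable fraction of
#' hens dead-before-end and of (hen, period) radiographs non-evaluable
#' for fractures. Identical seeds give identical output.
#'
#' @param design a [cohort_design()].
#' @param include_event_log simulate a transponder registration log
#'   (Poisson stream at each hen's activity rate over the lighting
#'   windows)? Adds realistic bulk; switch off for large statistical
#'   simulations.
#' @return list with `records` (hen-period data frame), `event_log`
#'   (data frame or `NULL`), and `truth` (the per-hen hazard tables and
#'   first-event periods actually drawn).
#' @export
generate_cohort <- function(design = cohort_design(), include_event_log = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_p <- design$n_periods

  ## roster
  hens <- do.call(rbind, lapply(design$lines, function(l) {
    do.call(rbind, lapply(seq_len(design$pens_per_line), function(pen) {
      do.call(rbind, lapply(design$treatments, function(tr) {
        data.frame(line = l, treatment = tr,
                   pen_id = sprintf("%s_p%d", l, pen),
                   n = design$hens_per_cell[[tr]], stringsAsFactors = FALSE)
      }))
    }))
  }))
  hens <- hens[rep(seq_len(nrow(hens)), hens$n), c("line", "treatment", "pen_id")]
  n_hens <- nrow(hens)
  hens$hen_id <- sprintf("h%04d", seq_len(n_hens))
  rownames(hens) <- NULL

  pens <- unique(hens$pen_id)
  frailty <- stats::setNames(
    if (design$pen_frailty_sd > 0)
      exp(stats::rnorm(length(pens), -design$pen_frailty_sd^2 / 2,
                       design$pen_frailty_sd)) else rep(1, length(pens)),
    pens)

  ## per-hen hazard matrices [hen, period]
  mult_f <- design$hr_treatment[hens$treatment] * design$hr_line[hens$line] *
    frailty[hens$pen_id]
  mult_d <- design$hr_treatment_dev[hens$treatment] * design$hr_line_dev[hens$line]
  haz_f <- outer(mult_f, design$period_hazards)
  haz_d <- outer(mult_d, design$deviation_hazards)
  if (any(haz_f >= 1) || any(haz_d >= 1))
    stop("hazard factors push a per-period hazard to 1 or above")

  first_frac <- local({
    out <- rep(Inf, n_hens); alive <- seq_len(n_hens)
    for (p in seq_len(n_p)) {
      if (!length(alive)) break
      hit <- stats::runif(length(alive)) < haz_f[alive, p]
      out[alive[hit]] <- p; alive <- alive[!hit]
    }
    out
  })
  first_dev <- local({
    out <- rep(Inf, n_hens); alive <- seq_len(n_hens)
    for (p in seq_len(n_p)) {
      if (!length(alive)) break
      hit <- stats::runif(length(alive)) < haz_d[alive, p]
      out[alive[hit]] <- p; alive <- alive[!hit]
    }
    out
  })

  alive_to_end <- stats::runif(n_hens) >= design$death_fraction

  ## random intercepts per outcome
  tp <- design$trajectory_params
  b_pen <- lapply(tp, function(o) stats::setNames(
    stats::rnorm(length(pens), 0, o$sd_pen), pens))
  b_hen <- lapply(tp, function(o) stats::rnorm(n_hens, 0, o$sd_hen))

  rec <- hens[rep(seq_len(n_hens), each = n_p),
              c("hen_id", "line", "treatment", "pen_id")]
  rec$period <- rep(seq_len(n_p), times = n_hens)
  rec$alive_to_end <- rep(alive_to_end, each = n_p)
  hid <- rep(seq_len(n_hens), each = n_p)

  draw_outcome <- function(name) {
    o <- tp[[name]]
    mu <- o$mu[cbind(rec$line, rec$treatment, rec$period)]
    eff <- b_pen[[name]][rec$pen_id] + b_hen[[name]][hid] +
      stats::rnorm(nrow(rec), 0, o$sd_resid)
    if (o$log) mu * exp(eff - (o$sd_resid^2) / 2) else mu + eff
  }

  rec$fractured <- as.integer(rec$period >= first_frac[hid])
  rec$deviated <- rec$period >= first_dev[hid]
  rec$weight <- draw_outcome("weight")
  rec$density <- pmax(draw_outcome("density"), 0.05)
  rec$estradiol <- draw_outcome("estradiol")
  rec$activity <- draw_outcome("activity")
  pod <- draw_outcome("pod")
  rec$pod <- ifelse(rec$deviated, pmin(pod, 95), NA_real_)

  if (design$nonevaluable_fraction > 0) {
    ne <- stats::runif(nrow(rec)) < design$nonevaluable_fraction
    rec$fractured[ne] <- NA_integer_
  }
  rownames(rec) <- NULL

  event_log <- NULL
  if (include_event_log) event_log <- simulate_event_log(rec)

  list(records = rec, event_log = event_log,
       truth = list(hens = hens, first_fracture = first_frac,
                    first_deviation = first_dev,
                    fracture_hazards = haz_f, deviation_hazards = haz_d,
                    pen_frailty = frailty))
}

#' Simulate a transponder registration log from hen-period activity
#'
#' Each hen emits a homogeneous Poisson stream of antenna registrations
#' at its period activity rate (crossings/h) over that period's lighting
#' windows; antennae alternate at random between the pen's two loops.
#'
#' @param records hen-period records with an `activity` column.
#' @param schedule a [lighting_schedule()].
#' @return data frame with `hen_id`, `antenna_id`, `timestamp`, sorted
#'   by timestamp within period.
#' @export
simulate_event_log <- function(records, schedule = lighting_schedule()) {
  stopifnot(all(c("hen_id", "pen_id", "period", "activity") %in% names(records)))
  logs <- list()
  for (p in sort(unique(records$period))) {
    win <- activity_windows(p, schedule)
    n_days <- nrow(win)
    day_h <- as.numeric(difftime(win$end[1L], win$start[1L], units = "hours"))
    hours <- n_days * day_h
    sub <- records[records$period == p & !is.na(records$activity), ]
    counts <- stats::rpois(nrow(sub), sub$activity * hours)
    tot <- sum(counts)
    if (tot == 0L) next
    idx <- rep(seq_len(nrow(sub)), counts)
    day <- sample.int(n_days, tot, replace = TRUE)
    sec <- stats::runif(tot, 0, day_h * 3600)
    ts <- win$start[day] + sec
    ord <- order(ts)
    logs[[length(logs) + 1L]] <- data.frame(
      hen_id = sub$hen_id[idx][ord],
      antenna_id = paste0(sub$pen_id[idx][ord], "_a",
                          sample(1:2, tot, replace = TRUE)[ord]),
      timestamp = ts[ord], stringsAsFactors = FALSE)
  }
  if (!length(logs))
    return(data.frame(hen_id = character(), antenna_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}
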