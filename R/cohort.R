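#' Sampling schedule of the longitudinal design
#'
#' Seven sampling periods spread over weeks 12-62 of age. Each period is
#' a four-week window (three weeks for period 7) holding the weighings,
#' blood samplings, one radiograph and the activity recording; the
#' radiograph weeks are 13, 20, 27, 33, 40, 50 and 61.
#'
#' @return list with `radiograph_week` (named by period) and `spans`, a
#'   data frame of period week ranges.
#' @export
sampling_schedule <- function() {
  list(radiograph_week = stats::setNames(c(13L, 20L, 27L, 33L, 40L, 50L, 61L), 1:7),
       spans = data.frame(period = 1:7,
                          week_from = c(12L, 19L, 26L, 32L, 39L, 49L, 60L),
                          week_to   = c(15L, 22L, 29L, 35L, 42L, 52L, 62L)))
}

#' Map a week of age to its sampling period
#'
#' @param week_of_age integer week.
#' @param schedule a [sampling_schedule()].
#' @return the period index (1-7).
#' @export
#' @examples
#' period_of_week(13)  # 1
#' period_of_week(61)  # 7
period_of_week <- function(week_of_age, schedule = sampling_schedule()) {
  stopifnot(length(week_of_age) == 1L, is.finite(week_of_age))
  sp <- schedule$spans
  hit <- which(sp$week_from <= week_of_age & week_of_age <= sp$week_to)
  if (length(hit) != 1L)
    stop("week ", week_of_age, " falls outside every sampling period")
  sp$period[hit]
}

#' Mean of repeated measurements within a sampling period
#'
#' Arithmetic mean ignoring missing entries; used for body weight
#' (2-3 weighings per period) and for averaging assay duplicates and
#' day values.
#'
#' @param values numeric vector, possibly with `NA`s.
#' @return the mean, or `NA` if every value is missing.
#' @export
period_mean <- function(values) {
  stopifnot(is.numeric(values))
  if (all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Intra- and inter-assay coefficients of variation
#'
#' Every plasma sample is measured in duplicate: the per-pair CV is
#' `100 * sd / mean` (sample sd, n-1 denominator) and the intra-assay CV
#' is the mean of all per-pair CVs. A pool plasma sample run on every
#' kit gives the inter-assay CV as `100 * sd / mean` across kits.
#'
#' @param pairs duplicates as a 2-column matrix/data frame or a list of
#'   length-2 vectors; all values positive.
#' @param pool_values the pool sample's value on each kit (>= 2 kits).
#' @return list with `intra_cv` and `inter_cv`, both in percent.
#' @export
#' @examples
#' assay_cv(rbind(c(100, 102)), c(10, 10, 10))
assay_cv <- function(pairs, pool_values) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("each duplicate pair must hold exactly 2 values")
  if (anyNA(pairs) || any(pairs <= 0)) stop("duplicate values must be positive")
  pool_values <- as.numeric(pool_values)
  if (length(pool_values) < 2L) stop("need pool values from at least 2 kits")
  if (anyNA(pool_values) || any(pool_values <= 0)) stop("pool values must be positive")
  per_pair <- apply(pairs, 1L, function(v) 100 * stats::sd(v) / mean(v))
  list(intra_cv = mean(per_pair),
       inter_cv = 100 * stats::sd(pool_values) / mean(pool_values))
}

#' Read a transponder registration log
#'
#' ASCII lines of the form `hen_id<TAB>antenna_id<TAB>ISO-8601 timestamp`.
#'
#' @param path log file.
#' @param tz timezone for timestamp parsing.
#' @return data frame with columns `hen_id`, `antenna_id`, `timestamp`
#'   (POSIXct).
#' @export
read_event_log <- function(path, tz = "UTC") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed event-log line ", bad[1L], ": ", lines[bad[1L]])
  ts <- as.POSIXct(vapply(parts, `[`, "", 3L), tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("malformed timestamp on event-log line ", bad[1L], ": ", lines[bad[1L]])
  }
  data.frame(hen_id = vapply(parts, `[`, "", 1L),
             antenna_id = vapply(parts, `[`, "", 2L),
             timestamp = ts)
}

#' Write a transponder registration log
#'
#' @param log data frame as returned by [read_event_log()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(all(c("hen_id", "antenna_id", "timestamp") %in% names(log)))
  lines <- sprintf("%s\t%s\t%s", log$hen_id, log$antenna_id,
                   format(log$timestamp, "%Y-%m-%dT%H:%M:%S"))
  writeLines(lines, path)
  invisible(path)
}

#' Locomotor activity as antenna crossings per lighting hour
#'
#' Counts one hen's registrations whose timestamps fall inside the
#' lighting windows and divides by the total window duration in hours.
#'
#' @param event_log data frame from [read_event_log()] (or a path to a
#'   log file).
#' @param hen_id the hen.
#' @param lighting_windows data frame with POSIXct columns `start` and
#'   `end`; windows must not overlap.
#' @return crossings per hour.
#' @export
activity_rate <- function(event_log, hen_id, lighting_windows) {
  if (is.character(event_log) && length(event_log) == 1L)
    event_log <- read_event_log(event_log)
  stopifnot(all(c("start", "end") %in% names(lighting_windows)))
  w <- lighting_windows[order(lighting_windows$start), , drop = FALSE]
  if (any(w$end <= w$start)) stop("each lighting window must have end > start")
  if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)]))
    stop("lighting windows overlap")
  hours <- sum(as.numeric(difftime(w$end, w$start, units = "hours")))
  if (hours <= 0) stop("total lighting time is zero")
  ts <- event_log$timestamp[event_log$hen_id == hen_id]
  if (!length(ts)) return(0)
  inside <- vapply(ts, function(t) any(w$start <= t & t < w$end), logical(1L))
  sum(inside) / hours
}

#' Outcome prevalence per line, treatment and sampling period
#'
#' For each design cell and period: the number of hens scored positive
#' for the outcome, the number evaluable (radiographs that could not be
#' scored are excluded from the denominator), and the percentage rounded
#' to 2 decimals (`NA` when no hen was evaluable).
#'
#' @param records hen-period data frame (see [generate_cohort()] for the
#'   column contract; minimally `hen_id`, `line`, `treatment`, `period`
#'   and the outcome column).
#' @param outcome `"fracture"` (column `fractured`, 0/1/NA) or
#'   `"deviation"` (column `deviated`, logical/0/1/NA).
#' @return data frame with `line`, `treatment`, `period`, `cases`,
#'   `evaluable`, `percent`.
#' @export
prevalence_table <- function(records, outcome = c("fracture", "deviation")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "fracture") "fractured" else "deviated"
  stopifnot(is.data.frame(records),
            all(c("line", "treatment", "period", col) %in% names(records)))
  y <- as.integer(records[[col]])
  key <- list(line = records$line, treatment = records$treatment,
              period = records$period)
  cases <- stats::aggregate(list(cases = y), key,
                            function(v) sum(v == 1L, na.rm = TRUE), drop = FALSE)
  evals <- stats::aggregate(list(evaluable = y), key,
                            function(v) sum(!is.na(v)), drop = FALSE)
  out <- merge(cases, evals, sort = FALSE)
  out$cases[is.na(out$cases)] <- 0L
  out$evaluable[is.na(out$evaluable)] <- 0L
  out$percent <- ifelse(out$evaluable > 0L,
                        round(100 * out$cases / out$evaluable, 2L), NA_real_)
  out <- out[order(out$line, out$treatment, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a prevalence-count table into per-hen records
#'
#' Builds a minimal hen-period record set whose prevalence table
#' reproduces a given table of cases/evaluable counts per (line,
#' treatment, period) cell — useful for checking the prevalence
#' machinery against published summary tables. Evaluability and
#' positivity flags are assigned to the lowest-numbered hens of each
#' cell, and fracture scores are not forced to be monotone over periods.
#'
#' @param counts data frame with columns `line`, `treatment`, `period`,
#'   `cases`, `evaluable`.
#' @param outcome which outcome column to populate.
#' @return a hen-period records data frame.
#' @export
cohort_from_counts <- function(counts, outcome = c("fracture", "deviation")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "fracture") "fractured" else "deviated"
  stopifnot(all(c("line", "treatment", "period", "cases", "evaluable") %in% names(counts)))
  if (any(counts$cases > counts$evaluable))
    stop("cases cannot exceed evaluable hens")
  cells <- unique(counts[c("line", "treatment")])
  recs <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- counts[counts$line == cells$line[i] & counts$treatment == cells$treatment[i], ]
    n_hens <- max(sub$evaluable, 1L)
    for (p in sub$period) {
      row <- sub[sub$period == p, ]
      val <- rep(NA_integer_, n_hens)
      if (row$evaluable > 0L) {
        val[seq_len(row$evaluable)] <- 0L
        if (row$cases > 0L) val[seq_len(row$cases)] <- 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        hen_id = sprintf("%s_%s_%03d", cells$line[i], cells$treatment[i], seq_len(n_hens)),
        line = cells$line[i], treatment = cells$treatment[i],
        pen_id = paste0(cells$line[i], "_p1"), period = p,
        alive_to_end = TRUE, stringsAsFactors = FALSE)
      recs[[length(recs)]][[col]] <- val
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Build the time-to-first-damage survival table
#'
#' One row per included hen with the period of first damage. Hens that
#' did not live until the end of the study are dropped; for each
#' outcome, hens whose radiographs could not consistently be scored for
#' that outcome (any `NA` flag) are dropped too. The first period scored
#' positive defines the event regardless of later scores; hens never
#' scored positive are censored at period 7.
#'
#' @param records hen-period data frame.
#' @param outcome `"fracture"` or `"deviation"`.
#' @param n_periods final period (censoring time).
#' @return data frame of class `"survival_table"`: `hen_id`, `line`,
#'   `treatment`, `pen_id`, `time`, `event`.
#' @export
survival_dataset <- function(records, outcome = c("fracture", "deviation"),
                             n_periods = 7L) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "fracture") "fractured" else "deviated"
  stopifnot(is.data.frame(records),
            all(c("hen_id", "line", "treatment", "pen_id", "period", col) %in% names(records)))
  if (!"alive_to_end" %in% names(records)) records$alive_to_end <- TRUE
  rows <- lapply(split(records, records$hen_id), function(h) {
    if (!all(h$alive_to_end)) return(NULL)
    h <- h[order(h$period), , drop = FALSE]
    y <- as.integer(h[[col]])
    if (anyNA(y)) return(NULL)       # not consistently evaluable
    first <- which(y == 1L)
    data.frame(hen_id = h$hen_id[1L], line = h$line[1L],
               treatment = h$treatment[1L], pen_id = h$pen_id[1L],
               time = if (length(first)) h$period[first[1L]] else as.integer(n_periods),
               event = as.integer(length(first) > 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) out <- data.frame(hen_id = character(), line = character(),
                                      treatment = character(), pen_id = character(),
                                      time = integer(), event = integer())
  rownames(out) <- NULL
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Write / read a hen-period cohort table
#'
#' Plain CSV, one row per hen and period; round-trips exactly.
#'
#' @param records hen-period data frame.
#' @param path CSV file.
#' @return `path` invisibly (write) / the records (read).
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("alive_to_end" %in% names(out)) out$alive_to_end <- as.logical(out$alive_to_end)
  if ("deviated" %in% names(out)) out$deviated <- as.logical(out$deviated)
  out
}
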