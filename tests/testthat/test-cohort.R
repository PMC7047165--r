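test_that("weeks of age map to their sampling period", {
  expect_equal(period_of_week(13), 1L)
  expect_equal(period_of_week(61), 7L)
  expect_equal(period_of_week(40), 5L)
  ## every radiograph week falls in its own period
  sch <- sampling_schedule()
  for (p in 1:7) expect_equal(period_of_week(sch$radiograph_week[[p]]), p)
  expect_error(period_of_week(5), "outside")
  expect_error(period_of_week(17), "outside")
})

test_that("period means average repeated measurements, ignoring gaps", {
  expect_equal(period_mean(c(1800, 1850, 1825)), 1825)
  expect_equal(period_mean(c(40, 44)), 42)               # assay duplicate
  expect_equal(period_mean(c(42, 38, 40)), 40)           # day values
  expect_equal(period_mean(c(42, NA, 40)), 41)
  expect_true(is.na(period_mean(c(NA_real_, NA_real_))))
})

test_that("assay CVs follow the duplicate / pool definitions", {
  cv <- assay_cv(rbind(c(100, 102)), c(10, 11, 10.5))
  expect_equal(cv$intra_cv, 100 * stats::sd(c(100, 102)) / 101)  # 1.400%
  expect_equal(round(cv$intra_cv, 3), 1.400)
  expect_equal(assay_cv(rbind(c(50, 50), c(80, 80)), c(9, 9, 9))$intra_cv, 0)
  expect_equal(assay_cv(rbind(c(50, 52)), c(10, 10, 10))$inter_cv, 0)
  expect_error(assay_cv(rbind(c(100, -1)), c(10, 10)), "positive")
  expect_error(assay_cv(rbind(c(100, 101)), 10), "at least 2")
})

test_that("activity rates count registrations per lighting hour", {
  days <- as.Date("2016-03-01") + 0:9
  win <- data.frame(start = as.POSIXct(paste(days, "06:00:00"), tz = "UTC"))
  win$end <- win$start + 10 * 3600                       # 10 days x 10 h
  set.seed(1)
  ts <- sample(win$start, 280, replace = TRUE) + stats::runif(280, 0, 10 * 3600 - 1)
  log <- data.frame(hen_id = "h1", antenna_id = "p1_a1", timestamp = ts)
  expect_equal(activity_rate(log, "h1", win), 2.8)
  expect_equal(activity_rate(log, "h2", win), 0)
  ## registrations outside the windows do not count
  log2 <- rbind(log, data.frame(hen_id = "h1", antenna_id = "p1_a1",
                                timestamp = win$start[1L] - 3600))
  expect_equal(activity_rate(log2, "h1", win), 2.8)
  expect_error(activity_rate(log, "h1", data.frame(start = win$start[1L],
                                                   end = win$start[1L])),
               "end > start")
  over <- data.frame(start = win$start[1:2] - c(0, 3600 * 20), end = win$end[1:2])
  expect_error(activity_rate(log, "h1", over), "overlap")
})

test_that("event logs round-trip and malformed lines are located", {
  log <- data.frame(hen_id = c("h1", "h2"), antenna_id = c("p1_a1", "p1_a2"),
                    timestamp = as.POSIXct(c("2016-03-01 06:30:00",
                                             "2016-03-01 07:00:00"), tz = "UTC"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(back$hen_id, log$hen_id)
  expect_equal(back$timestamp, log$timestamp)

  writeLines(c("h1\tp1_a1\t2016-03-01T06:30:00", "h2 only-two-fields"), path)
  expect_error(read_event_log(path), "line 2")
})

test_that("a Poisson registration stream recovers its rate", {
  rec <- data.frame(hen_id = "h1", line = "G11", treatment = "C",
                    pen_id = "G11_p1", period = 5L, activity = 3.0)
  set.seed(7)
  log <- simulate_event_log(rec)
  win <- activity_windows(5L)
  hours <- nrow(win) * 14
  est <- activity_rate(log, "h1", win)
  expect_lt(abs(est - 3.0), 3 * sqrt(3.0 / hours))
})

test_that("prevalence tables reproduce a published count table", {
  counts <- utils::read.csv(table2_fixture_path())
  rec <- cohort_from_counts(counts, "fracture")
  tab <- prevalence_table(rec, "fracture")
  merged <- merge(tab, counts, by = c("line", "treatment", "period"))
  expect_equal(nrow(merged), nrow(counts))
  expect_equal(merged$cases.x, merged$cases.y)
  expect_equal(merged$evaluable.x, merged$evaluable.y)

  pick <- function(l, tr, p) tab$percent[tab$line == l & tab$treatment == tr &
                                           tab$period == p]
  expect_equal(pick("G11", "C", 7), 43.48)
  expect_equal(pick("WLA", "C", 7), 76.92)
  expect_equal(pick("WLA", "C", 5), 63.89)
  expect_equal(pick("G11", "C", 4), 12.90)
  expect_equal(pick("G11", "C", 1), 0)
  expect_true(is.na(pick("G11", "S", 7)))   # 0 evaluable -> n.a.
})

test_that("prevalence counting is conservative", {
  co <- generate_cohort(small_design(31, nonevaluable = 0.1), include_event_log = FALSE)
  tab <- prevalence_table(co$records, "fracture")
  for (i in seq_len(nrow(tab))) {
    sub <- co$records[co$records$line == tab$line[i] &
                      co$records$treatment == tab$treatment[i] &
                      co$records$period == tab$period[i], ]
    expect_equal(tab$cases[i] + sum(sub$fractured == 0L, na.rm = TRUE),
                 tab$evaluable[i])
  }
})

test_that("survival datasets apply first-event and inclusion rules", {
  base <- data.frame(hen_id = "h1", line = "G11", treatment = "C",
                     pen_id = "G11_p1", period = 1:7, alive_to_end = TRUE)
  r1 <- base; r1$fractured <- c(0, 0, 0, 1, 1, 1, 1)
  s1 <- survival_dataset(r1, "fracture")
  expect_equal(s1$time, 4L); expect_equal(s1$event, 1L)

  r2 <- base; r2$fractured <- rep(0L, 7)
  s2 <- survival_dataset(r2, "fracture")
  expect_equal(s2$time, 7L); expect_equal(s2$event, 0L)

  ## first occurrence counts even if later scores revert to 0
  r3 <- base; r3$fractured <- c(0, 0, 1, 0, 0, 1, 0)
  s3 <- survival_dataset(r3, "fracture")
  expect_equal(s3$time, 3L); expect_equal(s3$event, 1L)

  r4 <- base; r4$fractured <- rep(0L, 7); r4$alive_to_end <- FALSE
  expect_equal(nrow(survival_dataset(r4, "fracture")), 0L)

  ## unknown fracture flags drop the hen from the fracture analysis only
  r5 <- base; r5$fractured <- c(0, NA, 0, 1, 1, 1, 1)
  r5$deviated <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_equal(nrow(survival_dataset(r5, "fracture")), 0L)
  s5 <- survival_dataset(r5, "deviation")
  expect_equal(s5$time, 3L); expect_equal(s5$event, 1L)
})

test_that("Kaplan-Meier survival matches cumulative first-event proportions", {
  co <- generate_cohort(small_design(17, hens = c(C = 10L, E = 10L, S = 10L, SE = 10L)),
                        include_event_log = FALSE)
  st <- survival_dataset(co$records, "fracture")
  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = st)
  km_s <- stats::setNames(summary(km, times = 1:7, extend = TRUE)$surv, 1:7)
  first <- tapply(st$event == 1L, st$time, sum)
  cum <- cumsum(stats::setNames(rep(0L, 7), 1:7) + replace(rep(0, 7), as.integer(names(first)), first))
  expect_equal(unname(km_s), unname(1 - cum / nrow(st)), tolerance = 1e-10)
})

test_that("cohort CSVs round-trip records exactly", {
  co <- generate_cohort(small_design(23, nonevaluable = 0.1, death = 0.1),
                        include_event_log = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co$records, path)
  back <- read_cohort_csv(path)
  expect_equal(back, co$records, tolerance = 1e-12)
})
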