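test_that("hazard ratios convert to percent risk changes", {
  expect_equal(hr_to_percent(0.20)$percent_rounded, 80L)
  expect_equal(hr_to_percent(0.20)$direction, "reduced")
  expect_equal(hr_to_percent(1.66)$percent_rounded, 66L)
  expect_equal(hr_to_percent(1.66)$direction, "increased")
  expect_equal(hr_to_percent(1)$percent_rounded, 0L)
  expect_equal(hr_to_percent(1)$direction, "unchanged")
  expect_equal(hr_to_percent(0.25)$percent, 75)
  expect_error(hr_to_percent(0), "positive")
  expect_error(hr_to_percent(-1), "positive")
})

test_that("percent change is antitone in HR below 1 and monotone above", {
  betas <- seq(-2, -0.1, by = 0.1)
  red <- hr_to_percent(exp(betas))$percent
  expect_true(all(diff(red) < 0))      # less negative coef -> smaller reduction
  betas <- seq(0.1, 2, by = 0.1)
  inc <- hr_to_percent(exp(betas))$percent
  expect_true(all(diff(inc) > 0))
})

test_that("the Cox coefficient matches a grid-search partial-likelihood oracle", {
  toy <- toy_cox_data()
  fit <- fit_cox(toy, terms = "treatment", pen_effect = "cluster")
  beta_hat <- fit$coefficients$coef[fit$coefficients$term == "treatmentB"]
  beta_grid <- toy_cox_grid_oracle(toy$time, as.integer(toy$treatment == "B"))
  expect_lt(abs(beta_hat - beta_grid), 1e-3)
})

test_that("Cox fits are invariant to monotone relabelling of event times", {
  co <- generate_cohort(small_design(21, hens = c(C = 12L, E = 6L, S = 12L, SE = 6L)),
                        include_event_log = FALSE)
  st <- survival_dataset(co$records, "fracture")
  weeks <- sampling_schedule()$radiograph_week
  st_weeks <- st
  st_weeks$time <- unname(weeks[as.character(st$time)])
  f1 <- suppressWarnings(fit_cox(st, terms = c("treatment", "line")))
  f2 <- suppressWarnings(fit_cox(st_weeks, terms = c("treatment", "line")))
  expect_equal(f1$coefficients$coef, f2$coefficients$coef, tolerance = 1e-8)
  expect_equal(f1$wald$chisq, f2$wald$chisq, tolerance = 1e-6)
})

test_that("Cox errors and separation flags fire", {
  toy <- toy_cox_data()
  toy$event <- 0L
  expect_error(fit_cox(toy, terms = "treatment"), "no events")

  ## a treatment level with no events at all is flagged as unbounded
  co <- generate_cohort(cohort_design(seed = 3), include_event_log = FALSE)
  st <- survival_dataset(co$records, "fracture")
  expect_true(any(st$event == 1L))
  fit <- suppressWarnings(fit_cox(st))
  if (!any(st$event[st$treatment == "SE"] == 1L))
    expect_true("treatmentSE" %in% fit$separation)
})

test_that("frailty and cluster pen effects give the same point-estimate scale", {
  co <- generate_cohort(small_design(29, hens = c(C = 15L, E = 6L, S = 15L, SE = 6L)),
                        include_event_log = FALSE)
  st <- survival_dataset(co$records, "fracture")
  f1 <- suppressWarnings(fit_cox(st, pen_effect = "frailty"))
  f2 <- suppressWarnings(fit_cox(st, pen_effect = "cluster"))
  common <- intersect(f1$coefficients$term, f2$coefficients$term)
  expect_equal(f1$coefficients$coef[match(common, f1$coefficients$term)],
               f2$coefficients$coef[match(common, f2$coefficients$term)],
               tolerance = 0.2)
})

test_that("the OLS degenerate case equals lm on the identical model", {
  co <- generate_cohort(small_design(41), include_event_log = FALSE)
  fit <- fit_longitudinal(co$records, "weight", random = "none")
  d <- co$records
  ref <- stats::lm(weight ~ factor(line) * factor(treatment) * factor(period),
                   data = d)
  expect_equal(unname(fit$fixed), unname(stats::coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$varcomp[c("pen", "hen_in_pen")]), c(0, 0))
})

test_that("noise-free simulated fixed effects are recovered exactly", {
  tp <- default_trajectories()
  for (nm in names(tp)) { tp[[nm]]$sd_pen <- 0; tp[[nm]]$sd_hen <- 0; tp[[nm]]$sd_resid <- 0 }
  co <- generate_cohort(small_design(8, trajectories = tp), include_event_log = FALSE)
  ## a zero-residual fit trips lm's "essentially perfect fit" caution
  fit <- suppressWarnings(fit_longitudinal(co$records, "weight", random = "none"))
  mu <- tp$weight$mu
  pred <- stats::predict(fit$model)
  d <- co$records
  truth <- mu[cbind(d$line, d$treatment, d$period)]
  expect_lt(max(abs(pred - truth)), 1e-6)
})

test_that("the mixed model recovers structure and flags interactions", {
  co <- generate_cohort(small_design(55, hens = c(C = 8L, E = 8L, S = 8L, SE = 8L)),
                        include_event_log = FALSE)
  fit <- fit_longitudinal(co$records, "weight")
  expect_s3_class(fit, "kbd_lmm")
  expect_true(all(fit$varcomp >= 0))
  expect_true(all(c("line", "treatment", "period", "line:treatment:period")
                  %in% fit$anova$term))
  ## strong built-in treatment x period structure must be detected
  expect_lt(fit$anova$p[fit$anova$term == "treatment:period"], 0.01)

  ## log-transformed outcomes reject non-positive values
  bad <- co$records
  bad$estradiol[1L] <- -1
  expect_error(fit_longitudinal(bad, "estradiol"), "non-positive")
})

test_that("POD models use deviated hens in periods 3-7 only", {
  co <- generate_cohort(small_design(61, hens = c(C = 10L, E = 10L, S = 10L, SE = 10L)),
                        include_event_log = FALSE)
  fit <- fit_longitudinal(co$records, "pod")
  expect_equal(fit$transform, "log")
  expect_equal(fit$n, sum(co$records$deviated & co$records$period >= 3 &
                            !is.na(co$records$pod)))
})

test_that("empty design cells are reported by name", {
  co <- generate_cohort(small_design(71), include_event_log = FALSE)
  r <- co$records[!(co$records$treatment == "SE" & co$records$period == 4L), ]
  expect_error(fit_longitudinal(r, "weight"), "empty design cell.*SE.*4")
})

test_that("hen-level variance dominating pen-level is recovered", {
  tp <- default_trajectories()
  tp$weight$sd_pen <- 30; tp$weight$sd_hen <- 60   # 4x the variance
  ok <- 0L
  for (s in 1:20) {
    co <- generate_cohort(small_design(100 + s, hens = c(C = 8L, E = 8L, S = 8L, SE = 8L),
                                       trajectories = tp, pens_per_line = 3L),
                          include_event_log = FALSE)
    fit <- fit_longitudinal(co$records, "weight")
    if (fit$varcomp["hen_in_pen"] > fit$varcomp["pen"]) ok <- ok + 1L
  }
  expect_gte(ok, 16L)
})
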