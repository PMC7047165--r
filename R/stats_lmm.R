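#' Longitudinal mixed model for a period-wise outcome
#'
#' Gaussian linear mixed model on a (possibly log-transformed) outcome
#' with layer line, treatment, sampling period and all their two- and
#' three-way interactions as fixed effects and hen nested in pen as
#' random intercepts, estimated by REML. No model simplification is
#' performed: marginal (conditional-on-all-other-terms) F tests are read
#' from the full model. POD is analysed on deviated hens only and, with
#' deviations scarce early in life, restricted to sampling periods 3-7.
#'
#' Denominator degrees of freedom follow the containment convention of
#' [nlme::lme()] (the innermost grouping level at which each term
#' varies), which is reported in the output.
#'
#' @param records hen-period data frame (see [generate_cohort()]).
#' @param outcome one of `"weight"`, `"density"`, `"pod"`,
#'   `"estradiol"`, `"activity"`.
#' @param transform `"auto"` (log for POD, estradiol and activity; none
#'   for weight and density), `"none"` or `"log"`.
#' @param random `"hen_in_pen"` (the study design) or `"none"`
#'   (ordinary least squares on the identical fixed-effects model, the
#'   degenerate case with both variance components at zero).
#' @param periods periods to include; defaults to 3-7 for POD and all
#'   periods otherwise.
#' @return object of class `"kbd_lmm"`: `fixed` (coefficients),
#'   `varcomp` (pen, hen-in-pen, residual variances), `anova` (marginal
#'   F table), `transform`, `highest_significant_interaction` (at
#'   alpha = 0.05; `NA` if none), `df_method`, `n`, and the fitted
#'   `model`.
#' @export
fit_longitudinal <- function(records,
                             outcome = c("weight", "density", "pod",
                                         "estradiol", "activity"),
                             transform = c("auto", "none", "log"),
                             random = c("hen_in_pen", "none"),
                             periods = NULL) {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  random <- match.arg(random)
  if (transform == "auto")
    transform <- if (outcome %in% c("pod", "estradiol", "activity")) "log" else "none"
  stopifnot(is.data.frame(records),
            all(c("hen_id", "line", "treatment", "pen_id", "period", outcome)
                %in% names(records)))

  d <- records
  if (outcome == "pod") {
    if (is.null(periods)) periods <- 3:7
    if ("deviated" %in% names(d)) d <- d[!is.na(d$deviated) & d$deviated, , drop = FALSE]
  }
  if (!is.null(periods)) d <- d[d$period %in% periods, , drop = FALSE]
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  if (length(unique(d$period)) < 2L)
    stop("outcome must be observed in at least 2 sampling periods")

  y <- d[[outcome]]
  if (transform == "log") {
    if (any(y <= 0))
      stop("log transform requested but ", outcome, " has non-positive values")
    y <- log(y)
  }
  dat <- data.frame(y = y,
                    line = factor(d$line), treatment = factor(d$treatment),
                    period = factor(d$period),
                    pen_id = factor(d$pen_id), hen_id = factor(d$hen_id))

  ## a singular design (an empty line x treatment x period cell) is not
  ## estimable with the full interaction; name the first offending cell
  tab <- table(dat$line, dat$treatment, dat$period)
  if (any(tab == 0L)) {
    idx <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: line %s, treatment %s, period %s",
                 dimnames(tab)[[1L]][idx[1L]], dimnames(tab)[[2L]][idx[2L]],
                 dimnames(tab)[[3L]][idx[3L]]))
  }

  fml <- y ~ line * treatment * period
  if (random == "hen_in_pen") {
    fit <- nlme::lme(fixed = fml, random = ~ 1 | pen_id / hen_id, data = dat,
                     method = "REML")
    an <- stats::anova(fit, type = "marginal")
    an <- data.frame(term = rownames(an), num_df = an$numDF, den_df = an$denDF,
                     F = an[["F-value"]], p = an[["p-value"]])
    ## VarCorr rows for nested grouping: pen header, pen (Intercept),
    ## hen header, hen (Intercept), Residual; numeric rows survive coercion
    vc <- nlme::VarCorr(fit)
    v <- suppressWarnings(as.numeric(vc[, "Variance"]))
    v <- v[!is.na(v)]
    varcomp <- c(pen = v[1L], hen_in_pen = v[2L], residual = v[3L])
    fixed <- nlme::fixef(fit)
    df_method <- "containment (nlme::lme default)"
  } else {
    fit <- stats::lm(fml, data = dat)
    fixed <- stats::coef(fit)
    an <- marginal_f_lm(fit)
    varcomp <- c(pen = 0, hen_in_pen = 0,
                 residual = sum(stats::residuals(fit)^2) / fit$df.residual)
    df_method <- "residual (ordinary least squares)"
  }

  inter <- c("line:treatment:period", "line:treatment", "line:period",
             "treatment:period")
  sig <- inter[inter %in% an$term & an$p[match(inter, an$term)] < 0.05]
  structure(list(fixed = fixed, varcomp = varcomp, anova = an,
                 transform = transform, outcome = outcome,
                 highest_significant_interaction = if (length(sig)) sig[1L] else NA_character_,
                 df_method = df_method, n = nrow(dat), random = random,
                 model = fit),
            class = "kbd_lmm")
}

## marginal (type-III-style) Wald F tests for an lm fit: each term's
## coefficient block tested given all other terms, mirroring
## anova(lme_fit, type = "marginal")
marginal_f_lm <- function(fit) {
  asg <- fit$assign
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  keep <- !is.na(b)
  terms_lab <- c("(Intercept)", attr(stats::terms(fit), "term.labels"))
  df_res <- fit$df.residual
  rows <- lapply(unique(asg), function(a) {
    idx <- which(asg == a & keep)
    if (!length(idx)) return(NULL)
    bb <- b[idx]
    Fv <- drop(t(bb) %*% solve(V[idx, idx, drop = FALSE], bb)) / length(idx)
    data.frame(term = terms_lab[a + 1L], num_df = length(idx), den_df = df_res,
               F = Fv, p = stats::pf(Fv, length(idx), df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.kbd_lmm <- function(x, digits = 3L, ...) {
  cat(sprintf("Longitudinal mixed model: %s%s ~ line * treatment * period\n",
              if (x$transform == "log") "log " else "", x$outcome))
  cat(sprintf("  random intercepts: %s  (n = %d hen-periods)\n",
              if (x$random == "hen_in_pen") "pen, hen-in-pen" else "none", x$n))
  cat(sprintf("  variance components: pen %.4g, hen-in-pen %.4g, residual %.4g\n",
              x$varcomp["pen"], x$varcomp["hen_in_pen"], x$varcomp["residual"]))
  cat(sprintf("  marginal F tests (%s):\n", x$df_method))
  tab <- x$anova
  tab$F <- round(tab$F, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("  highest-order significant interaction: %s\n",
              x$highest_significant_interaction))
  invisible(x)
}

#' @export
summary.kbd_lmm <- function(object, ...) summary(object$model, ...)

#' @export
coef.kbd_lmm <- function(object, ...) object$fixed

#' Serialize a mixed-model result to JSON
#'
#' @param fit a `"kbd_lmm"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lmm_result <- function(fit, path) {
  stopifnot(inherits(fit, "kbd_lmm"))
  jsonlite::write_json(list(outcome = fit$outcome, transform = fit$transform,
                            fixed = as.list(fit$fixed),
                            varcomp = as.list(fit$varcomp),
                            anova = fit$anova, df_method = fit$df_method,
                            highest_significant_interaction =
                              fit$highest_significant_interaction, n = fit$n),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
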