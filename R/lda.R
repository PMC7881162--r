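#' Fit the single-hit model to a limiting-dilution design
#'
#' Under the single-hit Poisson model a well seeded with `d` cells is
#' negative with probability `exp(-f * d)`, where `f` is the frequency of
#' sphere-forming (active) cells. Equivalently, well positivity follows a
#' binomial GLM with complementary log-log link and `log(dose)` as an
#' offset; the intercept is `log(f)`. The fit is by maximum likelihood with
#' a Wald 95% confidence interval on `log(f)`, exponentiated onto the
#' frequency scale — the construction used by limiting-dilution software
#' such as ELDA. Frequencies are also reported as "1 in `1/f`" cells.
#'
#' @param design A tibble with `cells_per_well`, `wells`, `positive_wells`
#'   (one row per dose; a single arm).
#' @param conf_level Confidence level for the interval.
#'
#' @return An object of class `lda_fit`: list with `log_f`, `f`,
#'   `inv_f` (= 1/f), `ci95` (length-2 vector on the frequency scale),
#'   `se_log_f`, `deviance`, `df_residual`, `gof_p` (single-hit adequacy
#'   p when >= 3 doses, else NA) and the `design`.
#' @export
fit_single_hit <- function(design, conf_level = 0.95) {
  design <- check_lda_design(design)
  if (all(design$positive_wells == design$wells)) {
    abort("all wells positive: frequency not identifiable; extend the dilution series downward",
          class = "gliosplice_lda_error")
  }
  if (all(design$positive_wells == 0)) {
    abort("all wells negative: frequency not identifiable; no active cells detected at any dose",
          class = "gliosplice_lda_error")
  }
  # saturated doses (all wells positive) trigger benign glm convergence
  # warnings; they are part of the design, not a fitting problem
  fit <- suppressWarnings(glm(
    cbind(positive_wells, wells - positive_wells) ~ 1,
    family = binomial(link = "cloglog"),
    offset = log(cells_per_well),
    data = design
  ))
  log_f <- unname(coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log_f + c(-1, 1) * z * se)
  gof <- if (nrow(design) >= 3) {
    tryCatch(test_single_hit_adequacy(design)$p_value, error = function(e) NA_real_)
  } else NA_real_
  structure(
    list(log_f = log_f, f = exp(log_f), inv_f = exp(-log_f),
         ci95 = pmin(ci, 1), se_log_f = se,
         deviance = stats::deviance(fit),
         df_residual = stats::df.residual(fit),
         gof_p = gof, design = design),
    class = "lda_fit"
  )
}

check_lda_design <- function(design) {
  require_columns(design, c("cells_per_well", "wells", "positive_wells"),
                  "limiting-dilution design")
  if (any(design$positive_wells < 0 | design$positive_wells > design$wells)) {
    abort("positive_wells must lie in [0, wells]",
          class = "gliosplice_validation_error")
  }
  if (anyDuplicated(design$cells_per_well)) {
    abort("doses must be distinct", class = "gliosplice_validation_error")
  }
  design
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("Single-hit limiting-dilution fit\n")
  cat(sprintf("  frequency: %.4g  (1 in %.4g cells)\n", x$f, x$inv_f))
  cat(sprintf("  95%% CI: %.4g - %.4g\n", x$ci95[1], x$ci95[2]))
  if (!is.na(x$gof_p)) {
    cat(sprintf("  single-hit adequacy p: %.3g\n", x$gof_p))
  }
  invisible(x)
}

#' Test for inequality of active-cell frequency between arms
#'
#' Likelihood-ratio test comparing a shared-frequency single-hit model
#' against per-arm frequencies, on the combined well data. The statistic is
#' the deviance difference, chi-square distributed with
#' (number of arms - 1) degrees of freedom under the null of equal
#' frequencies.
#'
#' @param ... Two or more limiting-dilution design tibbles, or a single
#'   tibble containing an `arm` column with >= 2 arms.
#'
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
test_frequency_difference <- function(...) {
  designs <- list(...)
  if (length(designs) == 1 && "arm" %in% names(designs[[1]])) {
    combined <- designs[[1]]
  } else {
    stopifnot(length(designs) >= 2)
    combined <- bind_rows(purrr::imap(designs, function(d, i) {
      d$arm <- paste0("arm", i)
      d
    }))
  }
  arms <- unique(combined$arm)
  if (length(arms) < 2) abort("need at least two arms")
  for (a in arms) {
    d <- combined %>% filter(.data$arm == a)
    if (all(d$positive_wells == d$wells) || all(d$positive_wells == 0)) {
      abort(sprintf("arm '%s' is non-identifiable (all wells positive or all negative)", a),
            class = "gliosplice_lda_error")
    }
  }
  combined$arm <- factor(combined$arm)
  null_fit <- suppressWarnings(
    glm(cbind(positive_wells, wells - positive_wells) ~ 1,
        family = binomial(link = "cloglog"),
        offset = log(cells_per_well), data = combined))
  alt_fit <- suppressWarnings(
    glm(cbind(positive_wells, wells - positive_wells) ~ arm,
        family = binomial(link = "cloglog"),
        offset = log(cells_per_well), data = combined))
  stat <- max(0, stats::deviance(null_fit) - stats::deviance(alt_fit))
  df <- length(arms) - 1
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Test adequacy of the single-hit model
#'
#' Fits the extended model in which the complementary log-log of well
#' positivity has a free slope on `log(dose)` (the single-hit model fixes
#' the slope at 1: one active cell suffices) and Wald-tests slope = 1. A p
#' close to 1 indicates the single-hit model is adequate; data generated
#' with multi-hit kinetics (e.g. `P(negative) = exp(-f * d^2)`) yield slope
#' estimates near 2 and small p.
#'
#' @param design A limiting-dilution design tibble with >= 3 doses.
#'
#' @return A tibble with `slope`, `se`, `statistic` (Wald z), `p_value`.
#' @export
test_single_hit_adequacy <- function(design) {
  design <- check_lda_design(design)
  if (nrow(design) < 3) {
    abort("single-hit adequacy test needs at least three doses")
  }
  fit <- suppressWarnings(
    glm(cbind(positive_wells, wells - positive_wells) ~ log(cells_per_well),
        family = binomial(link = "cloglog"), data = design))
  slope <- unname(coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  z <- (slope - 1) / se
  tibble(slope = slope, se = se, statistic = z,
         p_value = 2 * pnorm(-abs(z)))
}

#' Relative change in sphere-forming capacity versus a control arm
#'
#' Ratio of fitted single-hit frequencies, expressed as percent change
#' relative to the control (e.g. DMSO) arm.
#'
#' @param fit_treated,fit_control `lda_fit` objects.
#' @return Percent change, `100 * (f_treated / f_control - 1)`.
#' @export
relative_sfc_change <- function(fit_treated, fit_control) {
  stopifnot(inherits(fit_treated, "lda_fit"), inherits(fit_control, "lda_fit"))
  100 * (fit_treated$f / fit_control$f - 1)
}
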