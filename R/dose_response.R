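#' Select the readout timepoint from DMSO confluence controls
#'
#' Dose-response curves are read at the 95th percentile of the times the
#' DMSO control wells take to reach 100% confluence — late enough for
#' maximum drug effect, early enough to avoid saturation. For each control
#' well the crossing time is the first observed time at or above the
#' threshold; a well that never reaches it contributes its last observed
#' time (with a warning). The 95th percentile uses the nearest-rank
#' definition and is snapped to the nearest observed timepoint at or below.
#'
#' @param confluence A tibble with `well`, `time`, `confluence` (percent,
#'   0-100) for the DMSO control wells.
#' @param threshold Confluence threshold, default 100.
#' @param prob Percentile of crossing times, default 0.95.
#'
#' @return The selected timepoint (same units as `time`).
#' @export
select_timepoint <- function(confluence, threshold = 100, prob = 0.95) {
  require_columns(confluence, c("well", "time", "confluence"),
                  "confluence series")
  if (nrow(confluence) == 0) abort("empty DMSO confluence series")
  cross <- confluence %>%
    group_by(.data$well) %>%
    arrange(.data$time, .by_group = TRUE) %>%
    summarise(
      t_cross = if (any(.data$confluence >= threshold))
        .data$time[which(.data$confluence >= threshold)[1]]
      else max(.data$time),
      reached = any(.data$confluence >= threshold),
      .groups = "drop"
    )
  if (!all(cross$reached)) {
    warn(sprintf("%d DMSO well(s) never reached %g%% confluence; using their last timepoint",
                 sum(!cross$reached), threshold))
  }
  times <- sort(cross$t_cross)
  t95 <- times[ceiling(prob * length(times))]   # nearest-rank percentile
  obs <- sort(unique(confluence$time))
  max(obs[obs <= t95])                          # snap to observed grid
}

#' Normalize raw readouts to the DMSO control
#'
#' Response is the raw readout divided by the DMSO mean, then clipped to
#' \[0, 1\] for area-above-curve computation. Clipping is recorded so
#' above-control growth remains auditable.
#'
#' @param raw Raw readouts (confluence or viability) at the selected
#'   timepoint.
#' @param dmso_mean Mean DMSO-control readout; must be positive.
#'
#' @return A tibble with `raw`, `response` (clipped fraction of control)
#'   and logical `clipped`.
#' @export
normalize_response <- function(raw, dmso_mean) {
  if (!is.numeric(dmso_mean) || length(dmso_mean) != 1 || dmso_mean <= 0) {
    abort("dmso_mean must be a single positive number")
  }
  frac <- raw / dmso_mean
  tibble(raw = raw,
         response = pmin(1, pmax(0, frac)),
         clipped = frac > 1 | frac < 0)
}

#' Area above the dose-response curve
#'
#' AAC is the trapezoidal integral of (1 - response) over log10(dose),
#' normalized by the tested log-dose range, giving a value on a 0-1 scale:
#' 0 for no effect at any dose, 1 for complete kill everywhere. Higher AAC
#' means greater sensitivity. Replicate-averaged responses are expected
#' (one value per dose), clipped to \[0, 1\].
#'
#' @param series A tibble with `dose` (molar, positive) and `response`
#'   (fraction of control in \[0, 1\]); one row per dose.
#'
#' @return AAC in \[0, 1\].
#' @export
compute_aac <- function(series) {
  require_columns(series, c("dose", "response"), "dose-response series")
  series <- series %>% arrange(.data$dose)
  if (nrow(series) < 2) abort("AAC needs at least two doses")
  if (any(series$dose <= 0)) abort("doses must be positive")
  if (anyDuplicated(series$dose)) {
    abort("one response per dose expected; average replicates first")
  }
  x <- log10(series$dose)
  y <- 1 - pmin(1, pmax(0, series$response))
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc / (max(x) - min(x))
}

#' Fit a descending Hill curve with the top fixed at 1
#'
#' Least-squares fit of `response = e_inf + (1 - e_inf) /
#' (1 + (dose / ec50)^hill)` by Levenberg-Marquardt, with bounds
#' `e_inf` in \[0, 1\], `hill` in \[0.1, 10\] and `ec50` within
#' \[d_min / 10, d_max * 10\] (fitted on the log10 scale). The top is fixed
#' at 1 because responses are control-normalized. The EC50 is reported as
#' undefined (`NA`) when the curve is flat (response range < 0.1), when the
#' fitted value hits the upper dose bound, or when the optimizer fails.
#'
#' @param series A tibble with `dose` and `response` (one row per dose,
#'   replicate-averaged).
#'
#' @return An object of class `hill_fit`: a list with `ec50`, `hill`,
#'   `e_inf`, `converged`, `flat`, `rss`, `n`, and the fitted `series`.
#' @export
fit_hill <- function(series) {
  require_columns(series, c("dose", "response"), "dose-response series")
  series <- series %>% arrange(.data$dose)
  if (nrow(series) < 4) abort("Hill fit needs at least four doses")
  d <- series$dose; y <- series$response
  out <- structure(
    list(ec50 = NA_real_, hill = NA_real_, e_inf = NA_real_,
         converged = FALSE, flat = FALSE, rss = NA_real_, n = length(d),
         series = series),
    class = "hill_fit"
  )
  if (max(y) - min(y) < 0.1) {
    out$flat <- TRUE
    out$e_inf <- mean(y)
    return(out)
  }
  lo <- c(log10(min(d) / 10), 0.1, 0)
  hi <- c(log10(max(d) * 10), 10, 1)
  resid_fn <- function(par) {
    y - (par[3] + (1 - par[3]) / (1 + (d / 10^par[1])^par[2]))
  }
  # multi-start over candidate EC50s (every observed dose plus the dose
  # nearest half-maximal response); keep the lowest-RSS converged fit
  half <- (max(y) + min(y)) / 2
  starts <- unique(c(log10(d[which.min(abs(y - half))]), log10(d)))
  e0 <- max(0, min(1, min(y)))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(s0, 1, e0), fn = resid_fn, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) return(out)
  out$converged <- TRUE
  out$hill <- best$par[2]
  out$e_inf <- best$par[3]
  out$rss <- best$rss
  # an EC50 pinned at the upper bound is censored, not estimated
  if (best$par[1] < hi[1] - 1e-6) out$ec50 <- 10^best$par[1]
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit (top = 1)\n")
  if (x$flat) {
    cat("  flat response (range < 0.1); EC50 undefined\n")
  } else {
    cat(sprintf("  EC50: %s  hill: %.3g  e_inf: %.3g  (n = %d doses)\n",
                if (is.na(x$ec50)) "undefined" else
                  sprintf("%.3g M (%.4g nM)", x$ec50, x$ec50 * 1e9),
                x$hill, x$e_inf, x$n))
  }
  invisible(x)
}

#' Summarise a dose-response plate into per-sample AAC and EC50
#'
#' Averages replicates per dose, computes AAC and fits the Hill model for
#' each sample x compound series.
#'
#' @param plate A plate tibble (`sample_id`, `compound`, `dose`,
#'   `replicate`, `response`).
#'
#' @return A tibble with one row per sample x compound: `aac`, `ec50`
#'   (molar; NA when undefined), `hill`, `e_inf`.
#' @export
summarise_dose_response <- function(plate) {
  require_columns(plate, c("sample_id", "compound", "dose", "response"),
                  "plate table")
  plate %>%
    group_by(.data$sample_id, .data$compound, .data$dose) %>%
    summarise(response = mean(.data$response), .groups = "drop") %>%
    group_by(.data$sample_id, .data$compound) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(
      aac = purrr::map_dbl(.data$data, compute_aac),
      fit = purrr::map(.data$data, fit_hill),
      ec50 = purrr::map_dbl(.data$fit, "ec50"),
      hill = purrr::map_dbl(.data$fit, "hill"),
      e_inf = purrr::map_dbl(.data$fit, "e_inf")
    ) %>%
    select("sample_id", "compound", "aac", "ec50", "hill", "e_inf")
}

#' Sensitivity calls and responder labels
#'
#' A line is *sensitive* when its EC50 is defined and below the configured
#' threshold (default 250 nM). Responder labels split the cohort on AAC:
#' *good* when AAC is at or above the threshold — by default the cohort
#' median AAC within each compound — else *poor*. With an even split this
#' reproduces a median dichotomy; when all AACs are equal every line is
#' labelled good (degenerate case of the >=-median rule).
#'
#' @param summaries A tibble with `sample_id`, `compound`, `aac`, `ec50`
#'   (molar).
#' @param ec50_sensitive_nM EC50 cutoff in nanomolar for the sensitivity
#'   call.
#' @param aac_threshold AAC cutoff for the good/poor split; `NULL` uses the
#'   per-compound cohort median.
#'
#' @return `summaries` with added logical `sensitive` and `responder`
#'   (`"good"`/`"poor"`).
#' @export
classify_and_label <- function(summaries, ec50_sensitive_nM = 250,
                               aac_threshold = NULL) {
  require_columns(summaries, c("sample_id", "compound", "aac", "ec50"),
                  "dose-response summaries")
  summaries %>%
    group_by(.data$compound) %>%
    mutate(
      sensitive = !is.na(.data$ec50) & .data$ec50 < ec50_sensitive_nM * 1e-9,
      .thr = if (is.null(aac_threshold)) median(.data$aac) else aac_threshold,
      responder = ifelse(.data$aac >= .data$.thr, "good", "poor")
    ) %>%
    ungroup() %>%
    select(-".thr")
}

#' Correlation between responses to two compounds
#'
#' Pearson correlation (with two-sided p-value) between paired AAC vectors,
#' e.g. GSK591 vs LLY-283 across a cell-line panel.
#'
#' @param aac_a,aac_b Paired numeric vectors, length >= 3.
#'
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
compound_correlation <- function(aac_a, aac_b) {
  stopifnot(length(aac_a) == length(aac_b))
  keep <- stats::complete.cases(aac_a, aac_b)
  a <- aac_a[keep]; b <- aac_b[keep]
  if (length(a) < 3) abort("need at least three complete pairs")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance in an AAC vector; correlation undefined")
  }
  ct <- cor.test(a, b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
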