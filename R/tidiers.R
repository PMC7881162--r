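#' Tidy a Hill dose-response fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return One row per parameter (`ec50`, `hill`, `e_inf`) with `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ec50", "hill", "e_inf"),
         estimate = c(x$ec50, x$hill, x$e_inf))
}

#' @rdname tidy.hill_fit
#' @return `glance()`: a one-row model summary (`ec50`, `hill`, `e_inf`,
#'   `rss`, `n`, `converged`, `flat`).
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, hill = x$hill, e_inf = x$e_inf, rss = x$rss,
         n = x$n, converged = x$converged, flat = x$flat)
}

#' Tidy a single-hit limiting-dilution fit
#'
#' @param x An `lda_fit` object.
#' @param ... Unused.
#' @return One row for the log-frequency with estimate, standard error and
#'   confidence bounds.
#' @export
tidy.lda_fit <- function(x, ...) {
  tibble(term = "log_f", estimate = x$log_f, std.error = x$se_log_f,
         conf.low = log(x$ci95[1]), conf.high = log(x$ci95[2]))
}

#' @rdname tidy.lda_fit
#' @return `glance()`: one-row summary with the frequency, its CI, the
#'   "1 in N" form, deviance and single-hit adequacy p.
#' @export
glance.lda_fit <- function(x, ...) {
  tibble(f = x$f, conf.low = x$ci95[1], conf.high = x$ci95[2],
         inv_f = x$inv_f, deviance = x$deviance,
         df.residual = x$df_residual, gof_p = x$gof_p)
}
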