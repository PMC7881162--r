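#' Plot a Hill dose-response fit
#'
#' Observed responses against log10 dose with the fitted descending Hill
#' curve overlaid (when the fit converged).
#'
#' @param object A `hill_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  s <- object$series
  p <- ggplot2::ggplot(s, ggplot2::aes(x = log10(.data$dose),
                                       y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 dose (M)", y = "fraction of control",
                  title = "Dose-response") +
    ggplot2::ylim(0, NA)
  if (object$converged) {
    grid <- tibble(dose = 10^seq(log10(min(s$dose)), log10(max(s$dose)),
                                 length.out = 200))
    ec50 <- if (is.na(object$ec50)) max(s$dose) * 10 else object$ec50
    grid$response <- hill_response(grid$dose, ec50, object$hill,
                                   object$e_inf)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Plot a limiting-dilution fit
#'
#' The classic limiting-dilution plot: log fraction of negative wells
#' against cells per well, with the fitted single-hit line (slope -f
#' through the origin).
#'
#' @param object An `lda_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lda_fit <- function(object, ...) {
  d <- object$design %>%
    mutate(frac_neg = (.data$wells - .data$positive_wells) / .data$wells)
  shown <- d %>% filter(.data$frac_neg > 0)
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$cells_per_well,
                                      y = log(.data$frac_neg))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = -object$f, intercept = 0,
                         colour = "steelblue") +
    ggplot2::labs(x = "cells per well", y = "log fraction negative wells",
                  title = sprintf("Single-hit fit: 1 active cell in %.3g",
                                  object$inv_f))
}

#' AAC waterfall across a cell-line panel
#'
#' Bar plot of the area above the dose-response curve per sample, ordered
#' by decreasing AAC within compound and coloured by responder label when
#' present.
#'
#' @param summaries A dose-response summary tibble (from
#'   [summarise_dose_response()], optionally through
#'   [classify_and_label()]).
#' @return A ggplot.
#' @export
plot_aac_waterfall <- function(summaries) {
  df <- summaries %>%
    group_by(.data$compound) %>%
    arrange(desc(.data$aac), .by_group = TRUE) %>%
    mutate(ord = row_number()) %>%
    ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ord, y = .data$aac))
  p <- if ("responder" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$responder))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::facet_wrap(~compound) +
    ggplot2::labs(x = "cell line (ranked)", y = "AAC",
                  title = "Sensitivity to PRMT5 inhibition")
}

#' Heatmap of signature-event PSI values across the cohort
#'
#' @param psi A wide PSI tibble.
#' @param signature A tibble from [derive_signature()].
#' @param labels Optional responder labels ordering the columns
#'   (good before poor).
#' @return A ggplot.
#' @export
plot_signature_heatmap <- function(psi, signature, labels = NULL) {
  samples <- setdiff(names(psi), c("event_id", "gene"))
  if (!is.null(labels)) {
    samples <- labels$sample_id[order(labels$responder)]
  }
  df <- psi %>%
    semi_join(signature, by = "event_id") %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "psi") %>%
    mutate(sample_id = factor(.data$sample_id, levels = samples),
           event_id = factor(.data$event_id,
                             levels = rev(signature$event_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$event_id,
                                   fill = .data$psi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PSI",
                  title = "Baseline splicing-response signature") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
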