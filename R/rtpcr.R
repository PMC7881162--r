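#' Select the long/short isoform pair for each assay
#'
#' For each assay (primer pair) the two isoforms are identified as the two
#' most abundantly expressed amplicon sizes, summing concentration over all
#' samples and conditions of that assay. The larger size of the pair is the
#' long (inclusion) isoform, the smaller the short isoform. Ties between
#' candidate sizes are broken in favour of the larger amplicon.
#'
#' @param peaks A peak tibble (`assay_id`, `sample_id`, `condition`,
#'   `size_bp`, `concentration`).
#'
#' @return A tibble with `assay_id`, `long_size`, `short_size`.
#' @export
select_isoforms <- function(peaks) {
  require_columns(peaks, c("assay_id", "size_bp", "concentration"),
                  "peak table")
  peaks %>%
    group_by(.data$assay_id, .data$size_bp) %>%
    summarise(total = sum(.data$concentration), .groups = "drop_last") %>%
    filter(.data$total > 0) %>%
    arrange(desc(.data$total), desc(.data$size_bp), .by_group = TRUE) %>%
    summarise(
      n_sizes = n(),
      long_size = if (n() >= 2) max(.data$size_bp[1:2]) else NA_real_,
      short_size = if (n() >= 2) min(.data$size_bp[1:2]) else NA_real_,
      .groups = "drop"
    ) %>%
    (function(df) {
      if (any(df$n_sizes < 2) || nrow(df) == 0) {
        bad <- if (nrow(df)) df$assay_id[df$n_sizes < 2] else "(none)"
        abort(sprintf(
          "assay(s) %s have fewer than two distinct amplicon sizes; PSI is not callable",
          paste(bad, collapse = ", ")),
          class = "gliosplice_validation_error")
      }
      df %>% select("assay_id", "long_size", "short_size")
    })
}

#' Percent spliced in from isoform concentrations
#'
#' PSI is the long-isoform fraction `L / (L + S)` where `L` and `S` are the
#' measured concentrations of the long and short amplicons. Vectorised;
#' scale-invariant in (L, S).
#'
#' @param L,S Non-negative concentrations of the long and short isoforms.
#' @return PSI fraction(s) in \[0, 1\].
#' @export
compute_psi <- function(L, S) {
  if (any(L < 0) || any(S < 0)) {
    abort("isoform concentrations must be non-negative",
          class = "gliosplice_validation_error")
  }
  if (any(L + S == 0)) {
    abort("PSI undefined: L + S is zero",
          class = "gliosplice_undefined_psi")
  }
  L / (L + S)
}

#' PSI matrix and dPSI versus control from an amplicon peak table
#'
#' Computes PSI per assay x sample x condition using the per-assay isoform
#' pair chosen by [select_isoforms()], then dPSI relative to the control
#' condition within the same assay and sample. A sample missing both
#' isoform peaks (zero total concentration) yields a missing PSI without
#' affecting the rest of the table.
#'
#' @param peaks A peak tibble.
#' @param control Condition label of the control (e.g. `"DMSO"`).
#'
#' @return A tibble with `assay_id`, `sample_id`, `condition`, `psi`,
#'   `delta_psi` (NA for the control rows' own comparison is 0; NA where
#'   PSI is missing on either side).
#' @export
psi_table <- function(peaks, control) {
  require_columns(peaks, c("assay_id", "sample_id", "condition", "size_bp",
                           "concentration"), "peak table")
  if (!any(peaks$condition == control)) {
    abort(sprintf("control condition '%s' not present in peak table", control),
          class = "gliosplice_validation_error")
  }
  iso <- select_isoforms(peaks)
  long_tbl <- peaks %>%
    inner_join(iso, by = "assay_id") %>%
    group_by(.data$assay_id, .data$sample_id, .data$condition) %>%
    summarise(
      L = sum(.data$concentration[.data$size_bp == .data$long_size]),
      S = sum(.data$concentration[.data$size_bp == .data$short_size]),
      .groups = "drop"
    ) %>%
    mutate(psi = ifelse(.data$L + .data$S > 0,
                        .data$L / (.data$L + .data$S), NA_real_))
  ctrl <- long_tbl %>%
    filter(.data$condition == control) %>%
    select("assay_id", "sample_id", psi_control = "psi")
  long_tbl %>%
    left_join(ctrl, by = c("assay_id", "sample_id")) %>%
    mutate(delta_psi = .data$psi - .data$psi_control) %>%
    select("assay_id", "sample_id", "condition", "psi", "delta_psi")
}
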