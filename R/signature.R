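#' Derive the baseline splicing-response signature
#'
#' Selects the baseline PSI events that separate good from poor responders
#' using three criteria, applied per event:
#' \enumerate{
#'   \item quantifiability — non-missing PSI in at least
#'     `min_frac` (default 75%) of all samples;
#'   \item variation — the intra-group variation must be smaller than the
#'     inter-group variation, both quantified by standard deviation: intra
#'     is the root of the average within-group variance, inter is the
#'     standard deviation of the two group means (equal to |dPSI| / sqrt(2)
#'     for two groups); both are reported so the criterion is auditable;
#'   \item effect size — |mean PSI difference| between groups of at least
#'     `min_dpsi` (default 0.20 on the fraction scale).
#' }
#' Events with fewer than two quantified samples in either group cannot be
#' assessed and are skipped; their ids and reasons are kept in the
#' `"skipped"` attribute. Output is ranked by the chosen key (default
#' |dPSI|, descending), ties broken by event id.
#'
#' @param psi A wide PSI tibble (`event_id`, `gene`, one column per
#'   sample), values in \[0, 1\] or NA.
#' @param labels A tibble with `sample_id`, `responder`
#'   (`"good"`/`"poor"`); every PSI sample column must be labelled.
#' @param min_frac Minimum fraction of samples with non-missing PSI.
#' @param min_dpsi Minimum |mean_good - mean_poor|.
#' @param rank_key Ranking key, `"dpsi"` (|dPSI|) or `"inter"`.
#'
#' @return A tibble of signature events: `event_id`, `gene`,
#'   `n_quantified`, `fraction_quantified`, `mean_good`, `mean_poor`,
#'   `sd_good`, `sd_poor`, `intra`, `inter`, `dpsi`.
#' @export
derive_signature <- function(psi, labels, min_frac = 0.75, min_dpsi = 0.20,
                             rank_key = c("dpsi", "inter")) {
  rank_key <- match.arg(rank_key)
  require_columns(psi, c("event_id", "gene"), "PSI matrix")
  require_columns(labels, c("sample_id", "responder"), "label table")
  samples <- setdiff(names(psi), c("event_id", "gene"))
  if (!all(samples %in% labels$sample_id)) {
    abort("every PSI sample column must appear in the label table")
  }
  resp <- labels$responder[match(samples, labels$sample_id)]
  good <- samples[resp == "good"]
  poor <- samples[resp == "poor"]
  if (length(good) < 2 || length(poor) < 2) {
    abort("need at least two samples per responder group")
  }
  m <- as.matrix(psi[, samples])
  n_q <- rowSums(!is.na(m))
  mg <- rowMeans(m[, good, drop = FALSE], na.rm = TRUE)
  mp <- rowMeans(m[, poor, drop = FALSE], na.rm = TRUE)
  vg <- apply(m[, good, drop = FALSE], 1, var, na.rm = TRUE)
  vp <- apply(m[, poor, drop = FALSE], 1, var, na.rm = TRUE)
  nq_g <- rowSums(!is.na(m[, good, drop = FALSE]))
  nq_p <- rowSums(!is.na(m[, poor, drop = FALSE]))

  stats_tbl <- tibble(
    event_id = psi$event_id, gene = psi$gene,
    n_quantified = as.integer(n_q),
    fraction_quantified = n_q / length(samples),
    mean_good = mg, mean_poor = mp,
    sd_good = sqrt(vg), sd_poor = sqrt(vp),
    intra = sqrt((vg + vp) / 2),
    inter = apply(cbind(mg, mp), 1, sd),
    dpsi = mg - mp,
    .n_good = nq_g, .n_poor = nq_p
  )
  skipped <- stats_tbl %>%
    filter(.data$.n_good < 2 | .data$.n_poor < 2) %>%
    mutate(reason = "fewer than two quantified samples in a group") %>%
    select("event_id", "reason")
  sig <- stats_tbl %>%
    filter(.data$.n_good >= 2, .data$.n_poor >= 2,
           .data$fraction_quantified >= min_frac,
           .data$intra < .data$inter,
           abs(.data$dpsi) >= min_dpsi) %>%
    select(-".n_good", -".n_poor")
  key <- if (rank_key == "dpsi") abs(sig$dpsi) else sig$inter
  sig <- sig[order(-key, sig$event_id), ]
  attr(sig, "skipped") <- skipped
  sig
}

#' Summary counts for a derived signature
#'
#' @param signature A tibble from [derive_signature()].
#' @return A tibble with `n_total`, `n_positive_dpsi` (higher inclusion in
#'   good responders), `n_negative_dpsi`, `n_genes`.
#' @export
signature_counts <- function(signature) {
  tibble(
    n_total = nrow(signature),
    n_positive_dpsi = sum(signature$dpsi > 0),
    n_negative_dpsi = sum(signature$dpsi < 0),
    n_genes = dplyr::n_distinct(signature$gene)
  )
}

#' Score a new sample against the signature
#'
#' The score is the mean, over signature events quantified in the sample,
#' of `sign(dpsi) * (psi - midpoint)` where the midpoint is halfway between
#' the good and poor group means. Positive scores predict a good responder.
#'
#' @param psi_vector Named numeric vector of PSI values for one sample
#'   (names are event ids; NA = not quantified).
#' @param signature A tibble from [derive_signature()].
#'
#' @return A single numeric score.
#' @export
score_sample <- function(psi_vector, signature) {
  vals <- psi_vector[signature$event_id]
  keep <- !is.na(vals)
  if (!any(keep)) {
    abort("no signature event is quantified in this sample; score undefined",
          class = "gliosplice_undefined_score")
  }
  mid <- (signature$mean_good + signature$mean_poor) / 2
  mean(sign(signature$dpsi[keep]) * (vals[keep] - mid[keep]))
}

#' Score every sample of a PSI matrix against the signature
#'
#' @param psi A wide PSI tibble.
#' @param signature A tibble from [derive_signature()].
#' @return A tibble with `sample_id`, `score`, `n_events_used`.
#' @export
score_samples <- function(psi, signature) {
  samples <- setdiff(names(psi), c("event_id", "gene"))
  purrr::map_dfr(samples, function(s) {
    v <- setNames(psi[[s]], psi$event_id)
    tibble(
      sample_id = s,
      score = score_sample(v, signature),
      n_events_used = sum(!is.na(v[signature$event_id]))
    )
  })
}
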