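#' Significance-filter alternative splicing events
#'
#' Keeps exactly the events passing all five significance clauses, every
#' comparison inclusive: p-value at most `p_max`; at least `min_inc_reads`
#' reads supporting inclusion; at least `min_exc_reads` supporting
#' exclusion; at least `min_total_reads` total supporting reads; and
#' |dPSI| (treated minus control) at least `min_abs_dpsi`. The absolute
#' value keeps both preferential-inclusion (dPSI > 0) and
#' preferential-exclusion (dPSI < 0) events.
#'
#' @param events A splice-event tibble (see [read_event_table()]).
#' @param thresholds Threshold list, e.g. `default_config()$thresholds`.
#'
#' @return The subset of `events` passing all filters, original order kept.
#' @export
filter_significant <- function(events, thresholds = default_config()$thresholds) {
  if (nrow(events) == 0) return(events)
  validate_events(events)
  th <- thresholds
  events %>%
    filter(
      .data$p_value <= th$p_max,
      .data$inclusion_reads >= th$min_inc_reads,
      .data$exclusion_reads >= th$min_exc_reads,
      .data$inclusion_reads + .data$exclusion_reads >= th$min_total_reads,
      abs(.data$delta_psi) >= th$min_abs_dpsi
    )
}

#' Reciprocal overlap between two stranded intervals
#'
#' Computes the overlap of two 0-based half-open genomic intervals and the
#' fraction of each interval covered. Two events are the same event when
#' the overlap covers at least `min_overlap` (default 95%) of *both*
#' intervals, on the same chromosome and strand — the bedtools
#' `-f 0.95 -r -s` convention.
#'
#' @param a,b Lists or one-row data frames with `chrom`, `start`, `end`,
#'   `strand`.
#' @param min_overlap Reciprocal-overlap fraction required for a match.
#'
#' @return A tibble with `overlap` (bp), `frac_a`, `frac_b`, `match`.
#' @export
reciprocal_overlap <- function(a, b, min_overlap = 0.95) {
  len_a <- a$end - a$start
  len_b <- b$end - b$start
  if (len_a <= 0 || len_b <= 0) {
    abort("zero-length interval in reciprocal_overlap",
          class = "gliosplice_validation_error")
  }
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  same <- identical(as.character(a$chrom), as.character(b$chrom)) &&
    identical(as.character(a$strand), as.character(b$strand))
  if (!same) ov_frac <- c(0, 0) else ov_frac <- c(ov / len_a, ov / len_b)
  tibble(
    overlap = if (same) ov else 0L,
    frac_a = ov_frac[1], frac_b = ov_frac[2],
    match = same && ov_frac[1] >= min_overlap && ov_frac[2] >= min_overlap
  )
}

# vectorised reciprocal-overlap filter for pre-joined candidate pairs
ro_match <- function(start_a, end_a, start_b, end_b, min_overlap) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov / (end_a - start_a) >= min_overlap & ov / (end_b - start_b) >= min_overlap
}

#' Consolidate filtered events across samples
#'
#' Returns the events observed in *all* samples: an event from the first
#' table is retained when every other table contains a same-class,
#' same-strand, same-chromosome event with at least `min_overlap` reciprocal
#' coordinate overlap. The representative record is the first table's event;
#' each matched sample's dPSI (and matched event id) is carried alongside as
#' `dpsi_<sample>` / `match_id_<sample>` columns. When an event has several
#' qualifying matches in a sample, the one with the largest minimum
#' reciprocal fraction wins (ties by event id).
#'
#' @param tables A list of (typically already filtered) event tibbles, one
#'   per sample. Names are used as sample labels; unnamed lists get
#'   `sample1`, `sample2`, ...
#' @param min_overlap Reciprocal-overlap fraction for event identity.
#'
#' @return A tibble of consolidated events with per-sample dPSI columns.
#'   Attributes `n_events` and `n_genes` hold the event and distinct-gene
#'   counts.
#' @export
consolidate_events <- function(tables, min_overlap = 0.95) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  ref <- tables[[1]]
  if (nrow(ref) == 0) return(empty_consolidated(names(tables)))
  out <- ref
  out[[paste0("dpsi_", names(tables)[1])]] <- ref$delta_psi
  out[[paste0("match_id_", names(tables)[1])]] <- ref$event_id
  keep <- rep(TRUE, nrow(ref))
  for (s in seq_along(tables)[-1]) {
    other <- tables[[s]]
    if (nrow(other) == 0) return(empty_consolidated(names(tables)))
    cand <- inner_join(
      ref %>% select("event_id", "event_class", "chrom", "strand",
                     "start", "end"),
      other %>% select(o_event_id = "event_id", "event_class", "chrom",
                       "strand", o_start = "start", o_end = "end",
                       o_dpsi = "delta_psi"),
      by = c("event_class", "chrom", "strand"),
      relationship = "many-to-many"
    ) %>%
      mutate(
        ov = pmax(0, pmin(.data$end, .data$o_end) -
                    pmax(.data$start, .data$o_start)),
        min_frac = pmin(.data$ov / (.data$end - .data$start),
                        .data$ov / (.data$o_end - .data$o_start))
      ) %>%
      filter(ro_match(.data$start, .data$end, .data$o_start, .data$o_end,
                      .env$min_overlap)) %>%
      group_by(.data$event_id) %>%
      arrange(desc(.data$min_frac), .data$o_event_id, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
    keep <- keep & ref$event_id %in% cand$event_id
    idx <- match(ref$event_id, cand$event_id)
    out[[paste0("dpsi_", names(tables)[s])]] <- cand$o_dpsi[idx]
    out[[paste0("match_id_", names(tables)[s])]] <- cand$o_event_id[idx]
  }
  out <- out[keep, ]
  attr(out, "n_events") <- nrow(out)
  attr(out, "n_genes") <- dplyr::n_distinct(out$gene)
  out
}

empty_consolidated <- function(sample_names) {
  out <- tibble(!!!setNames(
    rep(list(character(0)), length(event_columns())), event_columns()))
  for (s in sample_names) {
    out[[paste0("dpsi_", s)]] <- numeric(0)
    out[[paste0("match_id_", s)]] <- character(0)
  }
  attr(out, "n_events") <- 0L
  attr(out, "n_genes") <- 0L
  out
}

#' Classify the predicted protein impact of splice events
#'
#' Maps each event onto transcript models and predicts whether the splicing
#' change disrupts the open reading frame. Mapping follows
#' complete-inclusion / complete-exclusion rules: a retained intron (RI)
#' maps when some transcript carries the intron completely inserted within
#' an exon (the intron-retaining transcript); a cassette exon (and the
#' other exonic classes) maps when some transcript completely excludes the
#' segment (no exon overlap, within the transcript span) while a canonical
#' transcript carries it completely inside an exon.
#'
#' A mapped event whose segment length is not a multiple of 3 is called
#' `disruptive_frameshift` (basis `length_mod3`). In-frame events are
#' `in_frame_preserving` unless a genome sequence is supplied and the
#' segment introduces an in-frame stop codon — read in the frame
#' established by the mapping transcript's coding start — in which case the
#' call is `disruptive_frameshift` with basis `stop_codon`. Unmapped events
#' are `unknown` (basis `no_transcript_match`).
#'
#' @param events A splice-event tibble.
#' @param transcripts Exon models: tibble with `transcript_id`, `gene`,
#'   `chrom`, `strand`, `exon_start`, `exon_end` (0-based half-open, one
#'   row per exon), logical `is_canonical`, and optional `coding_start`
#'   (genomic 0-based position of the first coding base in transcript
#'   orientation; NA for non-coding).
#' @param genome Optional named character vector of chromosome sequences
#'   (plus-strand, position 1 = coordinate 0) enabling the stop-codon scan.
#'
#' @return A tibble with `event_id`, `call`, `basis`.
#' @export
classify_impact <- function(events, transcripts, genome = NULL) {
  need <- c("transcript_id", "gene", "chrom", "strand", "exon_start",
            "exon_end")
  require_columns(transcripts, need, "transcript model")
  if (any(transcripts$exon_start >= transcripts$exon_end)) {
    abort("malformed transcript model: exon_start must be < exon_end",
          class = "gliosplice_validation_error")
  }
  if (!"is_canonical" %in% names(transcripts)) transcripts$is_canonical <- FALSE
  if (!"coding_start" %in% names(transcripts)) {
    transcripts$coding_start <- NA_real_
  }
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    tx <- transcripts %>%
      filter(.data$chrom == ev$chrom, .data$strand == ev$strand)
    mapped_tx <- map_event_to_transcript(ev, tx)
    if (is.null(mapped_tx)) {
      return(tibble(event_id = ev$event_id, call = "unknown",
                    basis = "no_transcript_match"))
    }
    len <- ev$end - ev$start
    if (len %% 3 != 0) {
      return(tibble(event_id = ev$event_id, call = "disruptive_frameshift",
                    basis = "length_mod3"))
    }
    if (!is.null(genome) &&
        has_inframe_stop(ev, mapped_tx, genome)) {
      return(tibble(event_id = ev$event_id, call = "disruptive_frameshift",
                    basis = "stop_codon"))
    }
    tibble(event_id = ev$event_id, call = "in_frame_preserving",
           basis = "length_mod3")
  })
}

# returns the exon rows of a transcript carrying the event fully inside one
# exon (the inclusion transcript), or NULL when mapping rules are not met
map_event_to_transcript <- function(ev, tx) {
  if (nrow(tx) == 0) return(NULL)
  contains <- tx %>%
    filter(.data$exon_start <= ev$start, .data$exon_end >= ev$end)
  if (nrow(contains) == 0) return(NULL)
  if (ev$event_class == "RI") {
    # complete inclusion within an exon is the retained-intron transcript
    incl_id <- contains$transcript_id[1]
  } else {
    # need a transcript completely excluding the segment...
    spans <- tx %>%
      group_by(.data$transcript_id) %>%
      summarise(span_start = min(.data$exon_start),
                span_end = max(.data$exon_end), .groups = "drop")
    overlapping <- tx %>%
      filter(.data$exon_start < ev$end, .data$exon_end > ev$start) %>%
      pull("transcript_id") %>% unique()
    excluded <- spans %>%
      filter(.data$span_start <= ev$start, .data$span_end >= ev$end,
             !(.data$transcript_id %in% overlapping))
    if (nrow(excluded) == 0) return(NULL)
    # ...and a canonical transcript carrying it completely inside an exon
    canon <- contains %>% filter(.data$is_canonical)
    if (ev$event_class == "CE" && nrow(canon) == 0) return(NULL)
    incl_id <- if (nrow(canon)) canon$transcript_id[1] else
      contains$transcript_id[1]
  }
  tx %>% filter(.data$transcript_id == incl_id)
}

# scan the event segment for a stop codon in the frame set by the mapping
# transcript's coding start
has_inframe_stop <- function(ev, mapped_tx, genome) {
  cs <- mapped_tx$coding_start[1]
  if (is.na(cs)) return(FALSE)
  chrom_seq <- genome[[as.character(ev$chrom)]]
  if (is.null(chrom_seq)) return(FALSE)
  seg <- substr(chrom_seq, ev$start + 1, ev$end)
  if (ev$strand == "+") {
    # coding nucleotides 5' of the segment within the transcript's exons
    before <- sum(pmax(0, pmin(mapped_tx$exon_end, ev$start) -
                         pmax(mapped_tx$exon_start, cs)))
  } else {
    seg <- revcomp(seg)
    before <- sum(pmax(0, pmin(mapped_tx$exon_end, cs + 1) -
                         pmax(mapped_tx$exon_start, ev$end)))
  }
  phase <- before %% 3
  lead <- (3 - phase) %% 3  # bases completing the codon begun upstream
  codon_starts <- seq(1 + lead, nchar(seg) - 2, by = 3)
  if (!length(codon_starts)) return(FALSE)
  codons <- substring(seg, codon_starts, codon_starts + 2)
  any(toupper(codons) %in% c("TAA", "TAG", "TGA"))
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Association between splicing direction and predicted ORF disruption
#'
#' Builds the 2x2 contingency table of splicing direction (dPSI > 0
#' inclusion vs dPSI < 0 exclusion) against predicted impact (disruptive vs
#' non-disruptive) and applies Fisher's exact test. The null is that an
#' event's direction is independent of its predicted effect.
#'
#' @param events A tibble with `delta_psi` and impact `call` columns (e.g.
#'   the output of [classify_impact()] joined back onto events). Events
#'   with `call == "unknown"` or `delta_psi == 0` are not permitted.
#' @param alternative Sidedness passed to [stats::fisher.test()]
#'   (default two-sided).
#'
#' @return A tibble with `odds_ratio`, `p_value`, and the four cell counts
#'   `incl_disr`, `incl_nondisr`, `excl_disr`, `excl_nondisr`. If any table
#'   margin is zero the association is undefined: p is 1 with a warning.
#' @export
direction_disruption_test <- function(events, alternative = "two.sided") {
  require_columns(events, c("delta_psi", "call"), "impact-annotated events")
  if (any(events$call == "unknown")) {
    abort("events with unknown impact must be removed first",
          class = "gliosplice_validation_error")
  }
  if (any(events$delta_psi == 0)) {
    abort("events with delta_psi == 0 have no direction",
          class = "gliosplice_validation_error")
  }
  incl <- events$delta_psi > 0
  disr <- events$call == "disruptive_frameshift"
  tab <- matrix(c(sum(incl & disr), sum(incl & !disr),
                  sum(!incl & disr), sum(!incl & !disr)),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate 2x2 table (a zero margin); association undefined, p = 1")
    return(tibble(odds_ratio = NA_real_, p_value = 1,
                  incl_disr = tab[1, 1], incl_nondisr = tab[1, 2],
                  excl_disr = tab[2, 1], excl_nondisr = tab[2, 2]))
  }
  ft <- fisher.test(tab, alternative = alternative)
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         incl_disr = tab[1, 1], incl_nondisr = tab[1, 2],
         excl_disr = tab[2, 1], excl_nondisr = tab[2, 2])
}
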