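# in-code fixtures shared across test files

# minimal valid event row(s); override any field via ...
make_events <- function(n = 1, ...) {
  ev <- tibble::tibble(
    event_id = sprintf("ev%03d", seq_len(n)),
    gene = sprintf("GENE%03d", seq_len(n)),
    event_class = "CE",
    chrom = "chr1",
    start = 100L + 1000L * (seq_len(n) - 1L),
    end = 200L + 1000L * (seq_len(n) - 1L),
    strand = "+",
    p_value = 0.01,
    inclusion_reads = 10L,
    exclusion_reads = 10L,
    psi_treated = 0.6,
    psi_control = 0.4,
    delta_psi = 0.2
  )
  over <- list(...)
  for (nm in names(over)) ev[[nm]] <- over[[nm]]
  ev$delta_psi <- ev$psi_treated - ev$psi_control
  ev
}

# random event table for oracle-equivalence tests
random_events <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(1e6, n)
  ev <- tibble::tibble(
    event_id = sprintf("r%06d", seq_len(n)),
    gene = sprintf("G%05d", sample.int(n, n, replace = TRUE)),
    event_class = sample(c("CE", "RI", "MXE", "A3SS", "A5SS"), n, TRUE),
    chrom = sample(paste0("chr", 1:5), n, TRUE),
    start = start,
    end = start + sample(50:500, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    p_value = runif(n),
    inclusion_reads = rpois(n, 5),
    exclusion_reads = rpois(n, 5),
    psi_treated = runif(n),
    psi_control = runif(n)
  )
  ev$delta_psi <- ev$psi_treated - ev$psi_control
  ev
}

# independent row-by-row re-check of the five significance clauses
brute_force_filter <- function(events, th = default_config()$thresholds) {
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    keep[i] <- e$p_value <= th$p_max &&
      e$inclusion_reads >= th$min_inc_reads &&
      e$exclusion_reads >= th$min_exc_reads &&
      (e$inclusion_reads + e$exclusion_reads) >= th$min_total_reads &&
      abs(e$delta_psi) >= th$min_abs_dpsi
  }
  events[keep, ]
}

# direct hypergeometric upper-tail summation from binomial coefficients,
# independent of phyper
brute_force_tail <- function(N, K, n, k) {
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# replicate-average a simulated plate into a per-dose series
average_series <- function(plate) {
  dplyr::summarise(dplyr::group_by(plate, dose),
                   response = mean(response), .groups = "drop")
}

# toy transcript models: a canonical three-exon transcript, a skipping
# transcript, and a single-exon inclusion transcript on chr1:+
toy_transcripts <- function() {
  tibble::tibble(
    transcript_id = c("tx_incl", "tx_skip", "tx_skip", "tx_canon",
                      "tx_canon", "tx_canon"),
    gene = "G1", chrom = "chr1", strand = "+",
    exon_start = c(0, 0, 400, 0, 100, 400),
    exon_end = c(500, 80, 500, 80, 200, 500),
    is_canonical = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    coding_start = 0
  )
}
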