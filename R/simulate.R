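#' Simulate per-sample splice-event tables with planted shared events
#'
#' Generates one event table per sample in the native representation, with a
#' planted fraction of events that (a) pass every significance filter in
#' every sample and (b) carry identical coordinates, class and strand across
#' samples so that cross-sample consolidation recovers exactly the planted
#' set. Background events are given sample-specific coordinates (offset
#' blocks, so spurious reciprocal-overlap matches cannot occur) and each
#' fails at least one filter, drawn at random among the five filter clauses.
#' Background p-values are uniform; planted p-values follow a Beta
#' concentrated near zero, rescaled below the significance cutoff (the
#' standard p-value mixture model).
#'
#' @param n_events Events per sample table.
#' @param n_samples Number of samples (cell lines).
#' @param frac_shared_significant Fraction of events planted as shared
#'   significant events.
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A list with `tables` (list of event tibbles, one per sample) and
#'   `truth` (list with `shared_significant_event_ids`).
#' @export
sim_ase_tables <- function(n_events = 1000, n_samples = 3,
                           frac_shared_significant = 0.05, seed = 1) {
  stopifnot(n_events >= 1, n_samples >= 1,
            frac_shared_significant >= 0, frac_shared_significant <= 1)
  withr_seed(seed)
  n_shared <- round(n_events * frac_shared_significant)
  classes <- event_classes()

  # planted events: one coordinate block below 1e7, identical across samples
  shared <- NULL
  if (n_shared > 0) {
    len <- sample(c(seq(51, 500), seq(51, 499, by = 3)), n_shared, replace = TRUE)
    start <- sample.int(9e6, n_shared) + 1000L
    sign <- sample(c(-1, 1), n_shared, replace = TRUE)
    mag <- 0.10 + 0.40 * rbeta(n_shared, 2, 2)
    dpsi <- sign * mag
    lo <- pmax(0, -dpsi)
    hi <- pmin(1, 1 - dpsi)
    psi_c <- lo + runif(n_shared) * (hi - lo)
    shared <- tibble(
      event_id = sprintf("shared%04d", seq_len(n_shared)),
      gene = sprintf("GENES%04d", seq_len(n_shared)),
      event_class = sample(classes, n_shared, replace = TRUE),
      chrom = sample(paste0("chr", 1:22), n_shared, replace = TRUE),
      start = as.integer(start), end = as.integer(start + len),
      strand = sample(c("+", "-"), n_shared, replace = TRUE),
      dpsi0 = dpsi, psi_c0 = psi_c
    )
  }

  tables <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    n_bg <- n_events - n_shared
    # background coordinates live on a per-sample offset grid: starts are
    # multiples of 10000 plus a sample offset, lengths <= 500, so events from
    # different samples can never reach 95% reciprocal overlap
    bg_start <- 1e7 + sample.int(5e4, n_bg) * 10000 + s * 1000
    bg_len <- sample(50:500, n_bg, replace = TRUE)
    fail_mode <- sample(5, n_bg, replace = TRUE)
    p <- runif(n_bg)
    inc <- 1L + rpois(n_bg, 15)
    exc <- 1L + rpois(n_bg, 15)
    dpsi <- runif(n_bg, -1, 1) * 0.5
    p[fail_mode == 1] <- 0.05 + runif(sum(fail_mode == 1)) * 0.95
    inc[fail_mode == 2] <- 0L
    exc[fail_mode == 3] <- 0L
    if (any(fail_mode == 4)) {
      k <- sum(fail_mode == 4)
      inc[fail_mode == 4] <- sample(1:4, k, replace = TRUE)
      exc[fail_mode == 4] <- pmax(1L, 9L - inc[fail_mode == 4] -
                                    sample(0:3, k, replace = TRUE))
    }
    dpsi[fail_mode == 5] <- runif(sum(fail_mode == 5), -0.099, 0.099)
    lo <- pmax(0, -dpsi); hi <- pmin(1, 1 - dpsi)
    psi_c <- lo + runif(n_bg) * (hi - lo)
    bg <- tibble(
      event_id = sprintf("s%d_bg%05d", s, seq_len(n_bg)),
      gene = sprintf("GENEB%05d", sample.int(5 * n_bg, n_bg)),
      event_class = sample(classes, n_bg, replace = TRUE),
      chrom = sample(paste0("chr", 1:22), n_bg, replace = TRUE),
      start = as.integer(bg_start), end = as.integer(bg_start + bg_len),
      strand = sample(c("+", "-"), n_bg, replace = TRUE),
      p_value = p,
      inclusion_reads = as.integer(inc), exclusion_reads = as.integer(exc),
      psi_control = psi_c, psi_treated = pmin(1, pmax(0, psi_c + dpsi))
    )
    bg$delta_psi <- bg$psi_treated - bg$psi_control
    if (n_shared > 0) {
      sh <- shared
      noise <- pmin(0.05, pmax(-0.05, rnorm(n_shared, 0, 0.01)))
      # keep |dPSI| >= 0.10 in every sample: perturb magnitude, not sign
      mag_s <- pmax(0.10, abs(sh$dpsi0) + noise)
      dpsi_s <- sign(sh$dpsi0) * pmin(mag_s, 1)
      lo <- pmax(0, -dpsi_s); hi <- pmin(1, 1 - dpsi_s)
      psi_c <- pmin(hi, pmax(lo, sh$psi_c0))
      sh_tbl <- tibble(
        event_id = sh$event_id, gene = sh$gene,
        event_class = sh$event_class, chrom = sh$chrom,
        start = sh$start, end = sh$end, strand = sh$strand,
        p_value = 0.05 * rbeta(n_shared, 0.5, 5),
        inclusion_reads = as.integer(5L + rpois(n_shared, 20)),
        exclusion_reads = as.integer(5L + rpois(n_shared, 20)),
        psi_control = psi_c, psi_treated = psi_c + dpsi_s
      )
      sh_tbl$delta_psi <- sh_tbl$psi_treated - sh_tbl$psi_control
      bg <- bind_rows(sh_tbl, bg)
    }
    tables[[s]] <- validate_events(bg[, event_columns()])
  }
  list(
    tables = tables,
    truth = list(
      shared_significant_event_ids =
        if (n_shared > 0) shared$event_id else character(0)
    )
  )
}

#' Simulate a baseline PSI matrix with a planted responder signature
#'
#' Emulates baseline (untreated) PSI quantification across a cohort of cell
#' lines labelled good or poor responders. Signature events have group means
#' separated by `delta` (positive-dPSI events higher in good responders,
#' negative-dPSI events higher in poor responders, in the printed 29:16
#' proportion by default); non-signature events share a single mean. Noise
#' is Gaussian on the PSI scale, clipped to \[0, 1\]; entries are set
#' missing independently at `missing_rate`. Cohort defaults are the study's
#' 19 good and 12 poor responder lines.
#'
#' @param n_events Total number of events in the matrix.
#' @param n_good,n_poor Samples per responder group.
#' @param n_signature Number of planted signature events.
#' @param prop_positive Fraction of signature events with dPSI > 0
#'   (good minus poor); default 29/45.
#' @param delta Planted mean PSI separation between groups, in (0, 1\].
#' @param within_sd Within-group PSI standard deviation.
#' @param missing_rate Independent missingness probability per cell.
#' @param seed Integer seed.
#'
#' @return A list with `psi` (wide tibble: `event_id`, `gene`, sample
#'   columns), `labels` (tibble `sample_id`, `responder`) and `truth`
#'   (planted ids, signs and group means).
#' @export
sim_baseline_psi <- function(n_events = 1000, n_good = 19, n_poor = 12,
                             n_signature = 45, prop_positive = 29 / 45,
                             delta = 0.3, within_sd = 0.05,
                             missing_rate = 0.1, seed = 1) {
  stopifnot(n_signature <= n_events, delta > 0, delta <= 1, within_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  withr_seed(seed)
  samples <- c(sprintf("G%03d", seq_len(n_good)),
               sprintf("P%03d", seq_len(n_poor)))
  responder <- c(rep("good", n_good), rep("poor", n_poor))
  n_pos <- round(n_signature * prop_positive)
  sig_sign <- c(rep(1, n_pos), rep(-1, n_signature - n_pos))
  is_sig <- seq_len(n_events) <= n_signature

  base_mean <- runif(n_events, 0.5 - (1 - delta) / 2, 0.5 + (1 - delta) / 2)
  mean_good <- base_mean
  mean_poor <- base_mean
  if (n_signature > 0) {
    mean_good[is_sig] <- base_mean[is_sig] + sig_sign * delta / 2
    mean_poor[is_sig] <- base_mean[is_sig] - sig_sign * delta / 2
  }
  mu <- cbind(matrix(mean_good, n_events, n_good),
              matrix(mean_poor, n_events, n_poor))
  vals <- matrix(pmin(1, pmax(0, mu + rnorm(length(mu), 0, within_sd))),
                 nrow = n_events)
  if (missing_rate > 0) {
    vals[runif(length(vals)) < missing_rate] <- NA_real_
  }
  colnames(vals) <- samples
  psi <- bind_cols(
    tibble(event_id = sprintf("ev%05d", seq_len(n_events)),
           gene = sprintf("GENE%05d", seq_len(n_events))),
    as_tibble(vals)
  )
  list(
    psi = psi,
    labels = tibble(sample_id = samples, responder = responder),
    truth = list(
      signature_event_ids = psi$event_id[is_sig],
      signature_sign = if (n_signature > 0) sig_sign else numeric(0),
      mean_good = mean_good, mean_poor = mean_poor
    )
  )
}

#' Simulate a dose-response series on the nine-point half-log dose ladder
#'
#' Doses are the nine half-log concentrations 3, 10, 30, 100, 300 nM and
#' 1, 3, 10, 30 uM used in the dose-response assays. The response (fraction
#' of DMSO control) follows a descending Hill curve with top fixed at 1:
#' `e_inf + (1 - e_inf) / (1 + (dose / ec50)^hill)`, plus Gaussian noise per
#' replicate.
#'
#' @param ec50 True EC50 in molar units.
#' @param hill Hill slope.
#' @param e_inf Response floor at infinite dose, in \[0, 1\].
#' @param noise_sd Gaussian noise standard deviation on the response scale.
#' @param n_replicates Replicates per dose.
#' @param sample_id,compound Identifier columns for the output.
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id`, `compound`, `dose`, `replicate`,
#'   `response`.
#' @export
sim_dose_response <- function(ec50 = 1e-8, hill = 1, e_inf = 0,
                              noise_sd = 0.02, n_replicates = 3,
                              sample_id = "G001", compound = "LLY-283",
                              seed = 1) {
  stopifnot(ec50 > 0, e_inf >= 0, e_inf <= 1, noise_sd >= 0)
  withr_seed(seed)
  doses <- dose_ladder()
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(n_replicates))
  mu <- hill_response(grid$dose, ec50, hill, e_inf)
  tibble(
    sample_id = sample_id, compound = compound,
    dose = grid$dose, replicate = grid$replicate,
    response = pmax(0, mu + rnorm(nrow(grid), 0, noise_sd))
  )
}

#' The nine-concentration dose ladder (molar)
#' @return Numeric vector of nine doses from 3 nM to 30 uM.
#' @export
dose_ladder <- function() {
  c(3e-9, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5, 3e-5)
}

hill_response <- function(dose, ec50, hill, e_inf) {
  e_inf + (1 - e_inf) / (1 + (dose / ec50)^hill)
}

#' Simulate a protein fold-change table with planted depletion
#'
#' Draws null log2 fold changes for a universe of proteins and shifts a
#' planted fraction of a designated ASE-affected gene set negative so those
#' genes concentrate among the most downregulated ranks. A small fraction of
#' proteins is flagged undetected (missing fold change); downstream ranking
#' assigns those a log2 fold change of zero.
#'
#' @param n_universe Universe size (default: the 5355 detected proteins).
#' @param ase_genes Character vector of gene ids forming the ASE set, or an
#'   integer giving the set size (genes sampled from the universe).
#' @param frac_depleted_in_set Fraction of the set shifted negative.
#' @param shift Mean downward log2FC shift applied to depleted set members.
#' @param null_sd Standard deviation of the null log2FC distribution.
#' @param undetected_rate Fraction of proteins flagged undetected.
#' @param seed Integer seed.
#'
#' @return A list with `proteins` (tibble `gene`, `log2fc`, `detected`),
#'   `gene_set` (character) and `truth` (depleted gene ids).
#' @export
sim_proteome <- function(n_universe = 5355, ase_genes = 194,
                         frac_depleted_in_set = 0.25, shift = 3,
                         null_sd = 0.5, undetected_rate = 0.02, seed = 1) {
  withr_seed(seed)
  genes <- sprintf("PROT%05d", seq_len(n_universe))
  if (is.numeric(ase_genes) && length(ase_genes) == 1) {
    stopifnot(ase_genes <= n_universe)
    gene_set <- sample(genes, ase_genes)
  } else {
    stopifnot(all(ase_genes %in% genes))
    gene_set <- as.character(ase_genes)
  }
  lfc <- rnorm(n_universe, 0, null_sd)
  names(lfc) <- genes
  n_dep <- round(length(gene_set) * frac_depleted_in_set)
  depleted <- if (n_dep > 0) sample(gene_set, n_dep) else character(0)
  lfc[depleted] <- lfc[depleted] - shift
  detected <- runif(n_universe) >= undetected_rate
  proteins <- tibble(
    gene = genes,
    log2fc = ifelse(detected, unname(lfc), NA_real_),
    detected = detected
  )
  list(proteins = proteins, gene_set = gene_set,
       truth = list(enriched_gene_ids = depleted))
}

#' Simulate a limiting-dilution design under the single-hit model
#'
#' Seeds the printed ten-step dilution series (2000, 1000, 500, 250, 125,
#' 63, 31, 16, 8, 4 cells per well; the odd numbers are the rounded halving
#' series as plated) with six technical replicate wells per dose. Each well
#' is positive for sphere formation independently with probability
#' `1 - exp(-true_f * dose)`, the single-hit Poisson model.
#'
#' @param true_f True sphere-forming (active cell) frequency in (0, 1\].
#' @param doses Cells per well.
#' @param wells Replicate wells per dose.
#' @param arm Arm label.
#' @param seed Integer seed.
#'
#' @return A tibble with `arm`, `cells_per_well`, `wells`, `positive_wells`.
#' @export
sim_lda <- function(true_f = 0.01,
                    doses = c(2000, 1000, 500, 250, 125, 63, 31, 16, 8, 4),
                    wells = 6, arm = "treated", seed = 1) {
  stopifnot(true_f > 0, true_f <= 1, all(doses > 0), wells >= 1)
  withr_seed(seed)
  p_pos <- 1 - exp(-true_f * doses)
  tibble(
    arm = arm, cells_per_well = doses, wells = as.integer(wells),
    positive_wells = rbinom(length(doses), wells, p_pos)
  )
}

#' Simulate a capillary-electrophoresis amplicon peak table
#'
#' Emits the long and short isoform peaks for one assay/sample at the given
#' true PSI (long-isoform concentration `true_psi * total_conc`, short
#' `(1 - true_psi) * total_conc`), plus optional spurious noise peaks, each
#' below 10% of the total concentration and at sizes distinct from the two
#' isoforms.
#'
#' @param true_psi True fraction spliced in, in \[0, 1\].
#' @param total_conc Total isoform concentration (arbitrary units).
#' @param n_noise_peaks Number of spurious peaks.
#' @param long_size,short_size Amplicon sizes (bp) of the two isoforms.
#' @param assay_id,sample_id,condition Identifier columns.
#' @param seed Integer seed.
#'
#' @return A peak tibble (`assay_id`, `sample_id`, `condition`, `size_bp`,
#'   `concentration`). Zero-concentration isoform peaks are omitted.
#' @export
sim_amplicons <- function(true_psi = 0.5, total_conc = 100, n_noise_peaks = 0,
                          long_size = 300, short_size = 200,
                          assay_id = "assay1", sample_id = "G001",
                          condition = "treated", seed = 1) {
  stopifnot(true_psi >= 0, true_psi <= 1, total_conc > 0,
            long_size > short_size)
  withr_seed(seed)
  pk <- tibble(
    assay_id = assay_id, sample_id = sample_id, condition = condition,
    size_bp = c(long_size, short_size),
    concentration = c(true_psi, 1 - true_psi) * total_conc
  )
  if (n_noise_peaks > 0) {
    sizes <- setdiff(seq(50, 1000, by = 7), c(long_size, short_size))
    pk <- bind_rows(pk, tibble(
      assay_id = assay_id, sample_id = sample_id, condition = condition,
      size_bp = sample(sizes, n_noise_peaks),
      concentration = runif(n_noise_peaks, 0, 0.099) * total_conc
    ))
  }
  pk[pk$concentration > 0 | seq_len(nrow(pk)) > 2, ]
}

# seed helper: scoped RNG so generators do not disturb the caller's stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(seed)
}
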