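# gliosplice

Analysis toolkit for linking alternative-splicing disruption to PRMT5-inhibitor
response in patient-derived glioblastoma stem cell (GSC) lines.

PRMT5 inhibition broadly disrupts pre-mRNA splicing. In GSC panels this shows
up as thousands of differential alternative splicing events (ASEs) after
treatment, depletion of the proteins encoded by affected genes, loss of
sphere-forming (self-renewal) capacity, and a spread of drug sensitivities
across lines that can be predicted from baseline splicing patterns.
`gliosplice` implements the quantitative spine of that analysis as a set of
tibble-in / tibble-out functions, so each stage can be run, tested, and
audited on its own — and a synthetic-data module generates every input shape
with planted ground truth, so the whole pipeline is exercisable without
controlled-access patient data.

## What it computes

- **ASE filtering** — keep events with p ≤ 0.05, ≥ 1 inclusion read,
  ≥ 1 exclusion read, ≥ 10 total reads and |ΔPSI| ≥ 0.10 (all inclusive);
  consolidate events across samples requiring a 95% reciprocal coordinate
  overlap, same strand and same event class; classify predicted protein
  impact (frameshift by segment length mod 3, in-frame stop-codon scan);
  test association between splicing direction and ORF disruption (Fisher).
- **RT-PCR PSI** — from capillary-electrophoresis amplicon tables: per assay,
  the two most abundant amplicon sizes across all samples are the isoforms,
  and PSI = L / (L + S) for the long (L) and short (S) concentrations.
- **Dose–response** — readout timepoint at the 95th percentile of DMSO
  time-to-confluence; response normalized to DMSO and clipped to [0, 1];
  AAC as the trapezoidal integral of (1 − response) over log10 dose,
  normalized to the tested range (0 = no effect, 1 = complete kill); Hill
  fits with top fixed at 1 giving EC50; sensitivity call at EC50 < 250 nM;
  good/poor responder split on cohort-median AAC.
- **Splicing-response signature** — baseline PSI events quantifiable in
  ≥ 75% of lines, with intra-group sd < inter-group sd and
  |mean PSI difference| ≥ 0.20 between good and poor responders, ranked by
  |dPSI|; plus a per-sample signature score for classification.
- **Proteome enrichment** — proteins ranked by mean log2 fold change
  (undetected set to 0); gene-set enrichment among the top-k most
  downregulated as fold = k / (n·K/N) with one-sided hypergeometric p;
  bootstrap SE of the fold over row resamples; the signed GSEA ranking
  statistic sign(LFC)·(−log10 adj p) with randomized infinity handling.
- **Limiting dilution** — single-hit model P(negative | d cells) = exp(−f·d)
  fitted as a binomial GLM with complementary log-log link and log(dose)
  offset; Wald 95% CI on log f; likelihood-ratio test for frequency
  inequality between arms; adequacy test of the single-hit slope.

## Worked example

```r
library(gliosplice)

# three treated GSC lines, 1000 events each, 5% planted shared events
sim <- sim_ase_tables(n_events = 1000, n_samples = 3,
                      frac_shared_significant = 0.05, seed = 42)
filtered <- lapply(sim$tables, filter_significant)
common <- consolidate_events(filtered)
cat(attr(common, "n_events"), "common events in", attr(common, "n_genes"), "genes\n")
#> 50 common events in 50 genes

# proteome depletion enrichment at the study margins
hyper_enrichment(N = 5355, K = 194, n = 50, k = 12)
#>      N   K  n  k expected fold  p_value
#> 1 5355 194 50 12     1.81 6.62 1.32e-07

# dose-response scoring of a simulated line (true EC50 20 nM)
plate <- sim_dose_response(ec50 = 2e-8, hill = 1, e_inf = 0.05,
                           noise_sd = 0.02, seed = 42)
summarise_dose_response(plate)
#>   sample_id compound   aac     ec50  hill  e_inf
#> 1      G001  LLY-283 0.736 2.21e-08 0.976 0.0421

# sphere-forming frequency from a limiting-dilution plate (true f = 0.01)
fit_single_hit(sim_lda(true_f = 0.01, seed = 42))
#> Single-hit limiting-dilution fit
#>   frequency: 0.008981  (1 in 111.3 cells)
#>   95% CI: 0.005325 - 0.01515
#>   single-hit adequacy p: 0.887
```

The 50 consolidated events are exactly the planted shared set; the
enrichment row says 12 observed set members in the top 50 against 1.81
expected — a 6.6-fold enrichment at p = 1.3e-7; the Hill fit recovers the
20 nM EC50 within noise; and the limiting-dilution fit brackets the true
frequency of 1 in 100 cells inside its 95% CI.

Every stage is also scriptable through the bundled CLI
(`system.file("cli", "gliosplice", package = "gliosplice")`), with
subcommands `simulate`, `filter-ase`, `consolidate`, `impact`, `psi-rtpcr`,
`dose-response`, `signature`, `enrich`, `gsea-rank` and `lda`.

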