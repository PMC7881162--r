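#' Splice-event table I/O
#'
#' Reads a per-sample table of alternative splicing events (ASEs) into the
#' native tibble representation: one row per event with columns `event_id`,
#' `gene`, `event_class` (one of CE, RI, MXE, A3SS, A5SS), `chrom`, `start`,
#' `end`, `strand`, `p_value`, `inclusion_reads`, `exclusion_reads`,
#' `psi_treated`, `psi_control`, `delta_psi`. Coordinates are stored 0-based
#' half-open internally (BED convention), which removes off-by-one ambiguity
#' when events are exported and intersected.
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`native`}{the package's own TSV with the columns above, 0-based
#'     half-open.}
#'   \item{`mats_like`}{rMATS-style columns (`ID`, `GeneID`, `chr`, `strand`,
#'     `exonStart_0base`, `exonEnd`, `PValue`, `IJC_SAMPLE_1`,
#'     `SJC_SAMPLE_1`, `IncLevel1`, `IncLevel2`, `event_type`); coordinates
#'     already 0-based. `IncLevel1` is the treated PSI, `IncLevel2` control.}
#'   \item{`irfinder_like`}{IRFinder-style retained-intron columns (`Chr`,
#'     `Start`, `End`, `Gene`, `Strand`, `PValue`, `IntronDepth`,
#'     `SpliceExact`, `IRratio_treated`, `IRratio_control`); 1-based
#'     inclusive coordinates, converted on read.}
#' }
#'
#' @param path Path to a tab-separated event table.
#' @param dialect One of `"native"`, `"mats_like"`, `"irfinder_like"`.
#'
#' @return A tibble of validated splice events.
#' @seealso [write_event_table()], [write_bed()], [filter_significant()]
#' @export
read_event_table <- function(path,
                             dialect = c("native", "mats_like", "irfinder_like")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ev <- switch(dialect,
    native = {
      require_columns(raw, event_columns(), "native event table")
      as_tibble(raw)
    },
    mats_like = {
      need <- c("ID", "GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
                "PValue", "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncLevel1",
                "IncLevel2", "event_type")
      require_columns(raw, need, "mats_like event table")
      tibble(
        event_id = as.character(raw$ID),
        gene = as.character(raw$GeneID),
        event_class = as.character(raw$event_type),
        chrom = as.character(raw$chr),
        start = as.integer(raw$exonStart_0base),
        end = as.integer(raw$exonEnd),
        strand = as.character(raw$strand),
        p_value = raw$PValue,
        inclusion_reads = as.integer(raw$IJC_SAMPLE_1),
        exclusion_reads = as.integer(raw$SJC_SAMPLE_1),
        psi_treated = raw$IncLevel1,
        psi_control = raw$IncLevel2,
        delta_psi = raw$IncLevel1 - raw$IncLevel2
      )
    },
    irfinder_like = {
      need <- c("Chr", "Start", "End", "Gene", "Strand", "PValue",
                "IntronDepth", "SpliceExact", "IRratio_treated",
                "IRratio_control")
      require_columns(raw, need, "irfinder_like event table")
      tibble(
        event_id = paste0(raw$Chr, ":", raw$Start, "-", raw$End, ":", raw$Strand),
        gene = as.character(raw$Gene),
        event_class = "RI",
        chrom = as.character(raw$Chr),
        start = as.integer(raw$Start) - 1L,  # 1-based inclusive -> 0-based half-open
        end = as.integer(raw$End),
        strand = as.character(raw$Strand),
        p_value = raw$PValue,
        inclusion_reads = as.integer(raw$IntronDepth),
        exclusion_reads = as.integer(raw$SpliceExact),
        psi_treated = raw$IRratio_treated,
        psi_control = raw$IRratio_control,
        delta_psi = raw$IRratio_treated - raw$IRratio_control
      )
    }
  )
  validate_events(ev)
}

event_columns <- function() {
  c("event_id", "gene", "event_class", "chrom", "start", "end", "strand",
    "p_value", "inclusion_reads", "exclusion_reads", "psi_treated",
    "psi_control", "delta_psi")
}

event_classes <- function() c("CE", "RI", "MXE", "A3SS", "A5SS")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "gliosplice_schema_error")
  }
  invisible(df)
}

#' Validate a splice-event tibble
#'
#' Checks the event invariants: `start < end`, p-values and PSI values in
#' \[0, 1\], non-negative read counts, recognised event classes and strands,
#' and `delta_psi` consistent with `psi_treated - psi_control` to 1e-9.
#' Errors name the offending row.
#'
#' @param events A tibble of splice events.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_events <- function(events) {
  require_columns(events, event_columns(), "event table")
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      abort(sprintf("invalid event at row %d: %s", i[1], msg),
            class = "gliosplice_validation_error")
    }
  }
  bad_row(!(events$event_class %in% event_classes()),
          "event_class must be one of CE, RI, MXE, A3SS, A5SS")
  bad_row(!(events$strand %in% c("+", "-")), "strand must be '+' or '-'")
  bad_row(events$start >= events$end, "start must be < end (0-based half-open)")
  bad_row(events$p_value < 0 | events$p_value > 1, "p_value outside [0, 1]")
  bad_row(events$inclusion_reads < 0 | events$exclusion_reads < 0,
          "read counts must be non-negative")
  for (col in c("psi_treated", "psi_control")) {
    bad_row(events[[col]] < 0 | events[[col]] > 1,
            sprintf("%s outside [0, 1]", col))
  }
  bad_row(abs(events$delta_psi - (events$psi_treated - events$psi_control)) > 1e-9,
          "delta_psi inconsistent with psi_treated - psi_control")
  events
}

#' @rdname read_event_table
#' @param events A tibble of splice events in the native representation.
#' @export
write_event_table <- function(events, path) {
  validate_events(events)
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Export splice events as BED6
#'
#' Writes one BED6 line per event (`chrom`, `start`, `end`, `event_id`,
#' score 0, `strand`), 0-based half-open, supporting bedtools-style
#' coordinate intersection against external event catalogues.
#'
#' @param events A tibble of splice events.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(events, path) {
  if (nrow(events)) validate_events(events)
  bed <- tibble(
    chrom = events$chrom, start = events$start, end = events$end,
    name = events$event_id, score = 0L, strand = events$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' PSI matrix and responder-label I/O
#'
#' The PSI matrix is a wide TSV: one row per event with `event_id` and
#' `gene`, then one numeric column per sample holding percent-spliced-in
#' values as fractions in \[0, 1\] (empty cells are missing). Responder
#' labels are a two-column TSV (`sample_id`, `responder` in
#' \{`good`, `poor`\}).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_psi_matrix <- function(path) {
  stopifnot(file.exists(path))
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(m, c("event_id", "gene"), "PSI matrix")
  num <- setdiff(names(m), c("event_id", "gene"))
  vals <- unlist(m[num], use.names = FALSE)
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("PSI matrix contains values outside [0, 1]",
          class = "gliosplice_validation_error")
  }
  m
}

#' @rdname read_psi_matrix
#' @param psi A wide PSI tibble as returned by [read_psi_matrix()].
#' @export
write_psi_matrix <- function(psi, path) {
  readr::write_tsv(psi, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_psi_matrix
#' @export
read_labels <- function(path) {
  stopifnot(file.exists(path))
  lab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(lab, c("sample_id", "responder"), "label table")
  if (!all(lab$responder %in% c("good", "poor"))) {
    abort("responder labels must be 'good' or 'poor'",
          class = "gliosplice_validation_error")
  }
  lab
}

#' @rdname read_psi_matrix
#' @param labels A tibble with `sample_id` and `responder` columns.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Amplicon peak-table I/O
#'
#' Capillary-electrophoresis peak tables hold one row per detected amplicon:
#' `assay_id` (primer pair / event), `sample_id`, `condition`, `size_bp`,
#' `concentration` (non-negative, arbitrary units).
#'
#' @param path File path.
#' @return A tibble of peaks.
#' @export
read_peak_table <- function(path) {
  stopifnot(file.exists(path))
  pk <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(pk, c("assay_id", "sample_id", "condition", "size_bp",
                        "concentration"), "peak table")
  if (any(pk$size_bp <= 0)) abort("amplicon size_bp must be positive")
  if (any(pk$concentration < 0)) abort("peak concentration must be >= 0")
  pk
}

#' @rdname read_peak_table
#' @param peaks A peak tibble.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}

#' Dose-response plate I/O
#'
#' Plate readouts are CSV with columns `sample_id`, `compound`, `dose`
#' (molar), `replicate`, `response` (fraction of the DMSO control).
#'
#' @param path File path.
#' @return A tibble of plate readings.
#' @export
read_plate <- function(path) {
  stopifnot(file.exists(path))
  pl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(pl, c("sample_id", "compound", "dose", "replicate",
                        "response"), "plate table")
  if (any(pl$dose <= 0)) abort("doses must be positive")
  pl
}

#' @rdname read_plate
#' @param plate A plate tibble.
#' @export
write_plate <- function(plate, path) {
  readr::write_csv(plate, path, progress = FALSE)
  invisible(path)
}

#' Protein fold-change table I/O
#'
#' One row per protein-coding gene: `gene`, `log2fc` (mean log2 fold change
#' active vs inactive compound; may be missing for undetected proteins) and
#' a logical `detected` flag.
#'
#' @param path File path.
#' @return A tibble of proteins.
#' @export
read_protein_table <- function(path) {
  stopifnot(file.exists(path))
  pr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(pr, c("gene", "log2fc", "detected"), "protein table")
  pr$detected <- as.logical(pr$detected)
  pr
}

#' @rdname read_protein_table
#' @param proteins A protein tibble.
#' @export
write_protein_table <- function(proteins, path) {
  readr::write_tsv(proteins, path, progress = FALSE)
  invisible(path)
}

#' Limiting-dilution table I/O
#'
#' One row per (arm, dose): `arm`, `cells_per_well`, `wells`,
#' `positive_wells`.
#'
#' @param path File path.
#' @return A tibble of limiting-dilution counts.
#' @export
read_lda_table <- function(path) {
  stopifnot(file.exists(path))
  ld <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(ld, c("arm", "cells_per_well", "wells", "positive_wells"),
                  "limiting-dilution table")
  if (any(ld$positive_wells < 0 | ld$positive_wells > ld$wells)) {
    abort("positive_wells must lie in [0, wells]",
          class = "gliosplice_validation_error")
  }
  ld
}

#' @rdname read_lda_table
#' @param design A limiting-dilution tibble.
#' @export
write_lda_table <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}
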