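#' Default pipeline configuration
#'
#' Returns the configuration used throughout the pipeline: the significance
#' thresholds applied to alternative splicing events, the reciprocal-overlap
#' fraction for cross-sample event matching, the signature selection criteria,
#' the EC50 cutoff for calling a line sensitive, and the bootstrap resampling
#' count. Values mirror the analysis constants: ASE p-value at most 0.05, at
#' least one read on each of the inclusion and exclusion forms, at least 10
#' total supporting reads, |dPSI| at least 0.10, a 95% reciprocal overlap for
#' event identity, quantifiability in at least 75% of samples and a 20% mean
#' PSI difference for the signature, 250 nM EC50 for the sensitivity call and
#' 100 bootstrap resamplings.
#'
#' @param ... Named overrides for individual threshold entries or `seed`.
#'
#' @return A list with elements `seed` and `thresholds` (itself a named list).
#' @examples
#' cfg <- default_config(seed = 42)
#' cfg$thresholds$p_max
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    thresholds = list(
      p_max = 0.05,
      min_inc_reads = 1,
      min_exc_reads = 1,
      min_total_reads = 10,
      min_abs_dpsi = 0.10,
      min_reciprocal_overlap = 0.95,
      min_fraction_quantified = 0.75,
      min_signature_dpsi = 0.20,
      ec50_sensitive_nM = 250,
      bootstrap_B = 100
    )
  )
  dots <- list(...)
  if (length(dots)) {
    for (nm in names(dots)) {
      if (nm == "seed") cfg$seed <- as.integer(dots[[nm]])
      else cfg$thresholds[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  for (nm in c("p_max", "min_abs_dpsi", "min_reciprocal_overlap",
               "min_fraction_quantified", "min_signature_dpsi")) {
    v <- th[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("config threshold '%s' must lie in [0, 1], got %s", nm, v))
    }
  }
  if (th$min_total_reads < max(th$min_inc_reads, th$min_exc_reads)) {
    abort("min_total_reads must be >= max(min_inc_reads, min_exc_reads)")
  }
  if (th$bootstrap_B < 1) abort("bootstrap_B must be >= 1")
  invisible(cfg)
}

#' Read and write pipeline configuration
#'
#' Configuration is stored as a flat YAML document. Values absent from the
#' file fall back to [default_config()] entries, so a partial file overriding
#' a single threshold is valid.
#'
#' @param path Path to a YAML configuration file.
#' @param cfg A configuration list as returned by [default_config()].
#'
#' @return `read_config()` returns a validated configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  th <- raw$thresholds %||% raw[setdiff(names(raw), "seed")]
  for (nm in names(th)) cfg$thresholds[[nm]] <- th[[nm]]
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
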