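#' Pipeline configuration
#'
#' Central configuration object holding the grid, filtering, smoothing
#' and feature-window settings used across the pipeline. Defaults match
#' the published analysis conventions: 100-200 bp fragments, +/-5 kb
#' window in 15 bp bins, Savitzky-Golay smoothing over 165 bp (11 bins)
#' at order 3, central window +/-30 bp, mean window +/-1 kb, FFT window
#' +/-960 bp with frequency term 10, bin outlier cutoff at 10 SD,
#' mappability threshold 1.
#'
#' @param ... overrides for any default field (unknown names error).
#' @return A named list of class `GriffinConfig`.
#' @export
griffin_config <- function(...) {
  cfg <- list(
    fragment_range = c(100, 200),
    window = 5000,
    bin_size = 15,
    sg_window_bp = 165,
    sg_order = 3,
    central_halfwidth = 30,
    mean_halfwidth = 1000,
    trim_halfwidth = 1000,
    fft_halfwidth = 960,
    fft_term = 10,
    outlier_sd = 10,
    min_mapq = 20,
    mappability_threshold = 1.0,
    gc_correction = TRUE,
    mappability_correction = FALSE,
    cna_correction = FALSE,
    cna_halfwidth = 50000,
    gc_length_range = c(100, 200),
    smoothing_pool_bp = 10,
    classifier = list(n_iterations = 1000, cv_folds = 10,
                      pca_variance_target = NA_real_,
                      C_grid = c(1e-3, 1e-2, 1e-1, 1, 10, 100),
                      resample_unit = "sample"),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (nm == "classifier") {
      bad <- setdiff(names(dots$classifier), names(cfg$classifier))
      if (length(bad))
        stop("unknown configuration key(s): ",
             paste(paste0("classifier.", bad), collapse = ", "))
      cfg$classifier[names(dots$classifier)] <- dots$classifier
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if ((cfg$sg_window_bp / cfg$bin_size) %% 2 != 1)
    stop("sg_window_bp must span an odd number of bins")
  class(cfg) <- c("GriffinConfig", "list")
  cfg
}

#' Load and validate a YAML configuration file
#'
#' Unknown keys are an error (typos should fail loudly, not silently
#' fall back to defaults); values round-trip through
#' [write_config()] / [load_config()].
#'
#' @param path path to a YAML file of configuration overrides.
#' @return A `GriffinConfig`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(griffin_config, vals)
}

#' Serialize a configuration to YAML
#'
#' @param config a `GriffinConfig`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "GriffinConfig"))
  out <- unclass(config)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Embedded in output files so every result is traceable to the exact
#' settings that produced it.
#'
#' @param config a `GriffinConfig`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# header comment lines stamped into TSV outputs
provenance_header <- function(config) {
  c(sprintf("# griffin %s", as.character(utils::packageVersion("griffin"))),
    sprintf("# config_hash: %s", config_hash(config)))
}

#' Write a results table with provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config a `GriffinConfig`, stamped as comment lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, config = griffin_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
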