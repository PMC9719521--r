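#' Profile features
#'
#' Three features summarize a trimmed composite profile: central
#' coverage (mean over bins whose centers lie within +/-30 bp; lower
#' values mean more accessibility), mean coverage (+/-1 kb), and the
#' amplitude of the nucleosome periodicity, taken as the modulus of
#' frequency term 10 of the unnormalized forward DFT of the 128 bins
#' spanning +/-960 bp (period 192 bp, matching the ~190 bp nucleosome
#' spacing at active sites).
#'
#' @name features
NULL

# bins of a trimmed profile selected by center position
select_bins <- function(cp, halfwidth, config) {
  centers <- cp$offsets + config$bin_size / 2
  abs(centers) <= halfwidth
}

#' Central coverage
#'
#' @param cp a trimmed `CompositeProfile`.
#' @param config a `GriffinConfig`.
#' @return Mean of unmasked bins with centers within
#'   `config$central_halfwidth` of the site.
#' @export
central_coverage <- function(cp, config = griffin_config()) {
  v <- cp$values[select_bins(cp, config$central_halfwidth, config)]
  if (all(is.na(v))) stop("feature undefined: all central bins masked")
  mean(v, na.rm = TRUE)
}

#' Mean coverage
#'
#' @inheritParams central_coverage
#' @return Mean of unmasked bins with centers within
#'   `config$mean_halfwidth` of the site.
#' @export
mean_coverage <- function(cp, config = griffin_config()) {
  v <- cp$values[select_bins(cp, config$mean_halfwidth, config)]
  if (all(is.na(v))) stop("feature undefined: all bins masked")
  mean(v, na.rm = TRUE)
}

#' FFT amplitude of the nucleosome periodicity
#'
#' Modulus of coefficient index `config$fft_term` (0-indexed) of the
#' unnormalized forward DFT of the bins whose start offsets lie in
#' `[-fft_halfwidth, +fft_halfwidth)` — exactly 128 bins under the
#' default grid. All of those bins must be unmasked.
#'
#' @inheritParams central_coverage
#' @return Non-negative amplitude.
#' @export
fft_amplitude <- function(cp, config = griffin_config()) {
  sel <- cp$offsets >= -config$fft_halfwidth &
    cp$offsets < config$fft_halfwidth
  v <- cp$values[sel]
  if (anyNA(v)) stop("feature undefined: masked bins in the FFT window")
  Mod(stats::fft(v)[config$fft_term + 1])
}

#' All three features of a profile
#'
#' @inheritParams central_coverage
#' @return A one-row data.frame with `central_coverage`, `mean_coverage`
#'   and `amplitude`.
#' @export
profile_features <- function(cp, config = griffin_config()) {
  data.frame(central_coverage = central_coverage(cp, config),
             mean_coverage = mean_coverage(cp, config),
             amplitude = fft_amplitude(cp, config))
}

#' Assemble a cohort feature matrix
#'
#' Builds the samples x (site list x feature) matrix consumed by the
#' classifier. Column order is deterministic: site lists sorted by name,
#' features in the order central_coverage, mean_coverage, amplitude.
#' Samples missing any (site list, feature) cell are dropped with a
#' message.
#'
#' @param features long data.frame with columns `sample`, `site_list`,
#'   `central_coverage`, `mean_coverage`, `amplitude`.
#' @param metadata data.frame with column `sample` plus per-sample
#'   metadata (`label`, `tumor_fraction`, `patient_id`, optionally
#'   `timepoint`, `cohort`).
#' @return An object of class `FeatureMatrix`: list with `x` (numeric
#'   matrix) and `metadata` (rows aligned to `x`).
#' @export
assemble_feature_matrix <- function(features, metadata) {
  stopifnot(all(c("sample", "site_list", "central_coverage",
                  "mean_coverage", "amplitude") %in% names(features)),
            "sample" %in% names(metadata))
  lists <- sort(unique(features$site_list))
  feat_names <- c("central_coverage", "mean_coverage", "amplitude")
  samples <- unique(features$sample)
  x <- matrix(NA_real_, length(samples), length(lists) * 3,
              dimnames = list(samples,
                              paste(rep(lists, each = 3),
                                    rep(feat_names, length(lists)),
                                    sep = ".")))
  for (i in seq_len(nrow(features))) {
    r <- match(features$sample[i], samples)
    base <- (match(features$site_list[i], lists) - 1) * 3
    x[r, base + 1:3] <- as.numeric(features[i, feat_names])
  }
  complete <- !apply(x, 1, anyNA)
  if (any(!complete))
    message("dropping ", sum(!complete), " sample(s) with missing profiles: ",
            paste(samples[!complete], collapse = ", "))
  x <- x[complete, , drop = FALSE]
  md <- metadata[match(rownames(x), metadata$sample), , drop = FALSE]
  if (anyNA(md$sample)) stop("metadata missing for some samples")
  rownames(md) <- NULL
  structure(list(x = x, metadata = md), class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d samples x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Write a feature matrix with sidecar metadata
#'
#' @param fm a `FeatureMatrix`.
#' @param prefix output prefix; writes `<prefix>_features.tsv` and
#'   `<prefix>_metadata.tsv`.
#' @param config configuration stamped into the headers.
#' @return The two paths, invisibly.
#' @export
write_feature_matrix <- function(fm, prefix, config = griffin_config()) {
  fpath <- paste0(prefix, "_features.tsv")
  mpath <- paste0(prefix, "_metadata.tsv")
  df <- data.frame(sample = rownames(fm$x), fm$x, check.names = FALSE)
  write_result_tsv(df, fpath, config)
  write_result_tsv(fm$metadata, mpath, config)
  invisible(c(fpath, mpath))
}
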