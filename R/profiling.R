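#' Composite midpoint-coverage profiling
#'
#' Produces GC-corrected (optionally mappability- and CNA-corrected)
#' composite fragment-midpoint coverage profiles around a site list.
#' Fragments passing quality and length filters are weighted by the
#' inverse of their GC bias, their midpoints summed into 15 bp bins over
#' +/-5 kb around each site; bins overlapping excluded or not fully
#' mappable regions, or with extreme coverage, are masked; the per-bin
#' mean over sites is smoothed (Savitzky-Golay, 165 bp window, order 3),
#' normalized to mean 1 over the window, and trimmed to +/-1 kb.
#'
#' @name profiling
NULL

# constructor for composite profiles
composite_profile_obj <- function(values, offsets, state, provenance = list()) {
  structure(list(offsets = offsets, values = values, state = state,
                 provenance = provenance),
            class = "CompositeProfile")
}

#' @export
print.CompositeProfile <- function(x, ...) {
  cat(sprintf("CompositeProfile [%s]: %d bins, offsets %d..%d, %d masked\n",
              x$state, length(x$values), min(x$offsets), max(x$offsets),
              sum(is.na(x$values))))
  invisible(x)
}

#' Collect fragments around sites
#'
#' Fetches proper-pair fragments in a window around each site, applies
#' quality and fragment-length filters, and keeps fragments whose
#' midpoint falls on the profile bin grid. Sites too close to a
#' chromosome edge are skipped with a count.
#'
#' @param bam indexed BAM path.
#' @param sites a `SiteList`.
#' @param genome a `GenomeCache` (used for chromosome bounds and
#'   fragment GC).
#' @param window half-window (bp).
#' @param length_range fragment length range, inclusive.
#' @param min_mapq minimum mapping quality.
#' @param bin_size bin width (bp).
#' @return List with `fragments` (one element per retained site holding
#'   parallel vectors `start`, `end`, `length`, `midpoint`, `bin`),
#'   `sites` (retained site table) and `n_skipped_sites`.
#' @export
collect_fragments <- function(bam, sites, genome, window = 5000,
                              length_range = c(100, 200), min_mapq = 20,
                              bin_size = 15) {
  cache <- genome_cache(genome)
  st <- sites$sites
  fetch_pad <- window + length_range[2] + 10
  lens <- vapply(st$chrom, function(ch) chrom_length(cache, ch), numeric(1))
  ok_site <- st$position - fetch_pad >= 0 & st$position + fetch_pad <= lens
  n_skipped <- sum(!ok_site)
  if (n_skipped) warning(n_skipped, " site(s) too close to a contig edge, skipped")
  st <- st[ok_site, , drop = FALSE]
  if (nrow(st) == 0) stop("no usable sites")
  gr <- GenomicRanges::GRanges(st$chrom,
                               IRanges::IRanges(start = st$position - fetch_pad + 1,
                                                end = st$position + fetch_pad))
  res <- scan_fragments(bam, min_mapq = min_mapq, which = gr)
  grid <- bin_grid(window, bin_size)
  frags <- lapply(seq_len(nrow(st)), function(i) {
    f <- res[[i]]
    len <- f$end - f$start
    keep <- len >= length_range[1] & len <= length_range[2]
    start <- f$start[keep]; end <- f$end[keep]; len <- len[keep]
    mid <- (start + end - 1) %/% 2
    bin <- (mid - st$position[i] + window) %/% bin_size
    ongrid <- bin >= 0 & bin < grid$n
    list(start = start[ongrid], end = end[ongrid], length = len[ongrid],
         midpoint = mid[ongrid], bin = bin[ongrid])
  })
  list(fragments = frags, sites = st, n_skipped_sites = n_skipped,
       window = window, bin_size = bin_size)
}

#' Sum weighted fragment midpoints into bins
#'
#' @param collected output of [collect_fragments()].
#' @param weights list (parallel to `collected$fragments`) of per-fragment
#'   weights, or `NULL` for unweighted counts.
#' @return An object of class `SiteProfileSet`: matrices `counts`
#'   (weighted) and `raw` (unweighted), sites x bins, plus the grid.
#' @export
bin_midpoints <- function(collected, weights = NULL) {
  grid <- bin_grid(collected$window, collected$bin_size)
  n_sites <- length(collected$fragments)
  counts <- matrix(0, n_sites, grid$n)
  raw <- matrix(0, n_sites, grid$n)
  n_excluded <- 0
  for (i in seq_len(n_sites)) {
    f <- collected$fragments[[i]]
    if (length(f$bin) == 0) next
    w <- if (is.null(weights)) rep(1, length(f$bin)) else weights[[i]]
    stopifnot(length(w) == length(f$bin))
    n_excluded <- n_excluded + sum(w == 0)
    counts[i, ] <- as.numeric(tapply2(w, f$bin + 1, grid$n))
    raw[i, ] <- tabulate(f$bin + 1, nbins = grid$n)
  }
  structure(list(counts = counts, raw = raw, mask = matrix(FALSE, n_sites, grid$n),
                 sites = collected$sites, offsets = grid$starts,
                 bin_size = collected$bin_size, window = collected$window,
                 n_excluded_fragments = n_excluded),
            class = "SiteProfileSet")
}

# weighted tabulate
tapply2 <- function(w, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Mask unusable bins
#'
#' A bin is masked when it is not fully contained in a valid region
#' (i.e. it intersects an exclusion interval or contains a position of
#' mappability below threshold), or when its weighted coverage exceeds
#' `mean + outlier_sd * SD`, the statistic pooled over all bins of all
#' sites in the set.
#'
#' @param sps a `SiteProfileSet`.
#' @param valid a `RegionSet` of valid regions, or `NULL` to skip
#'   structural masking.
#' @param outlier_sd outlier cutoff in pooled standard deviations;
#'   `Inf` disables.
#' @return The `SiteProfileSet` with its `mask` updated (masked bins set
#'   `NA` in `counts`).
#' @export
mask_bins <- function(sps, valid = NULL, outlier_sd = 10) {
  stopifnot(inherits(sps, "SiteProfileSet"))
  mask <- sps$mask
  if (!is.null(valid)) {
    for (i in seq_len(nrow(sps$sites))) {
      bs <- sps$sites$position[i] + sps$offsets
      contained <- region_contains(valid, rep(sps$sites$chrom[i], length(bs)),
                                   bs, bs + sps$bin_size)
      mask[i, ] <- mask[i, ] | !contained
    }
  }
  if (is.finite(outlier_sd)) {
    vals <- sps$counts[!mask]
    mu <- mean(vals); sdv <- stats::sd(vals)
    if (is.finite(sdv) && sdv > 0)
      mask <- mask | (sps$counts > mu + outlier_sd * sdv)
  }
  sps$mask <- mask
  sps$counts[mask] <- NA_real_
  sps
}

#' Composite profile: mean over sites ignoring masked bins
#'
#' @param sps a `SiteProfileSet` (after [mask_bins()]).
#' @param provenance provenance list carried on the result.
#' @return A `CompositeProfile` with state `"raw-mean"`; bins masked at
#'   every site are `NA`.
#' @export
composite_profile <- function(sps, provenance = list()) {
  stopifnot(inherits(sps, "SiteProfileSet"))
  vals <- colMeans(sps$counts, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  composite_profile_obj(vals, sps$offsets, "raw-mean", provenance)
}

#' Smooth, normalize and trim a composite profile
#'
#' Savitzky-Golay filter (default 165 bp window = 11 bins, polynomial
#' order 3), division by the mean over unmasked bins of the full window,
#' then trimming to bins whose centers lie within the trim half-width
#' (+/-1 kb). Masked bins are linearly interpolated for filtering only
#' and restored to `NA` afterwards.
#'
#' @param cp a `CompositeProfile` with state `"raw-mean"`.
#' @param config a `GriffinConfig`.
#' @param window profile half-window the offsets span.
#' @return A `CompositeProfile` with state `"trimmed"`.
#' @export
smooth_and_normalize <- function(cp, config = griffin_config(),
                                 window = 5000) {
  stopifnot(inherits(cp, "CompositeProfile"))
  v <- cp$values
  if (all(is.na(v))) stop("empty profile")
  na_at <- is.na(v)
  sg_bins <- as.integer(config$sg_window_bp / config$bin_size)
  sm <- signal::sgolayfilt(fill_na(v), p = config$sg_order, n = sg_bins)
  sm[na_at] <- NA_real_
  m <- mean(sm, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("cannot normalize profile with mean <= 0")
  sm <- sm / m
  centers <- cp$offsets + config$bin_size / 2
  keep <- abs(centers) <= config$trim_halfwidth
  composite_profile_obj(sm[keep], cp$offsets[keep], "trimmed",
                        c(cp$provenance, list(normalized_mean = m)))
}

#' Local copy-number correction of a site profile
#'
#' Divides each profile bin by the mean binned coverage in the
#' surrounding local window (default +/-50 kb), computed from the same
#' weighted midpoint coverage at bin resolution. Intended per site,
#' before compositing; off by default in the pipeline.
#'
#' @param extended_values binned coverage over the extended local window
#'   (centered on the site).
#' @param bin_size bin width in bp.
#' @param local_halfwidth local window half-width in bp.
#' @param profile_halfwidth profile half-width in bp; the central
#'   `2 * profile_halfwidth / bin_size` bins are returned, corrected.
#' @return Corrected central bins, or all-`NA` (with a warning) when the
#'   local mean is zero.
#' @export
cna_local_correct <- function(extended_values, bin_size = 15,
                              local_halfwidth = 50000,
                              profile_halfwidth = 5000) {
  n <- length(extended_values)
  halfbins <- local_halfwidth %/% bin_size
  cs <- cumsum(c(0, ifelse(is.na(extended_values), 0, extended_values)))
  cn <- cumsum(c(0, !is.na(extended_values)))
  lo <- pmax(seq_len(n) - halfbins, 1)
  hi <- pmin(seq_len(n) + halfbins, n)
  local_mean <- (cs[hi + 1] - cs[lo]) / pmax(cn[hi + 1] - cn[lo], 1)
  prof_bins <- (2 * profile_halfwidth) %/% bin_size
  ctr <- (n - prof_bins) %/% 2
  idx <- (ctr + 1):(ctr + prof_bins)
  lm <- local_mean[idx]
  if (any(lm <= 0, na.rm = TRUE) || all(is.na(lm))) {
    warning("local mean coverage is zero; site masked")
    return(rep(NA_real_, prof_bins))
  }
  extended_values[idx] / lm
}

#' End-to-end composite profile for one site list
#'
#' Runs [collect_fragments()], GC (and optional mappability) weighting,
#' [bin_midpoints()], [mask_bins()], optional CNA correction,
#' [composite_profile()] and [smooth_and_normalize()].
#'
#' @param bam indexed BAM path.
#' @param sites a `SiteList`.
#' @param genome a `GenomeCache` (or FASTA path / `DNAStringSet`).
#' @param gc_model a `GCBiasModel`, or `NULL` for uncorrected profiles.
#' @param valid a `RegionSet` for bin masking (`NULL` to skip).
#' @param mappability a `MappabilityTrack` (only used when
#'   `config$mappability_correction` is on).
#' @param map_bias a `MappabilityBiasModel` (idem).
#' @param config a `GriffinConfig`.
#' @return A trimmed `CompositeProfile`.
#' @export
nucleosome_profile <- function(bam, sites, genome, gc_model = NULL,
                               valid = NULL, mappability = NULL,
                               map_bias = NULL, config = griffin_config()) {
  cache <- genome_cache(genome)
  col <- collect_fragments(bam, sites, cache, window = config$window,
                           length_range = config$fragment_range,
                           min_mapq = config$min_mapq,
                           bin_size = config$bin_size)
  weights <- NULL
  if (!is.null(gc_model) || config$mappability_correction) {
    weights <- lapply(seq_along(col$fragments), function(i) {
      f <- col$fragments[[i]]
      if (length(f$start) == 0) return(numeric(0))
      chrom <- col$sites$chrom[i]
      w <- rep(1, length(f$start))
      if (!is.null(gc_model)) {
        g <- interval_gc(cache, chrom, f$start, f$end)
        w <- fragment_weight(gc_model, f$length, g)
      }
      if (config$mappability_correction) {
        stopifnot(!is.null(mappability), !is.null(map_bias))
        w <- w * vapply(seq_along(f$start), function(j) {
          mappability_fragment_weight(map_bias, mappability, chrom,
                                      f$start[j], f$end[j])
        }, numeric(1))
      }
      w
    })
  }
  sps <- bin_midpoints(col, weights)
  sps <- mask_bins(sps, valid = valid, outlier_sd = config$outlier_sd)
  if (config$cna_correction) {
    ext_half <- config$cna_halfwidth + config$window
    for (i in seq_len(nrow(sps$sites))) {
      ext <- binned_coverage_window(bam, cache, sps$sites$chrom[i],
                                    sps$sites$position[i], ext_half,
                                    config, gc_model)
      corr <- cna_local_correct(ext, config$bin_size, config$cna_halfwidth,
                                config$window)
      sps$counts[i, ] <- ifelse(is.na(sps$counts[i, ]), NA_real_, corr)
    }
  }
  cp <- composite_profile(sps, provenance = list(
    bam = bam, site_list = sites$name,
    fragment_range = config$fragment_range,
    gc_corrected = !is.null(gc_model),
    n_sites = nrow(sps$sites),
    n_excluded_fragments = sps$n_excluded_fragments,
    config_hash = config_hash(config)))
  smooth_and_normalize(cp, config = config, window = config$window)
}

# weighted binned midpoint coverage over an arbitrary window (used by
# the CNA correction)
binned_coverage_window <- function(bam, cache, chrom, center, halfwidth,
                                   config, gc_model) {
  lo <- max(center - halfwidth, 0)
  hi <- min(center + halfwidth, chrom_length(cache, chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo + 1, hi))
  f <- scan_fragments(bam, min_mapq = config$min_mapq, which = gr)[[1]]
  len <- f$end - f$start
  keep <- len >= config$fragment_range[1] & len <= config$fragment_range[2]
  f <- f[keep, , drop = FALSE]
  mid <- (f$start + f$end - 1) %/% 2
  nb <- (2 * halfwidth) %/% config$bin_size
  bin <- (mid - (center - halfwidth)) %/% config$bin_size
  ok <- bin >= 0 & bin < nb
  f <- f[ok, , drop = FALSE]; bin <- bin[ok]
  w <- rep(1, nrow(f))
  if (!is.null(gc_model) && nrow(f)) {
    g <- interval_gc(cache, chrom, f$start, f$end)
    w <- fragment_weight(gc_model, f$end - f$start, g)
  }
  tapply2(w, bin + 1, nb)
}

#' Write composite profiles as TSV
#'
#' @param profiles named list of `CompositeProfile`s.
#' @param path output path; columns `site_list`, `offset_bp`, `value`,
#'   `masked`.
#' @param config configuration stamped into the header.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path, config = griffin_config()) {
  df <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    data.frame(site_list = nm, offset_bp = p$offsets, value = p$values,
               masked = is.na(p$values))
  }))
  write_result_tsv(df, path, config)
}
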