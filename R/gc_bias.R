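#' Fragment-length-specific GC bias
#'
#' Implements the fragment length position model for sample-specific GC
#' bias: the GC composition of observed fragments, stratified by fragment
#' length, is divided by the genome's GC frequencies for the same
#' lengths, normalized to a per-length mean of one, and smoothed with a
#' k-nearest-neighbour median across similar fragment lengths. The
#' inverse of the smoothed bias is the per-fragment weight used in
#' profiling.
#'
#' @name gc-bias
NULL

# read proper-pair fragments (first mate records) from an indexed BAM;
# returns chrom/start/end in 0-based half-open coordinates
scan_fragments <- function(bam, min_mapq = 20, which = NULL) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isFirstMateRead = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isNotPassingQualityControls = FALSE,
                                 isDuplicate = FALSE)
  what <- c("rname", "pos", "isize")
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flag, what = what, mapqFilter = min_mapq)
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what, mapqFilter = min_mapq,
                            which = which)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  lapply(res, function(r) {
    keep <- !is.na(r$isize) & r$isize > 0
    data.frame(chrom = as.character(r$rname[keep]),
               start = r$pos[keep] - 1,
               end = r$pos[keep] - 1 + r$isize[keep],
               stringsAsFactors = FALSE)
  })
}

#' Count sample fragment GC composition
#'
#' Counts the reference-sequence GC content of every accepted proper-pair
#' fragment, stratified by fragment length. A fragment is accepted when
#' it passes quality rules (proper pair, mapping quality >= `min_mapq`,
#' not duplicate, not QC-fail), its length lies in `length_range`, its
#' span is fully contained in one valid interval (the same admissibility
#' rule as the genome frequencies) and its span contains no ambiguous
#' base.
#'
#' @param bam path to a coordinate-sorted indexed BAM.
#' @param genome a `GenomeCache` (or FASTA path / `DNAStringSet`).
#' @param valid a `RegionSet` of valid regions.
#' @param length_range integer `c(min, max)` fragment length.
#' @param min_mapq minimum mapping quality.
#' @return An object of class `GCCounts`: counts matrix (length x GC
#'   count) plus `n_fragments_used`.
#' @export
count_sample_gc <- function(bam, genome, valid,
                            length_range = c(100, 200), min_mapq = 20) {
  stopifnot(is_region_set(valid), nrow(valid) > 0)
  cache <- genome_cache(genome)
  frags <- scan_fragments(bam, min_mapq = min_mapq)[[1]]
  lmin <- as.integer(length_range[1]); lmax <- as.integer(length_range[2])
  counts <- matrix(0, nrow = lmax - lmin + 1, ncol = lmax + 1,
                   dimnames = list(length = lmin:lmax, gc = 0:lmax))
  n_used <- 0
  if (nrow(frags)) {
    len <- frags$end - frags$start
    keep <- len >= lmin & len <= lmax &
      region_contains(valid, frags$chrom, frags$start, frags$end)
    frags <- frags[keep, , drop = FALSE]
    len <- len[keep]
    if (nrow(frags)) {
      gc <- rep(NA_integer_, nrow(frags))
      for (chrom in unique(frags$chrom)) {
        j <- frags$chrom == chrom
        gc[j] <- interval_gc(cache, chrom, frags$start[j], frags$end[j])
      }
      ok <- !is.na(gc)
      len <- len[ok]; gc <- gc[ok]
      n_used <- length(len)
      if (n_used) {
        idx <- (len - lmin) * (lmax + 1) + gc + 1
        tab <- tabulate(idx, nbins = nrow(counts) * ncol(counts))
        counts <- counts + matrix(tab, nrow = nrow(counts),
                                  ncol = ncol(counts), byrow = TRUE,
                                  dimnames = dimnames(counts))
      }
    }
  }
  if (n_used == 0) warning("no accepted fragments in ", bam)
  structure(list(counts = counts, length_range = c(lmin, lmax),
                 n_fragments_used = n_used),
            class = "GCCounts")
}

#' Raw GC bias: sample counts over genome frequencies
#'
#' `bias(L, g) = counts(L, g) / frequency(L, g)` wherever the genome
#' frequency is positive, rescaled so the mean bias over observed
#' combinations at each fragment length is 1. Combinations never
#' observed in the genome are missing (`NA`).
#'
#' @param sample a `GCCounts`.
#' @param genome_freqs a `GenomeGCFrequencies` covering the sample's
#'   length range.
#' @return A numeric matrix (length x GC count) with `NA` at missing
#'   combinations.
#' @export
compute_raw_gc_bias <- function(sample, genome_freqs) {
  stopifnot(inherits(sample, "GCCounts"),
            inherits(genome_freqs, "GenomeGCFrequencies"))
  lens <- as.integer(rownames(sample$counts))
  fl <- as.integer(rownames(genome_freqs$counts))
  missing_l <- setdiff(lens, fl)
  if (length(missing_l))
    stop("genome frequencies lack fragment length(s): ",
         paste(missing_l, collapse = ", "))
  bias <- matrix(NA_real_, nrow = nrow(sample$counts),
                 ncol = ncol(sample$counts),
                 dimnames = dimnames(sample$counts))
  for (i in seq_along(lens)) {
    f <- genome_freqs$counts[match(lens[i], fl), seq_len(ncol(bias))]
    obs <- f > 0
    b <- sample$counts[i, obs] / f[obs]
    m <- mean(b)
    bias[i, obs] <- if (m > 0) b / m else b
  }
  bias
}

# median of the k nearest neighbours in sorted order, window clipped at
# the ends so it always holds exactly k values (compiled)
knn_median <- function(v, k) {
  .sliding_clipped_median(as.numeric(v), as.integer(min(k, length(v))))
}

#' Smooth a raw GC bias surface
#'
#' For each fragment length, all non-missing bias values for lengths
#' within `pool_bp` (default +/-10 bp) are pooled, sorted by GC fraction
#' (comparable across lengths), and each value is replaced by the median
#' of its k nearest neighbours in that sorted order with
#' `k = max(50, 5% of the vector length)`. Each length then gets its own
#' smoothed curve, renormalized to mean 1 over its observed
#' combinations.
#'
#' @param raw_bias matrix from [compute_raw_gc_bias()].
#' @param k_rule optional override for the neighbourhood size: a fixed
#'   integer or a function of the pooled vector length (unit-test hook;
#'   the default is the production rule).
#' @param pool_bp half-width of the fragment-length pooling window.
#' @param mode `"multi-length"` or `"single-length-165"`.
#' @return An object of class `GCBiasModel` with `bias` (smoothed),
#'   `raw`, `length_range`, and `mode`.
#' @export
smooth_gc_bias <- function(raw_bias, k_rule = NULL, pool_bp = 10,
                           mode = "multi-length") {
  if (all(is.na(raw_bias))) stop("raw bias is empty")
  lens <- as.integer(rownames(raw_bias))
  smoothed <- raw_bias
  for (i in seq_along(lens)) {
    pool <- which(abs(lens - lens[i]) <= pool_bp)
    ent <- do.call(rbind, lapply(pool, function(j) {
      g <- which(!is.na(raw_bias[j, ])) - 1
      if (!length(g)) return(NULL)
      data.frame(len = lens[j], g = g, gf = g / lens[j],
                 value = raw_bias[j, g + 1])
    }))
    if (is.null(ent) || !any(ent$len == lens[i])) next
    ord <- order(ent$gf, ent$len, ent$g)
    ent <- ent[ord, , drop = FALSE]
    k <- if (is.null(k_rule)) max(50, ceiling(0.05 * nrow(ent)))
         else if (is.function(k_rule)) k_rule(nrow(ent))
         else k_rule
    if (k > nrow(ent)) {
      warning("fewer than k = ", k, " values available; clamping to ",
              nrow(ent))
      k <- nrow(ent)
    }
    sm <- knn_median(ent$value, k)
    mine <- ent$len == lens[i]
    smoothed[i, ent$g[mine] + 1] <- sm[mine]
    obs <- !is.na(smoothed[i, ])
    m <- mean(smoothed[i, obs])
    if (m > 0) smoothed[i, obs] <- smoothed[i, obs] / m
  }
  structure(list(bias = smoothed, raw = raw_bias,
                 length_range = range(lens), mode = mode),
            class = "GCBiasModel")
}

#' @export
print.GCBiasModel <- function(x, ...) {
  cat(sprintf("GCBiasModel (%s): lengths %d-%d, %d observed combinations\n",
              x$mode, x$length_range[1], x$length_range[2],
              sum(!is.na(x$bias))))
  invisible(x)
}

#' Per-fragment GC correction weight
#'
#' Returns `1 / bias(L, g)`. Fragments whose (length, GC) combination is
#' missing from the model, or whose bias falls below `min_bias`, get
#' weight 0 (the exclusion sentinel: they contribute nothing to
#' profiles and are counted in diagnostics by the caller). The floor
#' keeps rare combinations whose smoothed bias collapses toward zero
#' from entering profiles with unbounded weights.
#'
#' @param model a `GCBiasModel`.
#' @param L fragment length(s).
#' @param g GC count(s), same length as `L`.
#' @param min_bias smallest usable bias (default 0.05, i.e. weights are
#'   capped at 20 by exclusion, not truncation).
#' @return Non-negative numeric weights.
#' @export
fragment_weight <- function(model, L, g, min_bias = 0.05) {
  stopifnot(inherits(model, "GCBiasModel"))
  lens <- as.integer(rownames(model$bias))
  if (model$mode == "single-length-165") {
    # map any fragment to the closest 165 bp GC content
    g <- round(165 * g / L)
    L <- rep(165L, length(g))
  }
  li <- match(L, lens)
  w <- rep(0, length(L))
  ok <- !is.na(li) & !is.na(g) & g >= 0 & g <= ncol(model$bias) - 1
  b <- rep(NA_real_, length(L))
  b[ok] <- model$bias[cbind(li[ok], g[ok] + 1)]
  good <- ok & !is.na(b) & b >= min_bias
  w[good] <- 1 / b[good]
  w
}

#' Estimate a sample's smoothed GC bias model from a BAM
#'
#' Convenience wrapper: [count_sample_gc()] then
#' [compute_raw_gc_bias()] then [smooth_gc_bias()].
#'
#' @inheritParams count_sample_gc
#' @param genome_freqs a `GenomeGCFrequencies` for `valid`.
#' @param k_rule see [smooth_gc_bias()].
#' @return A `GCBiasModel`.
#' @export
estimate_gc_bias <- function(bam, genome, valid, genome_freqs,
                             length_range = c(100, 200), min_mapq = 20,
                             k_rule = NULL) {
  counts <- count_sample_gc(bam, genome, valid, length_range, min_mapq)
  raw <- compute_raw_gc_bias(counts, genome_freqs)
  smooth_gc_bias(raw, k_rule = k_rule)
}

#' Single-fragment-length GC bias model (165 bp)
#'
#' Comparison variant that assumes every read spans a 165 bp fragment
#' starting at the read start position. The resulting curve (one length,
#' 165 bp) is applied to arbitrary fragments by mapping their GC content
#' to the closest 165 bp GC content.
#'
#' @inheritParams count_sample_gc
#' @param k_rule see [smooth_gc_bias()].
#' @return A `GCBiasModel` with mode `"single-length-165"`.
#' @export
single_length_gc_bias <- function(bam, genome, valid, min_mapq = 20,
                                  k_rule = NULL) {
  stopifnot(is_region_set(valid), nrow(valid) > 0)
  cache <- genome_cache(genome)
  L0 <- 165L
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isNotPassingQualityControls = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"),
                                   mapqFilter = min_mapq)
  r <- Rsamtools::scanBam(bam, param = param)[[1]]
  start <- r$pos - 1
  chrom <- as.character(r$rname)
  keep <- region_contains(valid, chrom, start, start + L0)
  chrom <- chrom[keep]; start <- start[keep]
  counts <- matrix(0, nrow = 1, ncol = L0 + 1,
                   dimnames = list(length = L0, gc = 0:L0))
  n_used <- 0
  if (length(start)) {
    gc <- rep(NA_integer_, length(start))
    for (ch in unique(chrom)) {
      j <- chrom == ch
      gc[j] <- interval_gc(cache, ch, start[j], start[j] + L0)
    }
    gc <- gc[!is.na(gc)]
    n_used <- length(gc)
    if (n_used) counts[1, ] <- tabulate(gc + 1, nbins = L0 + 1)
  }
  if (n_used == 0) warning("no accepted reads in ", bam)
  gcc <- structure(list(counts = counts, length_range = c(L0, L0),
                        n_fragments_used = n_used), class = "GCCounts")
  freqs <- compute_genome_gc_frequencies(cache, valid,
                                         length_range = c(L0, L0))
  raw <- compute_raw_gc_bias(gcc, freqs)
  smooth_gc_bias(raw, k_rule = k_rule, mode = "single-length-165")
}

#' Read a GC bias model from TSV
#'
#' Inverse of [write_gc_bias_model()].
#'
#' @param path TSV with columns `length`, `gc_count`, `raw_bias`,
#'   `smoothed_bias`.
#' @param mode model mode tag.
#' @return A `GCBiasModel`.
#' @export
read_gc_bias_model <- function(path, mode = "multi-length") {
  df <- utils::read.delim(path, comment.char = "#")
  lens <- sort(unique(df$length))
  gmax <- max(df$gc_count)
  shape <- list(length = lens, gc = 0:gmax)
  bias <- matrix(NA_real_, length(lens), gmax + 1, dimnames = shape)
  raw <- bias
  bias[cbind(match(df$length, lens), df$gc_count + 1)] <- df$smoothed_bias
  raw[cbind(match(df$length, lens), df$gc_count + 1)] <- df$raw_bias
  structure(list(bias = bias, raw = raw, length_range = range(lens),
                 mode = mode), class = "GCBiasModel")
}

#' Serialize a GC bias model as TSV
#'
#' @param model a `GCBiasModel`.
#' @param path output path; columns `length`, `gc_count`, `raw_bias`,
#'   `smoothed_bias`.
#' @param config configuration stamped into the header.
#' @return `path`, invisibly.
#' @export
write_gc_bias_model <- function(model, path, config = griffin_config()) {
  lens <- as.integer(rownames(model$bias))
  df <- do.call(rbind, lapply(seq_along(lens), function(i) {
    g <- which(!is.na(model$raw[i, ]) | !is.na(model$bias[i, ])) - 1
    if (!length(g)) return(NULL)
    data.frame(length = lens[i], gc_count = g,
               raw_bias = model$raw[i, g + 1],
               smoothed_bias = model$bias[i, g + 1])
  }))
  write_result_tsv(df, path, config)
}
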