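#' Mappability bias estimation and correction
#'
#' Optional per-fragment mappability correction: genome segments are
#' sampled on a stride, read counts at sampled positions are grouped by
#' their mappability value, the per-value mean coverage is pooled across
#' segments and smoothed by locally weighted regression, and fragments
#' are reweighted by the inverse relative bias at their mean
#' mappability. Off by default in the pipeline.
#'
#' @name mappability-correction
NULL

#' Estimate the mappability bias of a sample
#'
#' @param bam indexed BAM path.
#' @param mappability a `MappabilityTrack`.
#' @param valid optional `RegionSet`; sampled positions outside are
#'   skipped.
#' @param segment genome segment size in bp (bias computed per segment,
#'   then pooled).
#' @param stride sample every `stride`-th position.
#' @param outlier_sd positions with read counts above
#'   `mean + outlier_sd * SD` are excluded.
#' @param span locally weighted regression span.
#' @param min_mapq minimum mapping quality.
#' @return An object of class `MappabilityBiasModel`: the fitted smooth
#'   and the reference value at mappability 1, so that
#'   [predict_mappability_bias()] returns a relative bias (1 at
#'   mappability 1).
#' @export
estimate_mappability_bias <- function(bam, mappability, valid = NULL,
                                      segment = 5e6, stride = 100,
                                      outlier_sd = 5, span = 2 / 3,
                                      min_mapq = 20) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isNotPassingQualityControls = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "qwidth"),
                                   mapqFilter = min_mapq)
  r <- Rsamtools::scanBam(bam, param = param)[[1]]
  reads <- data.frame(chrom = as.character(r$rname), start = r$pos - 1,
                      end = r$pos - 1 + r$qwidth)
  rows <- NULL
  for (chrom in unique(mappability$chrom)) {
    d <- mappability[mappability$chrom == chrom, , drop = FALSE]
    lim <- max(d$end)
    pos <- seq.int(0, lim - 1, by = stride)
    if (!is.null(valid))
      pos <- pos[region_contains(valid, rep(chrom, length(pos)), pos, pos + 1)]
    if (!length(pos)) next
    mval <- mappability_at(mappability, chrom, pos)
    keep <- !is.na(mval)
    pos <- pos[keep]; mval <- mval[keep]
    rd <- reads[reads$chrom == chrom, , drop = FALSE]
    s <- sort(rd$start); e <- sort(rd$end)
    cov <- findInterval(pos, s) - findInterval(pos, e)
    rows <- rbind(rows, data.frame(segment = pos %/% segment,
                                   mappability = mval, reads = cov))
  }
  if (is.null(rows) || nrow(rows) == 0) stop("no sampled positions")
  cutoff <- mean(rows$reads) + outlier_sd * stats::sd(rows$reads)
  excluded <- rows$reads > cutoff
  rows <- rows[!excluded, , drop = FALSE]
  agg <- stats::aggregate(reads ~ segment + mappability, rows, mean)
  fit <- if (length(unique(agg$mappability)) >= 4) {
    stats::loess(reads ~ mappability, agg, span = span,
                 control = stats::loess.control(surface = "direct"))
  } else {
    # too few distinct values for a local fit; fall back to per-value means
    NULL
  }
  per_value <- stats::aggregate(reads ~ mappability, agg, mean)
  ref <- if (!is.null(fit)) as.numeric(stats::predict(fit, data.frame(mappability = 1)))
         else per_value$reads[which.max(per_value$mappability)]
  if (!is.finite(ref) || ref <= 0) stop("cannot calibrate mappability bias")
  structure(list(fit = fit, per_value = per_value, ref = ref,
                 n_excluded_positions = sum(excluded)),
            class = "MappabilityBiasModel")
}

#' Relative mappability bias at given mappability values
#'
#' @param model a `MappabilityBiasModel`.
#' @param m mappability values in `[0, 1]`.
#' @return Relative bias (1 at mappability 1); `NA` outside the fitted
#'   range.
#' @export
predict_mappability_bias <- function(model, m) {
  raw <- if (!is.null(model$fit)) {
    as.numeric(stats::predict(model$fit, data.frame(mappability = m)))
  } else {
    model$per_value$reads[match(m, model$per_value$mappability)]
  }
  raw / model$ref
}

#' Mappability correction weight for one fragment
#'
#' The fragment's mappability is the mean over all positions covered by
#' the forward and reverse read; the weight is the inverse relative
#' bias at that value, multiplied with the GC weight by the caller.
#' Fragments covering any position without track coverage are excluded
#' (weight 0).
#'
#' @param model a `MappabilityBiasModel`.
#' @param mappability a `MappabilityTrack`.
#' @param chrom,start,end fragment span (0-based half-open).
#' @param read_length read length used to delimit the two reads.
#' @return A non-negative weight (0 = excluded).
#' @export
mappability_fragment_weight <- function(model, mappability, chrom,
                                        start, end, read_length = 100) {
  rl <- min(read_length, end - start)
  pos <- unique(c(seq.int(start, start + rl - 1),
                  seq.int(end - rl, end - 1)))
  vals <- mappability_at(mappability, chrom, pos)
  if (anyNA(vals)) return(0)
  b <- predict_mappability_bias(model, mean(vals))
  if (!is.finite(b) || b <= 0) return(0)
  1 / b
}
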