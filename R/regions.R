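#' Genomic region sets
#'
#' A `RegionSet` is a plain collection of genomic intervals in 0-based,
#' half-open coordinates, kept sorted by (chromosome, start) and merged so
#' that no two intervals overlap or abut ambiguously. It is the container
#' for "valid" (mappable, non-excluded) regions against which both genome
#' GC frequencies and sample fragment counts are computed.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @return An object of class `RegionSet`: a data.frame with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' region_set(c("chr1", "chr1"), c(0, 40), c(50, 100))
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start >= end)) stop("RegionSet intervals must satisfy start < end")
  if (any(start < 0)) stop("RegionSet intervals must have start >= 0")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- merge_regions(df)
  class(df) <- c("RegionSet", "data.frame")
  df
}

# sort + merge overlapping/adjacent intervals per chromosome
merge_regions <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

is_region_set <- function(x) inherits(x, "RegionSet")

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d intervals on %d chromosome(s), %s bp total\n",
              nrow(x), length(unique(x$chrom)),
              format(sum(x$end - x$start), big.mark = ",")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Subtract one region set from another
#'
#' Removes every base covered by `b` from `a` (set difference on genomic
#' positions). Chromosomes present only in `b` are ignored.
#'
#' @param a,b `RegionSet` objects.
#' @return A `RegionSet`.
#' @export
region_setdiff <- function(a, b) {
  stopifnot(is_region_set(a), is_region_set(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  pieces <- lapply(split(seq_len(nrow(a)), a$chrom), function(idx) {
    chrom <- a$chrom[idx[1]]
    air <- IRanges::IRanges(start = a$start[idx] + 1, end = a$end[idx])
    bsel <- b$chrom == chrom
    if (!any(bsel)) {
      keep <- air
    } else {
      bir <- IRanges::IRanges(start = b$start[bsel] + 1, end = b$end[bsel])
      keep <- IRanges::setdiff(air, bir)
    }
    if (length(keep) == 0) return(NULL)
    data.frame(chrom = chrom, start = IRanges::start(keep) - 1,
               end = IRanges::end(keep), stringsAsFactors = FALSE)
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces)) pieces <- data.frame(chrom = character(),
                                            start = numeric(), end = numeric())
  rownames(pieces) <- NULL
  pieces <- pieces[order(pieces$chrom, pieces$start), , drop = FALSE]
  class(pieces) <- c("RegionSet", "data.frame")
  pieces
}

#' Mappability tracks
#'
#' Per-base mappability values in `[0, 1]` stored as run-length intervals
#' (0-based half-open). Positions not covered by any interval are an
#' explicit miss (`NA` on query), not zero.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param value mappability score per interval, each in `[0, 1]`.
#' @return An object of class `MappabilityTrack`.
#' @export
mappability_track <- function(chrom, start, end, value) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(value))
  if (length(value) && (any(value < 0) || any(value > 1)))
    stop("mappability values must lie in [0, 1]")
  if (length(start) && any(start >= end)) stop("intervals must have start < end")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # overlapping runs would make per-base values ambiguous
  for (d in split(df, df$chrom)) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("mappability intervals may not overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("MappabilityTrack", "data.frame")
  df
}

#' Query per-base mappability
#'
#' @param track a `MappabilityTrack`.
#' @param chrom chromosome name (scalar).
#' @param positions 0-based positions.
#' @return Numeric vector of values; `NA` where the track has no coverage.
#' @export
mappability_at <- function(track, chrom, positions) {
  stopifnot(inherits(track, "MappabilityTrack"))
  d <- track[track$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, length(positions))
  if (nrow(d) == 0) return(out)
  idx <- findInterval(positions, d$start)
  hit <- idx >= 1 & positions < d$end[pmax(idx, 1)]
  out[hit] <- d$value[idx[hit]]
  out
}

#' Mean mappability over an interval, NA if any base is uncovered
#' @noRd
mappability_interval_mean <- function(track, chrom, start, end) {
  vals <- mappability_at(track, chrom, seq.int(start, end - 1))
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Build the valid-region mask
#'
#' Valid regions are positions whose mappability meets `threshold`
#' (default 1, i.e. uniquely mappable), minus any exclusion-list
#' intervals, merged and sorted. This mask is the admissibility rule
#' shared by genome GC frequencies, sample GC counts, and bin masking.
#'
#' @param mappability a `MappabilityTrack`.
#' @param exclusions a `RegionSet` of intervals to remove (may be empty).
#' @param threshold minimum mappability, in `(0, 1]`.
#' @param chroms optional character vector restricting output chromosomes
#'   (e.g. autosomes only).
#' @return A `RegionSet` of valid intervals.
#' @export
build_valid_regions <- function(mappability, exclusions = NULL,
                                threshold = 1.0, chroms = NULL) {
  stopifnot(inherits(mappability, "MappabilityTrack"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  keep <- mappability[mappability$value >= threshold, , drop = FALSE]
  if (!is.null(chroms)) keep <- keep[keep$chrom %in% chroms, , drop = FALSE]
  rs <- region_set(keep$chrom, keep$start, keep$end)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    missing_chrom <- setdiff(unique(exclusions$chrom), unique(mappability$chrom))
    if (length(missing_chrom)) {
      warning("exclusion chromosome(s) absent from mappability track, skipped: ",
              paste(missing_chrom, collapse = ", "))
      exclusions <- exclusions[!exclusions$chrom %in% missing_chrom, , drop = FALSE]
      class(exclusions) <- c("RegionSet", "data.frame")
    }
    rs <- region_setdiff(rs, exclusions)
  }
  rs
}

#' Read a BED file as a RegionSet
#'
#' @param path path to a BED file (0-based half-open on disk).
#' @return A `RegionSet`.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

#' Read a bedGraph file as a MappabilityTrack
#'
#' @param path path to a bedGraph file whose score column holds per-base
#'   mappability in `[0, 1]`.
#' @return A `MappabilityTrack`.
#' @export
read_mappability_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  mappability_track(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                    gr$score)
}

#' Write a RegionSet as a bedGraph of ones
#'
#' @param regions a `RegionSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bedgraph <- function(regions, path) {
  stopifnot(is_region_set(regions))
  df <- data.frame(regions$chrom, regions$start, regions$end, 1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
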