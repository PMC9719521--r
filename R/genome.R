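#' Cached genome base-composition lookups
#'
#' Loads a genome (FASTA path or `DNAStringSet`) into per-chromosome
#' cumulative G+C and A/C/G/T counts so that the GC count of any interval
#' is two array lookups. All downstream GC computation (genome
#' frequencies, sample fragment GC, site GC profiles) goes through this
#' cache, guaranteeing one consistent convention.
#'
#' @param genome path to an indexed FASTA file, or a
#'   `Biostrings::DNAStringSet`.
#' @return An object of class `GenomeCache`.
#' @export
genome_cache <- function(genome) {
  if (inherits(genome, "GenomeCache")) return(genome)
  if (is.character(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (inherits(genome, "DNAStringSet")) {
    seqs <- genome
  } else {
    stop("genome must be a FASTA path or a DNAStringSet")
  }
  chroms <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    gc <- as.integer(Biostrings::letterFrequencyInSlidingView(s, 1, "CG"))
    ok <- as.integer(Biostrings::letterFrequencyInSlidingView(s, 1, "ACGT"))
    has_n <- any(ok == 0L)
    list(cum_gc = cumsum(c(0, gc)),
         cum_ok = if (has_n) cumsum(c(0, ok)) else NULL,
         has_n = has_n, length = length(s))
  })
  names(chroms) <- names(seqs)
  structure(list(chroms = chroms), class = "GenomeCache")
}

#' @export
print.GenomeCache <- function(x, ...) {
  lens <- vapply(x$chroms, `[[`, numeric(1), "length")
  cat(sprintf("GenomeCache: %d chromosome(s), %s bp\n",
              length(lens), format(sum(lens), big.mark = ",")))
  invisible(x)
}

#' Chromosome length from a genome cache
#'
#' @param cache a `GenomeCache`.
#' @param chrom chromosome name.
#' @return Length in bp.
#' @export
chrom_length <- function(cache, chrom) {
  ch <- cache$chroms[[chrom]]
  if (is.null(ch)) stop("chromosome not in genome: ", chrom)
  ch$length
}

#' GC count of genomic intervals
#'
#' @param cache a `GenomeCache`.
#' @param chrom chromosome name (scalar).
#' @param start,end 0-based half-open interval bounds (vectorized).
#' @return Integer GC counts; `NA` where an interval contains a
#'   non-ACGT base.
#' @export
interval_gc <- function(cache, chrom, start, end) {
  ch <- cache$chroms[[chrom]]
  if (is.null(ch)) stop("chromosome not in genome: ", chrom)
  gc <- ch$cum_gc[end + 1] - ch$cum_gc[start + 1]
  if (ch$has_n) {
    ok <- ch$cum_ok[end + 1] - ch$cum_ok[start + 1]
    gc[ok < (end - start)] <- NA_integer_
  }
  gc
}

#' Genome GC frequencies under the fragment-length position model
#'
#' For every fragment length `L` in `length_range`, counts the GC content
#' of every `L`-mer fully contained in a single valid interval. The
#' resulting table is the "expected" GC composition of fragments drawn
#' uniformly from the valid genome, the denominator of the per-sample GC
#' bias. `L`-mers containing an ambiguous base (N) are skipped; the same
#' containment and N rules are applied to sample fragments so numerator
#' and denominator share one admissibility convention.
#'
#' @param genome a `GenomeCache`, FASTA path, or `DNAStringSet`.
#' @param valid a `RegionSet` of valid intervals.
#' @param length_range integer vector `c(min, max)` fragment length.
#' @return An object of class `GenomeGCFrequencies`: a counts matrix with
#'   one row per fragment length (`min:max`) and columns `g = 0..max`,
#'   plus a `length_range` attribute.
#' @export
compute_genome_gc_frequencies <- function(genome, valid,
                                          length_range = c(100, 200)) {
  stopifnot(is_region_set(valid), length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  cache <- genome_cache(genome)
  lmin <- as.integer(length_range[1]); lmax <- as.integer(length_range[2])
  lens <- lmin:lmax
  counts <- matrix(0, nrow = length(lens), ncol = lmax + 1,
                   dimnames = list(length = lens, gc = 0:lmax))
  for (chrom in unique(valid$chrom)) {
    d <- valid[valid$chrom == chrom, , drop = FALSE]
    if (max(d$end) > chrom_length(cache, chrom))
      stop("valid interval extends past end of ", chrom)
    ch <- cache$chroms[[chrom]]
    for (i in seq_len(nrow(d))) {
      s <- d$start[i]; e <- d$end[i]
      for (L in lens) {
        if (e - s < L) next
        # contiguous slices: GC of L-mers starting at s .. e-L
        gc <- ch$cum_gc[(s + L + 1):(e + 1)] - ch$cum_gc[(s + 1):(e - L + 1)]
        if (ch$has_n) {
          ok <- ch$cum_ok[(s + L + 1):(e + 1)] - ch$cum_ok[(s + 1):(e - L + 1)]
          gc <- gc[ok == L]
        }
        if (length(gc))
          counts[L - lmin + 1, ] <- counts[L - lmin + 1, ] +
            tabulate(gc + 1, nbins = lmax + 1)
      }
    }
  }
  structure(list(counts = counts, length_range = c(lmin, lmax)),
            class = "GenomeGCFrequencies")
}

#' @export
print.GenomeGCFrequencies <- function(x, ...) {
  cat(sprintf("GenomeGCFrequencies: lengths %d-%d, %s L-mers counted\n",
              x$length_range[1], x$length_range[2],
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Serialize genome GC frequencies as TSV
#'
#' @param freqs a `GenomeGCFrequencies`.
#' @param path output path; columns `length`, `gc_count`, `frequency`.
#' @return `path`, invisibly.
#' @export
write_gc_frequencies <- function(freqs, path) {
  lens <- as.integer(rownames(freqs$counts))
  df <- do.call(rbind, lapply(seq_along(lens), function(i) {
    data.frame(length = lens[i], gc_count = 0:(ncol(freqs$counts) - 1),
               frequency = freqs$counts[i, ])
  }))
  df <- df[df$gc_count <= df$length, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
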