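#' Synthetic cfDNA cohort simulation
#'
#' The simulator produces alignment files with known ground truth so the
#' whole pipeline — GC-bias estimation, composite profiling, feature
#' extraction, cohort statistics and classification — can be exercised at
#' desk scale without controlled-access data. It emulates the salient
#' structure of cfDNA WGS around regulatory sites: nucleosome-phased
#' fragment midpoint densities with ~190 bp periodicity, a central
#' protection dip whose depth scales with accessibility and tumor
#' fraction, per-fragment-length GC-bias curves that differ between
#' samples, and fragment lengths concentrated around the mononucleosome
#' mode (~167 bp).
#'
#' @name synthetic-cohort
NULL

#' Synthetic genome specification
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gc background GC fraction (the mean when `gc_spread > 0`).
#' @param gc_spread regional GC heterogeneity: per-`block_size` blocks
#'   draw their GC fraction uniformly from `gc +/- gc_spread`,
#'   emulating isochore-scale composition variation. 0 gives a
#'   homogeneous background.
#' @param block_size block length (bp) for regional GC variation.
#' @param enriched optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of intervals drawn at `gc_enriched` instead — used to
#'   emulate the elevated GC content at regulatory site centers.
#' @param gc_enriched GC fraction inside `enriched` intervals.
#' @return An object of class `SyntheticGenomeSpec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths, gc = 0.41, gc_spread = 0,
                                  block_size = 1000,
                                  enriched = NULL, gc_enriched = 0.65) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            gc > 0, gc < 1, gc_enriched > 0, gc_enriched < 1,
            gc_spread >= 0, gc - gc_spread > 0, gc + gc_spread < 1,
            block_size >= 1)
  structure(list(chrom_lengths = chrom_lengths, gc = gc,
                 gc_spread = gc_spread, block_size = block_size,
                 enriched = enriched, gc_enriched = gc_enriched),
            class = "SyntheticGenomeSpec")
}

#' Simulate a genome sequence
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return A `Biostrings::DNAStringSet`.
#' @export
simulate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  local_rng(seed)
  seqs <- vapply(names(spec$chrom_lengths), function(chrom) {
    n <- spec$chrom_lengths[[chrom]]
    # per-base GC probability: blocky background plus enriched islands
    if (spec$gc_spread > 0) {
      nb <- ceiling(n / spec$block_size)
      block_gc <- stats::runif(nb, spec$gc - spec$gc_spread,
                               spec$gc + spec$gc_spread)
      p <- rep(block_gc, each = spec$block_size)[seq_len(n)]
    } else {
      p <- rep(spec$gc, n)
    }
    if (!is.null(spec$enriched)) {
      d <- spec$enriched[spec$enriched$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(d)))
        p[(d$start[i] + 1):min(d$end[i], n)] <- spec$gc_enriched
    }
    is_gc <- stats::runif(n) < p
    pick <- stats::runif(n) < 0.5
    bases <- character(n)
    bases[is_gc & pick] <- "C"; bases[is_gc & !pick] <- "G"
    bases[!is_gc & pick] <- "A"; bases[!is_gc & !pick] <- "T"
    paste(bases, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Write a simulated genome as FASTA with index
#'
#' @param seqs a `DNAStringSet`.
#' @param path output FASTA path (`.fa`).
#' @return `path`, invisibly; a `.fai` index is written alongside.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Simulate a site list with non-overlapping profile windows
#'
#' Places `n` site centers on a jittered grid so consecutive sites are at
#' least `min_spacing` apart (profile windows never overlap) while the
#' marginal position distribution stays uniform over the admissible range
#' at any scale coarser than one grid cell.
#'
#' @param n number of sites.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param min_spacing minimum center-to-center distance (>= 12 kb so that
#'   +/-5 kb windows plus fragment overhang never overlap).
#' @param margin distance kept clear of chromosome ends.
#' @param seed integer seed.
#' @param name site list name.
#' @return A `SiteList`.
#' @export
simulate_site_list <- function(n, chrom_lengths, min_spacing = 12000,
                               margin = 6000, seed = 1, name = "synthetic") {
  stopifnot(min_spacing >= 12000, n >= 0)
  rng <- local_rng(seed)
  if (n == 0) {
    return(site_list(name, data.frame(chrom = character(),
                                      position = numeric(),
                                      score = numeric()),
                     provenance = "custom"))
  }
  spans <- pmax(chrom_lengths - 2 * margin, 0)
  if (sum(spans) < n * (min_spacing + 1))
    stop("chromosomes too small to place ", n,
         " sites at min_spacing ", min_spacing)
  alloc <- floor(n * spans / sum(spans))
  # distribute the remainder to the largest chromosomes
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(spans, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  out <- NULL
  for (i in seq_along(chrom_lengths)) {
    k <- alloc[i]
    if (k == 0) next
    cell <- floor(spans[i] / k)
    if (cell < min_spacing + 1)
      stop("chromosome ", names(chrom_lengths)[i], " too crowded")
    jitter <- floor(stats::runif(k) * (cell - min_spacing + 1))
    pos <- margin + (seq_len(k) - 1) * cell + jitter
    out <- rbind(out, data.frame(chrom = names(chrom_lengths)[i],
                                 position = pos, score = 1))
  }
  site_list(name, out, provenance = "custom")
}

#' Site accessibility specification
#'
#' Parameters of the per-site fragment-midpoint density
#' `d(x) = 1 - dip * exp(-x^2 / (2 * dip_width^2)) +
#'  amplitude * cos(2 * pi * x / period) * exp(-|x| / decay)`
#' where `x` is the offset from the site center in bp. `dip` models the
#' loss of protection (accessibility) at the site, the cosine term the
#' phased nucleosomes flanking it.
#'
#' @param dip central dip depth in `[0, 1]`.
#' @param amplitude phasing amplitude (>= 0).
#' @param period nucleosome spacing in bp (default 190).
#' @param decay exponential decay length of the phasing in bp; `Inf` for
#'   undamped phasing.
#' @param dip_width Gaussian width of the dip in bp.
#' @return An object of class `SiteAccessibilitySpec`.
#' @export
site_accessibility_spec <- function(dip = 0, amplitude = 0, period = 190,
                                    decay = 500, dip_width = 60) {
  stopifnot(dip >= 0, dip <= 1, amplitude >= 0, period > 0,
            decay > 0, dip_width > 0)
  spec <- structure(list(dip = dip, amplitude = amplitude, period = period,
                         decay = decay, dip_width = dip_width),
                    class = "SiteAccessibilitySpec")
  d <- site_density(spec, seq(-5000, 4999), clip = FALSE)
  clipped <- sum(pmax(-d, 0)) / sum(pmax(d, 0))
  if (clipped > 0.01)
    stop("accessibility spec clips more than 1% of density mass")
  spec
}

# midpoint density factor at offsets x from the site center; negative
# values (possible for extreme parameters) are clipped at 0 when
# sampling
site_density <- function(spec, x, clip = TRUE) {
  phase <- spec$amplitude * cos(2 * pi * x / spec$period)
  if (is.finite(spec$decay)) phase <- phase * exp(-abs(x) / spec$decay)
  d <- 1 - spec$dip * exp(-x^2 / (2 * spec$dip_width^2)) + phase
  if (clip) pmax(d, 0) else d
}

# tumor-fraction mixture of two accessibility specs
mixture_density <- function(tumor, background, tf, x) {
  tf * site_density(tumor, x) + (1 - tf) * site_density(background, x)
}

#' Sample specification for fragment simulation
#'
#' @param tumor_fraction fraction of cfDNA of tumor origin, in `[0, 1]`.
#' @param n_fragments target number of fragments.
#' @param gc_bias optional injected bias curve: a function
#'   `w(length, gc_count)` returning non-negative weights (vectorized);
#'   `NULL` for an unbiased sample.
#' @param length_mix fragment-length mixture: list of `means`, `sds`,
#'   `weights`. The default peaks at the mononucleosome mode (167 bp)
#'   with minor short (~90 bp) and dinucleosome (~330 bp) components,
#'   truncated to 35-500 bp.
#' @param seed integer seed.
#' @return An object of class `SampleSpec`.
#' @export
sample_spec <- function(tumor_fraction = 0, n_fragments = 1e5,
                        gc_bias = NULL,
                        length_mix = list(means = c(90, 167, 330),
                                          sds = c(15, 10, 25),
                                          weights = c(0.07, 0.85, 0.08)),
                        seed = 1) {
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1, n_fragments >= 1,
            is.null(gc_bias) || is.function(gc_bias))
  structure(list(tumor_fraction = tumor_fraction,
                 n_fragments = as.integer(n_fragments),
                 gc_bias = gc_bias, length_mix = length_mix,
                 seed = as.integer(seed)),
            class = "SampleSpec")
}

# sample fragment lengths from the truncated mixture
sample_fragment_lengths <- function(n, mix) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  len <- round(stats::rnorm(n, mix$means[comp], mix$sds[comp]))
  pmin(pmax(len, 35), 500)
}

#' Simulate a cfDNA sample as a coordinate-sorted indexed BAM
#'
#' Fragment midpoints follow a uniform genome-wide background modulated,
#' within +/-5 kb of each site, by the tumor-fraction mixture of the
#' tumor and background accessibility densities. Fragment lengths come
#' from the sample's length mixture; when an injected GC-bias curve is
#' present, each fragment is then accepted with probability proportional
#' to `w(L, gc)` of its reference span. Records carry proper-pair flags,
#' mapping quality 60, and 100 bp reads (mates overlap for fragments
#' shorter than 200 bp, deliberately).
#'
#' @param genome a `GenomeCache` (or FASTA path / `DNAStringSet`).
#' @param sites a `SiteList` (may be empty for a background-only sample).
#' @param tumor,background `SiteAccessibilitySpec`s for the tumor-open and
#'   background (e.g. hematopoietic) state of the sites.
#' @param spec a `SampleSpec`.
#' @param prefix output path prefix; `<prefix>.bam` and `.bam.bai` are
#'   written.
#' @param window profile half-window within which the site density acts.
#' @return A list with `bam` (path), `n_fragments` (written), and
#'   `ground_truth` (specs plus the analytic expected composite profile).
#' @export
simulate_fragments <- function(genome, sites, tumor, background, spec,
                               prefix, window = 5000) {
  cache <- genome_cache(genome)
  stopifnot(inherits(spec, "SampleSpec"))
  rng <- local_rng(spec$seed)
  chrom_lengths <- vapply(cache$chroms, `[[`, numeric(1), "length")
  margin <- 600
  spans <- chrom_lengths - 2 * margin
  tf <- spec$tumor_fraction
  dmax <- max(1, mixture_density(tumor, background, tf, seq(-window, window)))
  site_pos <- split(sites$sites$position, sites$sites$chrom)
  site_pos <- lapply(site_pos, sort)

  n_target <- spec$n_fragments
  got <- list(); n_got <- 0
  while (n_got < n_target) {
    n_draw <- ceiling((n_target - n_got) * 1.6 * dmax) + 1000
    ci <- sample.int(length(spans), n_draw, replace = TRUE,
                     prob = spans / sum(spans))
    mid <- margin + floor(stats::runif(n_draw) * spans[ci])
    d <- rep(1, n_draw)
    for (k in seq_along(site_pos)) {
      chrom <- names(site_pos)[k]
      j <- which(names(spans)[ci] == chrom)
      if (!length(j)) next
      sp <- site_pos[[k]]
      near <- findInterval(mid[j], sp)
      dist_lo <- ifelse(near >= 1, mid[j] - sp[pmax(near, 1)], Inf)
      dist_hi <- ifelse(near < length(sp), sp[pmin(near + 1, length(sp))] - mid[j], Inf)
      off <- ifelse(dist_lo <= dist_hi, -dist_lo, dist_hi)
      inw <- abs(off) <= window
      if (any(inw))
        d[j[inw]] <- mixture_density(tumor, background, tf, off[inw])
    }
    keep <- stats::runif(n_draw) < d / dmax
    ci <- ci[keep]; mid <- mid[keep]
    len <- sample_fragment_lengths(length(mid), spec$length_mix)
    start <- mid - ((len - 1) %/% 2)
    end <- start + len
    ok <- start >= 0 & end <= chrom_lengths[ci]
    ci <- ci[ok]; start <- start[ok]; end <- end[ok]; len <- len[ok]
    if (!is.null(spec$gc_bias) && length(start)) {
      gc <- rep(NA_integer_, length(start))
      for (chrom in unique(names(chrom_lengths)[ci])) {
        j <- which(names(chrom_lengths)[ci] == chrom)
        gc[j] <- interval_gc(cache, chrom, start[j], end[j])
      }
      w <- spec$gc_bias(len, gc)
      w[is.na(w)] <- 0
      wmax <- max(w, 1e-12)
      keep2 <- stats::runif(length(w)) < w / wmax
      ci <- ci[keep2]; start <- start[keep2]; end <- end[keep2]; len <- len[keep2]
    }
    if (length(start)) {
      n_got <- n_got + length(start)
      got[[length(got) + 1]] <- data.frame(chrom = names(chrom_lengths)[ci],
                                           start = start, end = end)
    }
  }
  frags <- do.call(rbind, got)
  frags <- frags[seq_len(n_target), , drop = FALSE]
  bam <- write_fragment_bam(frags, chrom_lengths, prefix)
  expected <- expected_composite(tumor, background, tf, window = window)
  list(bam = bam, n_fragments = nrow(frags),
       ground_truth = list(tumor = tumor, background = background,
                           tumor_fraction = tf, sample = spec,
                           expected = expected))
}

#' Write a fragment table as a sorted, indexed BAM of proper pairs
#'
#' @param frags data.frame with `chrom`, `start`, `end` (0-based
#'   half-open fragment spans).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param prefix output prefix; writes `<prefix>.bam` + `.bai`.
#' @param read_length read length (reads overlap when fragments are
#'   shorter than twice this).
#' @param mapq mapping quality stamped on every record.
#' @return Path to the BAM file.
#' @export
write_fragment_bam <- function(frags, chrom_lengths, prefix,
                               read_length = 100, mapq = 60) {
  ord <- order(frags$chrom, frags$start)
  frags <- frags[ord, , drop = FALSE]
  len <- frags$end - frags$start
  rlen <- pmin(read_length, len)
  qname <- sprintf("f%08d", seq_len(nrow(frags)))
  r1 <- sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qname, frags$chrom, frags$start + 1, mapq, rlen,
                frags$end - rlen + 1, len)
  r2 <- sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qname, frags$chrom, frags$end - rlen + 1, mapq, rlen,
                frags$start + 1, -len)
  # interleave so the file stays coordinate-sorted
  recs <- c(rbind(r1, r2))
  pos_all <- c(rbind(frags$start + 1, frags$end - rlen + 1))
  chrom_all <- c(rbind(frags$chrom, frags$chrom))
  ord2 <- order(chrom_all, pos_all)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, recs[ord2]), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Analytic expected composite profile and features
#'
#' Closed-form oracle for end-to-end tests: the trimmed, smoothed,
#' window-normalized composite profile implied by an accessibility
#' mixture, processed with exactly the pipeline's grid, smoothing and
#' normalization conventions, plus the three features extracted from it.
#'
#' @param tumor,background `SiteAccessibilitySpec`s.
#' @param tf tumor fraction.
#' @param config a `griffin_config()` list (grid and smoothing settings).
#' @param window profile half-window (bp).
#' @return A list with `profile` (a trimmed `CompositeProfile`) and
#'   `features` (a `ProfileFeatures` row).
#' @export
expected_composite <- function(tumor, background = NULL, tf = 1,
                               config = griffin_config(), window = 5000) {
  if (is.null(background)) background <- site_accessibility_spec()
  grid <- bin_grid(window, config$bin_size)
  x <- seq(-window, -window + grid$n * config$bin_size - 1)
  d <- mixture_density(tumor, background, tf, x)
  bin_mean <- tapply(d, findInterval(x, grid$starts), mean)
  cp <- composite_profile_obj(values = as.numeric(bin_mean),
                              offsets = grid$starts, state = "raw-mean",
                              provenance = list(source = "analytic"))
  cp <- smooth_and_normalize(cp, config = config, window = window)
  list(profile = cp, features = profile_features(cp, config = config))
}
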