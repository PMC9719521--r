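#' Site lists
#'
#' A `SiteList` is a named collection of single-coordinate genomic sites
#' with scores — the unit over which composite profiles are averaged.
#' Constructors exist for the common catalog dialects: ChIP-seq
#' meta-cluster tables ranked by peak count, DNase I hypersensitivity
#' index tables ranked by sample frequency, and differential ATAC-seq
#' results filtered on adjusted p-value and fold change.
#'
#' @param name list name (e.g. the factor symbol).
#' @param sites data.frame with `chrom`, `position` (0-based site
#'   center), `score`.
#' @param provenance one of `"TFBS"`, `"DHS"`, `"ATAC-diff"`, `"custom"`.
#' @return An object of class `SiteList`. Duplicate (chrom, position)
#'   pairs are collapsed keeping the maximum score.
#' @export
site_list <- function(name, sites, provenance = "custom") {
  stopifnot(all(c("chrom", "position", "score") %in% names(sites)),
            provenance %in% c("TFBS", "DHS", "ATAC-diff", "custom"))
  sites <- sites[, c("chrom", "position", "score")]
  if (nrow(sites)) {
    if (any(sites$position < 0)) stop("site positions must be >= 0")
    # deduplicate on (chrom, position), keeping the highest score
    sites <- sites[order(sites$chrom, sites$position, -sites$score), ]
    dup <- duplicated(sites[, c("chrom", "position")])
    sites <- sites[!dup, , drop = FALSE]
  }
  rownames(sites) <- NULL
  structure(list(name = name, sites = sites, provenance = provenance),
            class = "SiteList")
}

#' @export
print.SiteList <- function(x, ...) {
  cat(sprintf("SiteList '%s' (%s): %d sites\n", x$name, x$provenance,
              nrow(x$sites)))
  invisible(x)
}

autosome_filter <- function(df, allowed = NULL) {
  if (is.null(allowed)) {
    allowed_set <- paste0("chr", 1:22)
    keep <- df$chrom %in% allowed_set | !grepl("^chr[0-9XYM]+$", df$chrom)
  } else {
    keep <- df$chrom %in% allowed
  }
  df[keep, , drop = FALSE]
}

# deterministic ranking: score descending, ties by (chrom, position)
rank_sites <- function(df) {
  df[order(-df$score, df$chrom, df$position), , drop = FALSE]
}

#' Select top-N sites from a meta-cluster table
#'
#' Rows carry `chrom`, `start`, `end` and a score column (peak count);
#' the site position is `floor(mean(start, end))`. Rows are ranked by
#' score descending with a deterministic tie-break (chromosome, then
#' position ascending). Factors with fewer than `min_sites` autosomal
#' rows are excluded (returns `NULL`).
#'
#' @param rows data.frame with `chrom`, `start`, `end` and `score_column`.
#' @param n number of sites to keep.
#' @param score_column name of the ranking column.
#' @param min_sites minimum autosomal sites for the factor to qualify.
#' @param name list name.
#' @param chroms allowed chromosomes (`NULL` = autosomes for chr-style
#'   names, everything otherwise).
#' @return A `SiteList`, or `NULL` when the factor is excluded.
#' @export
select_top_sites <- function(rows, n = 10000, score_column = "peak.count",
                             min_sites = 10000, name = "sites",
                             chroms = NULL) {
  stopifnot(n >= 1)
  needed <- c("chrom", "start", "end", score_column)
  if (!all(needed %in% names(rows))) stop("missing column(s): ",
                                          paste(setdiff(needed, names(rows)), collapse = ", "))
  ok <- stats::complete.cases(rows[, needed])
  if (any(!ok)) message(sum(!ok), " malformed row(s) skipped")
  rows <- rows[ok, , drop = FALSE]
  df <- data.frame(chrom = rows$chrom,
                   position = floor((rows$start + rows$end) / 2),
                   score = rows[[score_column]])
  df <- autosome_filter(df, chroms)
  if (nrow(df) < min_sites) return(NULL)
  df <- rank_sites(df)
  site_list(name, utils::head(df, n), provenance = "TFBS")
}

#' Select top-N DNase I hypersensitive sites
#'
#' The `summit` column is the site position, ranked by `numsamples`
#' (how often the site was observed) descending.
#'
#' @param rows data.frame with `chrom`, `summit`, `numsamples`.
#' @param n number of sites to keep; a warning is issued when the table
#'   is smaller.
#' @param name list name.
#' @param chroms allowed chromosomes (see [select_top_sites()]).
#' @return A `SiteList`.
#' @export
select_dhs_sites <- function(rows, n = 10000, name = "DHS", chroms = NULL) {
  stopifnot(all(c("chrom", "summit", "numsamples") %in% names(rows)))
  df <- data.frame(chrom = rows$chrom, position = rows$summit,
                   score = rows$numsamples)
  df <- autosome_filter(df, chroms)
  if (nrow(df) < n) warning("table has only ", nrow(df), " sites; keeping all")
  df <- rank_sites(df)
  site_list(name, utils::head(df, n), provenance = "DHS")
}

#' Split differential accessibility results into phenotype site lists
#'
#' Sites with adjusted p-value below `padj_max` are split by log2 fold
#' change: `> lfc_min` into the positive-phenotype list, `< -lfc_min`
#' into the negative one. Rows with missing adjusted p-values are
#' dropped. Both thresholds are sweepable.
#'
#' @param rows data.frame with `chrom`, `start`, `end` (or `position`),
#'   `padj`, `log2FoldChange`.
#' @param padj_max adjusted p-value cutoff (default 5e-4).
#' @param lfc_min absolute log2 fold-change cutoff (default 0.5).
#' @param names names for the two lists.
#' @return List of two `SiteList`s: `pos` and `neg`.
#' @export
filter_differential_sites <- function(rows, padj_max = 5e-4, lfc_min = 0.5,
                                      names = c("pos", "neg")) {
  stopifnot(all(c("padj", "log2FoldChange") %in% colnames(rows)))
  if (!"position" %in% names(rows))
    rows$position <- floor((rows$start + rows$end) / 2)
  rows <- rows[!is.na(rows$padj), , drop = FALSE]
  sel <- rows$padj < padj_max
  mk <- function(r, nm) {
    site_list(nm, data.frame(chrom = r$chrom, position = r$position,
                             score = abs(r$log2FoldChange)),
              provenance = "ATAC-diff")
  }
  list(pos = mk(rows[sel & rows$log2FoldChange > lfc_min, , drop = FALSE],
                names[1]),
       neg = mk(rows[sel & rows$log2FoldChange < -lfc_min, , drop = FALSE],
                names[2]))
}

#' Count sites of one list near sites of another
#'
#' A site in `a` is flagged when any site in `b` has a center within
#' `max_dist` bp (inclusive). Runs on sorted positions; equals the
#' quadratic brute force.
#'
#' @param a,b `SiteList`s.
#' @param max_dist maximum center-to-center distance in bp.
#' @return List with `count` (flagged sites in `a`) and `flags` (logical
#'   per site of `a`, in `a`'s stored order).
#' @export
count_overlaps <- function(a, b, max_dist = 500) {
  stopifnot(inherits(a, "SiteList"), inherits(b, "SiteList"), max_dist >= 0)
  flags <- logical(nrow(a$sites))
  bpos <- split(b$sites$position, b$sites$chrom)
  for (chrom in names(bpos)) {
    j <- which(a$sites$chrom == chrom)
    if (!length(j)) next
    bp <- sort(bpos[[chrom]])
    lo <- findInterval(a$sites$position[j] - max_dist - 1, bp)
    hi <- findInterval(a$sites$position[j] + max_dist, bp)
    flags[j] <- hi > lo
  }
  list(count = sum(flags), flags = flags)
}

#' Exclude factors sharing too many sites with the opposite class
#'
#' For each candidate factor, the mean (over factors of the opposite
#' class) of the number of its sites within 250 bp of an opposite-class
#' site is computed; candidates with mean at or above
#' `overlap_mean_max` are excluded.
#'
#' @param candidates named list of `SiteList`s to screen.
#' @param opposite named list of `SiteList`s of the opposite class.
#' @param overlap_mean_max exclusion threshold on the mean shared-site
#'   count (default 400).
#' @param max_dist center distance defining a shared site.
#' @return Character vector of retained candidate names.
#' @export
filter_shared_tfs <- function(candidates, opposite, overlap_mean_max = 400,
                              max_dist = 250) {
  keep <- vapply(names(candidates), function(nm) {
    if (length(opposite) == 0) return(TRUE)
    shares <- vapply(opposite, function(op)
      count_overlaps(candidates[[nm]], op, max_dist)$count, numeric(1))
    mean(shares) < overlap_mean_max
  }, logical(1))
  names(candidates)[keep]
}

#' Partition a site list by sharing with a reference list
#'
#' @param sites a `SiteList`.
#' @param reference a `SiteList` (e.g. hematopoietic open chromatin).
#' @param max_dist center distance defining sharing (default 500 bp).
#' @return List of two `SiteList`s, `shared` and `not_shared`, an exact
#'   partition of `sites`.
#' @export
split_by_shared <- function(sites, reference, max_dist = 500) {
  ov <- count_overlaps(sites, reference, max_dist)
  mk <- function(sel, suffix) {
    site_list(paste0(sites$name, suffix),
              sites$sites[sel, , drop = FALSE], sites$provenance)
  }
  list(shared = mk(ov$flags, "_shared"),
       not_shared = mk(!ov$flags, "_not_shared"))
}

#' GC content profile around sites
#'
#' Per-site GC over +/-1000 bp from the center, positions outside the
#' valid regions masked, smoothed with an order-0 (moving average)
#' Savitzky-Golay filter of 165 bp, then averaged across sites. The
#' summary pairs the mean over the central +/-30 bp with the mean over
#' the remaining flanks.
#'
#' @param sites a `SiteList`.
#' @param genome a `GenomeCache` (or FASTA path / `DNAStringSet`).
#' @param valid optional `RegionSet`; positions outside are masked.
#' @param halfwidth window half-width (bp).
#' @param center_halfwidth central summary half-width (bp).
#' @param sg_bp moving-average window (bp, odd).
#' @return List with `offsets`, `mean_gc` (per-offset mean across
#'   sites), `center`, `flank`, and `n_sites_used`.
#' @export
gc_content_profile <- function(sites, genome, valid = NULL,
                               halfwidth = 1000, center_halfwidth = 30,
                               sg_bp = 165) {
  cache <- genome_cache(genome)
  offs <- seq(-halfwidth, halfwidth)
  acc <- numeric(length(offs)); cnt <- numeric(length(offs))
  used <- 0
  for (i in seq_len(nrow(sites$sites))) {
    chrom <- sites$sites$chrom[i]; pos <- sites$sites$position[i]
    if (pos - halfwidth < 0 || pos + halfwidth + 1 > chrom_length(cache, chrom)) {
      warning("site window leaves ", chrom, "; site skipped")
      next
    }
    p <- pos + offs
    gcv <- as.numeric(interval_gc(cache, chrom, p, p + 1))
    if (!is.null(valid))
      gcv[!region_contains(valid, rep(chrom, length(p)), p, p + 1)] <- NA
    sm <- moving_mean_na(gcv, sg_bp)
    ok <- !is.na(sm)
    acc[ok] <- acc[ok] + sm[ok]
    cnt <- cnt + ok
    used <- used + 1
  }
  if (used == 0) stop("no usable sites")
  mean_gc <- ifelse(cnt > 0, acc / cnt, NA_real_)
  central <- abs(offs) <= center_halfwidth
  list(offsets = offs, mean_gc = mean_gc,
       center = mean(mean_gc[central], na.rm = TRUE),
       flank = mean(mean_gc[!central], na.rm = TRUE),
       n_sites_used = used)
}

# centered moving average of width n ignoring NAs (order-0 smoother)
moving_mean_na <- function(x, n) {
  half <- (n - 1) %/% 2
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  i <- seq_along(x)
  lo <- pmax(i - half, 1); hi <- pmin(i + half, length(x))
  tot <- cs[hi + 1] - cs[lo]; m <- cn[hi + 1] - cn[lo]
  out <- ifelse(m > 0, tot / m, NA_real_)
  out[is.na(x)] <- NA_real_
  out
}

#' Read a site list from a BED-like TSV
#'
#' @param path TSV with columns `chrom`, `position`, `score`.
#' @param name list name (default: file base name).
#' @return A `SiteList`.
#' @export
read_site_list <- function(path, name = NULL) {
  df <- utils::read.delim(path, comment.char = "#")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  site_list(name, df)
}

#' Write a site list as a BED-like TSV
#'
#' @param sites a `SiteList`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_list <- function(sites, path) {
  utils::write.table(sites$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
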