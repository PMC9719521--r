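# shared internal helpers

local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# deterministic per-iteration substream seed, kept below 2^31
sub_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 1000003) %% 2147483647)
}

#' The frozen profile bin grid
#'
#' `n = floor(2 * window / bin_size)` bins of `bin_size` bp, bin `i`
#' (0-based) spanning `[-window + bin_size*i, -window + bin_size*(i+1))`
#' relative to the site center; with the defaults, 666 bins of 15 bp
#' spanning `[-5000, +4990)`, offset 0 falling in bin 333. All windowed
#' features use this grid.
#'
#' @param window profile half-window in bp.
#' @param bin_size bin width in bp.
#' @return List with `n`, `bin_size`, `starts` and `centers` (bp
#'   offsets relative to the site).
#' @export
bin_grid <- function(window = 5000, bin_size = 15) {
  n <- as.integer(2 * window / bin_size)
  starts <- -window + bin_size * (0:(n - 1))
  list(n = n, bin_size = bin_size, starts = starts,
       centers = starts + bin_size / 2)
}

# rank-statistic AUC with tie correction; labels logical/0-1, higher
# score = more positive
auc_rank <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# most frequent value; ties broken toward the smaller value (stronger
# regularization when applied to an inverse-strength grid)
mode_smallest <- function(x) {
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  min(as.numeric(best))
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# linear interpolation across NA runs (ends extended); used before
# Savitzky-Golay filtering of masked profiles
fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2) stop("empty profile")
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

# TRUE where [start, end) is fully contained in one interval of `regions`
region_contains <- function(regions, chrom, start, end) {
  out <- logical(length(start))
  for (ch in unique(chrom)) {
    j <- chrom == ch
    d <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    idx <- findInterval(start[j], d$start)
    hit <- idx >= 1
    hit[hit] <- end[j][hit] <= d$end[idx[hit]]
    out[j] <- hit
  }
  out
}
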