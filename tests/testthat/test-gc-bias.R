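test_that("sample GC counting applies quality and admissibility rules", {
  # 60 bp "chromosome" with a known 4-mer at position 20
  chars <- rep("A", 60); chars[21:24] <- c("C", "G", "C", "A")
  cache <- test_cache(cQ = paste(chars, collapse = ""))
  lens <- c(cQ = 60)
  valid <- region_set("cQ", 0, 60)

  mk <- function(...) write_records_bam(data.frame(...), lens)
  base <- list(chrom = "cQ", start = 20, end = 24)

  cnt <- count_sample_gc(do.call(mk, base), cache, valid,
                         length_range = c(4, 4))
  expect_equal(unname(cnt$counts["4", "3"]), 1)
  expect_equal(cnt$n_fragments_used, 1)

  # duplicates and low mapping quality are excluded
  expect_warning(
    cnt_dup <- count_sample_gc(do.call(mk, c(base, dup = TRUE)), cache,
                               valid, length_range = c(4, 4)),
    "no accepted fragments")
  expect_equal(sum(cnt_dup$counts), 0)
  expect_warning(
    cnt_mq <- count_sample_gc(do.call(mk, c(base, mapq = 10)), cache,
                              valid, length_range = c(4, 4)),
    "no accepted fragments")
  expect_equal(sum(cnt_mq$counts), 0)
  expect_warning(
    cnt_qc <- count_sample_gc(do.call(mk, c(base, qcfail = TRUE)), cache,
                              valid, length_range = c(4, 4)),
    "no accepted fragments")
  expect_equal(sum(cnt_qc$counts), 0)

  # fragment not contained in a valid interval is excluded
  expect_warning(
    cnt_out <- count_sample_gc(do.call(mk, base), cache,
                               region_set("cQ", 0, 22),
                               length_range = c(4, 4)),
    "no accepted fragments")
  expect_equal(sum(cnt_out$counts), 0)
})

test_that("raw bias is counts over frequencies, mean 1 per length", {
  mkc <- function(m) structure(list(counts = m, length_range = c(2, 2),
                                    n_fragments_used = sum(m)),
                               class = "GCCounts")
  mkf <- function(m) structure(list(counts = m, length_range = c(2, 2)),
                               class = "GenomeGCFrequencies")
  cm <- matrix(c(5, 15, 0), 1, 3, dimnames = list(length = "2", gc = 0:2))
  fm <- matrix(c(10, 10, 0), 1, 3, dimnames = list(length = "2", gc = 0:2))
  b <- compute_raw_gc_bias(mkc(cm), mkf(fm))
  expect_equal(unname(b["2", c("0", "1")]), c(0.5, 1.5))
  expect_true(is.na(b["2", "2"]))  # never observed in the genome

  # counts proportional to frequencies -> bias identically 1
  cm2 <- matrix(c(4, 4, 2), 1, 3, dimnames = dimnames(cm))
  fm2 <- matrix(c(20, 20, 10), 1, 3, dimnames = dimnames(cm))
  expect_equal(unname(compute_raw_gc_bias(mkc(cm2), mkf(fm2))["2", ]),
               c(1, 1, 1))

  # length absent from the genome frequencies is an error naming it
  fm3 <- mkf(matrix(1, 1, 3, dimnames = list(length = "3", gc = 0:2)))
  expect_error(compute_raw_gc_bias(mkc(cm), fm3), "2")
})

test_that("kNN-median smoothing follows the stated rule", {
  # median of k = 3 nearest neighbours flattens a spike
  expect_equal(griffin:::knn_median(c(1, 1, 10, 1, 1), 3), rep(1, 5))
  # the production k rule: 5% of the vector or 50, whichever is greater
  expect_equal(max(50, ceiling(0.05 * 400)), 50)
  expect_equal(max(50, ceiling(0.05 * 2000)), 100)

  # constant bias is unchanged by smoothing
  raw <- matrix(1, 3, 11, dimnames = list(length = 10:12, gc = 0:10))
  sm <- smooth_gc_bias(raw, k_rule = 5)
  expect_equal(unname(sm$bias), unname(raw))

  # spike flattened through the model interface with a test k
  raw2 <- matrix(NA_real_, 1, 6, dimnames = list(length = "5", gc = 0:5))
  raw2[1, ] <- c(1, 1, 10, 1, 1, 1)
  sm2 <- smooth_gc_bias(raw2, k_rule = 3)
  expect_equal(unname(sm2$bias[1, ]), rep(1, 6))

  # k larger than the pooled vector is clamped with a warning
  expect_warning(smooth_gc_bias(raw2, k_rule = 99), "clamping")
  expect_error(smooth_gc_bias(matrix(NA_real_, 1, 2,
                                     dimnames = list(length = "1", gc = 0:1))),
               "empty")
})

test_that("per-length mean stays 1 after smoothing", {
  set.seed(31)
  lens <- 40:60
  raw <- matrix(NA_real_, length(lens), 61,
                dimnames = list(length = lens, gc = 0:60))
  for (i in seq_along(lens)) {
    g <- 5:(lens[i] - 5)
    v <- exp(rnorm(length(g), sd = 0.4))
    raw[i, g + 1] <- v / mean(v)
  }
  sm <- smooth_gc_bias(raw)
  for (i in seq_along(lens)) {
    obs <- !is.na(sm$bias[i, ])
    expect_lt(abs(mean(sm$bias[i, obs]) - 1), 1e-6)
  }
})

test_that("fragment weights invert bias with an exclusion sentinel", {
  bias <- matrix(NA_real_, 1, 201, dimnames = list(length = 165, gc = 0:200))
  bias[1, 81] <- 2.11; bias[1, 82] <- 1; bias[1, 83] <- 0.01
  model <- structure(list(bias = bias, raw = bias,
                          length_range = c(165, 165),
                          mode = "multi-length"), class = "GCBiasModel")
  w <- fragment_weight(model, c(165, 165, 165, 165), c(80, 81, 99, 82))
  expect_equal(w[1], 1 / 2.11, tolerance = 1e-12)
  expect_equal(w[2], 1)
  expect_equal(w[3], 0)     # missing combination -> excluded
  expect_equal(w[4], 0)     # bias below the floor -> excluded
  # single-length mode maps any fragment to the closest 165 bp GC
  model$mode <- "single-length-165"
  expect_equal(fragment_weight(model, 330, 160), 1 / 2.11,
               tolerance = 1e-12)
})

test_that("weighting inverts an injected bias end to end", {
  env <- load_scenarios()
  lr <- c(130, 170)
  G <- 15000
  lens <- c(chrCal = G)
  genome <- simulate_genome(synthetic_genome_spec(lens, gc = 0.41), seed = 61)
  cache <- genome_cache(genome)
  valid <- region_set(names(lens), 800, G - 800)
  freqs <- compute_genome_gc_frequencies(cache, valid, lr)
  biasfun <- env$scn_bias_curve(1.2)
  flat <- site_accessibility_spec()
  sp <- sample_spec(n_fragments = 1e5, gc_bias = biasfun, seed = 62,
                    length_mix = list(means = 150, sds = 30, weights = 1))
  sim <- simulate_fragments(cache, simulate_site_list(0, lens), flat, flat,
                            sp, prefix = tempfile("inv"))
  model <- estimate_gc_bias(sim$bam, cache, valid, freqs, length_range = lr)
  frags <- griffin:::scan_fragments(sim$bam)[[1]]
  len <- frags$end - frags$start
  keep <- len >= lr[1] & len <= lr[2] &
    griffin:::region_contains(valid, frags$chrom, frags$start, frags$end)
  frags <- frags[keep, ]; len <- len[keep]
  g <- interval_gc(cache, "chrCal", frags$start, frags$end)
  w <- fragment_weight(model, len, g)
  # weighted GC histogram should match the genome frequencies in shape;
  # pool into GC-fraction bins and compare with a chi-square GOF test
  gf_breaks <- seq(0.25, 0.65, by = 0.05)
  gf <- pmin(pmax(g / len, 0.2500001), 0.6499999)
  obs <- tapply(w, cut(gf, gf_breaks), sum)
  lens_m <- as.integer(rownames(freqs$counts))
  exp_gf <- rep(0, length(gf_breaks) - 1)
  nl <- tabulate(len - lr[1] + 1, nbins = length(lens_m))
  for (i in seq_along(lens_m)) {
    gg <- which(freqs$counts[i, ] > 0) - 1
    p <- freqs$counts[i, gg + 1] / sum(freqs$counts[i, ])
    gfl <- pmin(pmax(gg / lens_m[i], 0.2500001), 0.6499999)
    exp_gf <- exp_gf + nl[i] * tapply(p, cut(gfl, gf_breaks), sum,
                                      default = 0)
  }
  obs[is.na(obs)] <- 0; exp_gf[is.na(exp_gf)] <- 0
  keep_bin <- exp_gf > 50
  gof <- suppressWarnings(
    chisq.test(obs[keep_bin], p = exp_gf[keep_bin] / sum(exp_gf[keep_bin]),
               rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
  unlink(paste0(sim$bam, c("", ".bai")))
})

test_that("single-length model builds a 165 bp pseudo-fragment curve", {
  set.seed(71)
  G <- 30000
  seq1 <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  cache <- test_cache(cS = seq1)
  lens <- c(cS = G)
  valid <- region_set("cS", 0, G)
  n <- 20000
  start <- sample.int(G - 400, n)
  frags <- data.frame(chrom = "cS", start = start, end = start + 166)
  bam <- write_records_bam(frags, lens)
  # the single 165 bp pool is smaller than the production k; the clamp
  # warning is expected at this fixture size
  model <- suppressWarnings(single_length_gc_bias(bam, cache, valid))
  expect_equal(model$mode, "single-length-165")
  expect_equal(as.integer(rownames(model$bias)), 165L)
  # uniform unbiased reads: bias ~ 1 where the genome has mass
  fr <- compute_genome_gc_frequencies(cache, valid, c(165, 165))
  dense <- which(fr$counts[1, ] > 2000) - 1
  expect_lt(max(abs(model$bias[1, dense + 1] - 1)), 0.15)
})

test_that("GC bias models round-trip through TSV", {
  raw <- matrix(NA_real_, 2, 6, dimnames = list(length = 4:5, gc = 0:5))
  raw[1, 1:5] <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  raw[2, 2:6] <- c(1.2, 1.1, 1.0, 0.9, 0.8)
  model <- smooth_gc_bias(raw, k_rule = 1)
  path <- tempfile(fileext = ".tsv")
  write_gc_bias_model(model, path)
  back <- read_gc_bias_model(path)
  expect_equal(back$bias[!is.na(back$bias)], model$bias[!is.na(model$bias)])
})
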