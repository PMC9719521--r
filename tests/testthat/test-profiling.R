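test_that("fragment collection filters by length, grid and contig edges", {
  ts <- tiny_sim()
  pos <- ts$sites$sites$position[1]
  chrom <- ts$sites$sites$chrom[1]
  frags <- data.frame(
    chrom = chrom,
    start = c(pos - 75, pos - 49, pos + 5090),     # lengths 150, 99, 150
    end   = c(pos + 75, pos + 50, pos + 5240))
  bam <- write_records_bam(frags, ts$lens)
  one_site <- site_list("one", ts$sites$sites[1, ])
  col <- collect_fragments(bam, one_site, ts$cache)
  f <- col$fragments[[1]]
  # length-99 fragment excluded; the last midpoint (offset +5165) is
  # off-grid and excluded
  expect_equal(f$length, 150)
  expect_equal(f$midpoint, pos - 1)  # floor((start + end - 1) / 2)
  expect_equal(f$bin, 333)

  # a site too close to the contig edge is skipped with a warning
  edge_sites <- site_list("edge", data.frame(
    chrom = chrom, position = c(1000, pos), score = 1))
  expect_warning(col2 <- collect_fragments(bam, edge_sites, ts$cache),
                 "contig edge")
  expect_equal(nrow(col2$sites), 1)
  expect_equal(col2$n_skipped_sites, 1)
})

test_that("weighted midpoint binning matches the stated grid arithmetic", {
  cfg <- griffin_config()
  site <- 50000
  col <- function(mids, lens = rep(150, length(mids))) {
    start <- mids - ((lens - 1) %/% 2)
    bin <- (mids - site + cfg$window) %/% cfg$bin_size
    list(fragments = list(list(start = start, end = start + lens,
                               length = lens, midpoint = mids, bin = bin)),
         sites = data.frame(chrom = "c", position = site, score = 1),
         n_skipped_sites = 0, window = cfg$window, bin_size = cfg$bin_size)
  }
  # one fragment with midpoint at the site and weight 0.5
  sps <- bin_midpoints(col(site), list(0.5))
  expect_equal(sps$counts[1, 334], 0.5)
  expect_equal(sum(sps$counts), 0.5)
  # midpoints at offsets 0 and 7 share bin 333 (0-based)
  sps2 <- bin_midpoints(col(c(site, site + 7)))
  expect_equal(sps2$counts[1, 334], 2)
  # a weight-0 (bias-excluded) fragment contributes nothing
  sps3 <- bin_midpoints(col(site), list(0))
  expect_equal(sum(sps3$counts), 0)
  expect_equal(sps3$n_excluded_fragments, 1)
})

test_that("bins are masked by exclusions, mappability and outliers", {
  cfg <- griffin_config()
  site <- 50000
  grid <- bin_grid()
  mids <- site + rep(seq(-4900, 4900, by = 100), 2)
  start <- mids - 74
  col <- list(fragments = list(list(start = start, end = start + 150,
                                    length = rep(150, length(mids)),
                                    midpoint = mids,
                                    bin = (mids - site + 5000) %/% 15)),
              sites = data.frame(chrom = "c", position = site, score = 1),
              n_skipped_sites = 0, window = 5000, bin_size = 15)
  sps <- bin_midpoints(col)

  # an exclusion overlapping bin 0 masks it; clean bins keep values
  valid <- region_setdiff(region_set("c", 0, 100000),
                          region_set("c", site - 5000, site - 4990))
  m1 <- mask_bins(sps, valid, outlier_sd = Inf)
  expect_true(m1$mask[1, 1])
  expect_true(is.na(m1$counts[1, 1]))
  expect_false(any(m1$mask[1, -1]))

  # masking monotonicity: a new exclusion never changes unmasked bins
  valid2 <- region_setdiff(valid, region_set("c", site, site + 1))
  m2 <- mask_bins(bin_midpoints(col), valid2, outlier_sd = Inf)
  still <- !m2$mask[1, ]
  expect_equal(m2$counts[1, still], m1$counts[1, still])

  # a bin at mean + 11 SD of the pooled statistic is masked
  sps_out <- bin_midpoints(col)
  base_sd <- sd(sps_out$counts[1, ])
  spike <- mean(sps_out$counts[1, ]) + 11 * base_sd * 40
  sps_out$counts[1, 400] <- spike
  m3 <- mask_bins(sps_out, valid = NULL, outlier_sd = 10)
  expect_true(m3$mask[1, 400])
  expect_false(m3$mask[1, 399])
})

test_that("composites average sites ignoring masked bins", {
  mk <- function(counts, mask = NULL) {
    n <- ncol(counts)
    sps <- structure(list(counts = counts, raw = counts,
                          mask = matrix(FALSE, nrow(counts), n),
                          sites = data.frame(chrom = "c",
                                             position = seq_len(nrow(counts)),
                                             score = 1),
                          offsets = seq_len(n), bin_size = 15, window = 5000,
                          n_excluded_fragments = 0),
                     class = "SiteProfileSet")
    if (!is.null(mask)) { sps$mask <- mask; sps$counts[mask] <- NA_real_ }
    sps
  }
  cp <- composite_profile(mk(rbind(c(1, 2), c(3, 4))))
  expect_equal(cp$values, c(2, 3))
  expect_equal(cp$state, "raw-mean")

  # bin masked at one of two sites -> mean of the unmasked value
  mask <- rbind(c(TRUE, FALSE), c(FALSE, FALSE))
  cp2 <- composite_profile(mk(rbind(c(9, 2), c(3, 4)), mask))
  expect_equal(cp2$values, c(3, 3))

  # single site -> itself; all-masked bin -> NA
  cp3 <- composite_profile(mk(rbind(c(5, 7))))
  expect_equal(cp3$values, c(5, 7))
  mask4 <- rbind(c(TRUE, FALSE))
  cp4 <- composite_profile(mk(rbind(c(5, 7)), mask4))
  expect_true(is.na(cp4$values[1]))
})

test_that("smoothing preserves constants and cubics, normalizes, trims", {
  cfg <- griffin_config()
  grid <- bin_grid()
  mkcp <- function(v) structure(list(offsets = grid$starts, values = v,
                                     state = "raw-mean", provenance = list()),
                                class = "CompositeProfile")
  # constant profile -> exactly ones after normalization
  out <- smooth_and_normalize(mkcp(rep(4.2, grid$n)), cfg)
  expect_equal(out$values, rep(1, 133))
  expect_equal(out$state, "trimmed")
  expect_equal(range(out$offsets + cfg$bin_size / 2), c(-987.5, 992.5))

  # a cubic is reproduced exactly by the order-3 filter
  x <- seq_len(grid$n) / grid$n
  cubic <- 2 + x + 0.5 * x^2 - 0.3 * x^3
  sm <- signal::sgolayfilt(cubic, p = cfg$sg_order,
                           n = cfg$sg_window_bp / cfg$bin_size)
  expect_equal(sm, cubic, tolerance = 1e-9)
  out2 <- smooth_and_normalize(mkcp(cubic), cfg)
  keep <- abs(grid$centers) <= cfg$trim_halfwidth
  expect_equal(out2$values, (cubic / mean(sm))[keep], tolerance = 1e-9)

  # the full +/-5 kb mean is 1 before trimming by construction
  v <- runif(grid$n, 0.5, 1.5)
  sm_v <- signal::sgolayfilt(v, p = 3, n = 11)
  out3 <- smooth_and_normalize(mkcp(v), cfg)
  expect_equal(mean(sm_v / mean(sm_v)), 1)

  expect_error(smooth_and_normalize(mkcp(rep(NA_real_, grid$n)), cfg),
               "empty profile")
})

test_that("local copy-number correction rescales by the running mean", {
  # constant coverage -> all ones
  n_ext <- (2 * 55000) %/% 15
  expect_equal(unique(cna_local_correct(rep(2, n_ext))), 1)
  # a value of 3 against a local mean of 2 -> 1.5
  v <- rep(2, n_ext)
  ctr <- (n_ext - 666) %/% 2 + 333
  v[ctr] <- 3
  out <- cna_local_correct(v)
  expect_equal(out[333], 3 / mean(v[(ctr - 3333):(ctr + 3333)]),
               tolerance = 1e-6)
  # zero local mean -> masked site with a warning
  expect_warning(out0 <- cna_local_correct(rep(0, n_ext)), "zero")
  expect_true(all(is.na(out0)))
})

test_that("the profiling pipeline recovers the simulated signal", {
  ts <- tiny_sim()
  cfg <- griffin_config()
  cp <- nucleosome_profile(ts$sim$bam, ts$sites, ts$cache,
                           valid = ts$valid, config = cfg)
  truth <- expected_composite(ts$tumor, ts$bg, tf = 0.5, config = cfg)
  # 80k fragments over 30 sites: agreement within counting noise
  # (~90 weighted midpoints per composite bin)
  expect_lt(max(abs(cp$values - truth$profile$values)), 0.25)
  expect_lt(abs(central_coverage(cp, cfg) -
                  truth$features$central_coverage), 0.10)
  expect_equal(length(cp$values), 133)
})
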