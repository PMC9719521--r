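test_that("simulated genomes are reproducible with controlled GC", {
  lens <- c(cG = 60000)
  spec <- synthetic_genome_spec(lens, gc = 0.5)
  g1 <- simulate_genome(spec, seed = 3)
  g2 <- simulate_genome(spec, seed = 3)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- simulate_genome(spec, seed = 4)
  expect_false(identical(as.character(g1), as.character(g3)))

  # GC of any 10 kb window within 2% of the specification
  cache <- genome_cache(g1)
  for (s in seq(0, 50000, by = 10000)) {
    gc <- interval_gc(cache, "cG", s, s + 10000) / 10000
    expect_lt(abs(gc - 0.5), 0.02)
  }

  # enriched intervals reach their own GC level
  spec2 <- synthetic_genome_spec(c(cG = 60000), gc = 0.4,
                                 enriched = data.frame(chrom = "cG",
                                                       start = 20000,
                                                       end = 30000),
                                 gc_enriched = 0.7)
  cache2 <- genome_cache(simulate_genome(spec2, seed = 5))
  expect_lt(abs(interval_gc(cache2, "cG", 21000, 29000) / 8000 - 0.7), 0.02)
  expect_lt(abs(interval_gc(cache2, "cG", 0, 19000) / 19000 - 0.4), 0.02)

  # blocky heterogeneity spreads window GC without moving the mean much
  spec3 <- synthetic_genome_spec(c(cG = 200000), gc = 0.45,
                                 gc_spread = 0.2, block_size = 800)
  cache3 <- genome_cache(simulate_genome(spec3, seed = 6))
  block_gc <- vapply(seq(0, 199200, by = 800), function(s)
    interval_gc(cache3, "cG", s, s + 800) / 800, numeric(1))
  expect_gt(sd(block_gc), 0.08)
  expect_lt(abs(mean(block_gc) - 0.45), 0.01)
})

test_that("site placement respects spacing and stays uniform", {
  lens <- c(cA = 2.6e6, cB = 2.6e6)
  expect_equal(nrow(simulate_site_list(0, lens)$sites), 0)
  sl <- simulate_site_list(400, lens, seed = 8)
  expect_equal(nrow(sl$sites), 400)
  for (ch in names(lens)) {
    pos <- sort(sl$sites$position[sl$sites$chrom == ch])
    expect_true(all(diff(pos) >= 12000))
    expect_true(all(pos >= 6000 & pos <= lens[ch] - 6000))
    ks <- suppressWarnings(ks.test(pos, "punif", 6000, lens[[ch]] - 6000))
    expect_gt(ks$p.value, 0.01)
  }
  expect_error(simulate_site_list(1000, c(cA = 1e6)), "too small")
})

test_that("fragment midpoints follow the specified density", {
  lens <- c(cF = 300000)
  cache <- genome_cache(simulate_genome(synthetic_genome_spec(lens, gc = 0.5),
                                        seed = 9))
  flat <- site_accessibility_spec()
  # no sites, no bias: uniform midpoints (chi-square over 10 kb bins)
  sp <- sample_spec(n_fragments = 3e4, seed = 10)
  sim <- simulate_fragments(cache, simulate_site_list(0, lens), flat, flat,
                            sp, prefix = tempfile("unif"))
  expect_equal(sim$n_fragments, 3e4)
  fr <- griffin:::scan_fragments(sim$bam)[[1]]
  mid <- (fr$start + fr$end - 1) %/% 2
  inner <- mid[mid >= 10000 & mid < 290000]
  h <- tabulate((inner - 10000) %/% 10000 + 1, nbins = 28)
  gof <- suppressWarnings(chisq.test(h))
  expect_gt(gof$p.value, 0.01)
  # fragment lengths live in the declared support
  len <- fr$end - fr$start
  expect_true(all(len >= 35 & len <= 500))
  unlink(paste0(sim$bam, c("", ".bai")))

  # tf = 0 -> pure background density (deep dip visible at sites)
  sites <- simulate_site_list(20, c(cF2 = 400000), seed = 11)
  cache2 <- genome_cache(simulate_genome(
    synthetic_genome_spec(c(cF2 = 400000), gc = 0.5), seed = 12))
  tumor <- site_accessibility_spec(dip = 0)          # tumor keeps flat
  bg <- site_accessibility_spec(dip = 0.9, dip_width = 100)
  sp2 <- sample_spec(tumor_fraction = 0, n_fragments = 6e4, seed = 13)
  sim2 <- simulate_fragments(cache2, sites, tumor, bg, sp2,
                             prefix = tempfile("tf0"))
  fr2 <- griffin:::scan_fragments(sim2$bam)[[1]]
  mid2 <- (fr2$start + fr2$end - 1) %/% 2
  near <- outer(mid2, sites$sites$position, "-")
  at_center <- rowSums(abs(near) <= 100) > 0
  at_flank <- rowSums(abs(near) >= 2000 & abs(near) <= 2100) > 0
  # background dip 0.9: center density ~10% of flank density
  expect_lt(sum(at_center) / sum(at_flank), 0.35)
  unlink(paste0(sim2$bam, c("", ".bai")))
})

test_that("injected GC bias shifts the fragment GC distribution as predicted", {
  env <- load_scenarios()
  G <- 40000
  lens <- c(cB = G)
  cache <- genome_cache(simulate_genome(synthetic_genome_spec(lens, gc = 0.5),
                                        seed = 14))
  valid <- region_set("cB", 800, G - 800)
  lr <- c(140, 160)
  freqs <- compute_genome_gc_frequencies(cache, valid, lr)
  flat <- site_accessibility_spec()
  w <- env$scn_bias_curve(2, pivot = 0.5)
  sp <- sample_spec(n_fragments = 4e4, gc_bias = w, seed = 15,
                    length_mix = list(means = 150, sds = 5, weights = 1))
  sim <- simulate_fragments(cache, simulate_site_list(0, lens), flat, flat,
                            sp, prefix = tempfile("gcb"))
  cnt <- count_sample_gc(sim$bam, cache, valid, length_range = lr)
  # observed counts at L=150 vs the analytic expectation freq * w
  i <- match(150, as.integer(rownames(cnt$counts)))
  fl <- freqs$counts[i, seq_len(ncol(cnt$counts))]
  g <- which(fl > 200) - 1
  expected <- fl[g + 1] * w(150, g)
  expected <- expected / sum(expected) * sum(cnt$counts[i, g + 1])
  # correlation of observed against expectation is near-perfect, and
  # the mean GC is shifted upward relative to the genome
  expect_gt(cor(cnt$counts[i, g + 1], expected), 0.98)
  # analytic mean shift for an exponential tilt: beta * Var(g) / L
  # = 2 * (150 * 0.25) / 150 = 0.5 GC units
  mean_gc_obs <- sum((g) * cnt$counts[i, g + 1]) / sum(cnt$counts[i, g + 1])
  mean_gc_genome <- sum((g) * fl[g + 1]) / sum(fl[g + 1])
  expect_gt(mean_gc_obs, mean_gc_genome + 0.3)
  expect_lt(mean_gc_obs, mean_gc_genome + 0.8)
  unlink(paste0(sim$bam, c("", ".bai")))
})

test_that("fragment tables round-trip through BAM", {
  lens <- c(cR = 5000)
  frags <- data.frame(chrom = "cR",
                      start = c(100, 220, 1500),
                      end = c(265, 400, 1640))
  bam <- write_fragment_bam(frags, lens, tempfile("rt"))
  back <- griffin:::scan_fragments(bam)[[1]]
  expect_equal(back$start, sort(frags$start))
  expect_equal(back$end[order(back$start)],
               frags$end[order(frags$start)])
  unlink(paste0(bam, c("", ".bai")))
})

test_that("analytic expected composites behave at the limits", {
  cfg <- griffin_config()
  bg <- site_accessibility_spec(dip = 0.5, amplitude = 0.1)
  tu <- site_accessibility_spec(dip = 0.9, amplitude = 0.2)
  # tf = 0 -> exactly the background profile
  e0 <- expected_composite(tu, bg, tf = 0, config = cfg)
  eb <- expected_composite(bg, bg, tf = 1, config = cfg)
  expect_equal(e0$profile$values, eb$profile$values)
  # profile normalization target holds
  expect_equal(e0$profile$state, "trimmed")
  # degenerate spec refused: undamped phasing overshooting zero
  expect_error(site_accessibility_spec(amplitude = 1.5, decay = 1e6),
               "clips")
})
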