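# fixtures built in code: tiny genomes, handcrafted alignments, and a
# memoised small simulated sample shared across test files

test_cache <- function(...) {
  seqs <- c(...)
  genome_cache(Biostrings::DNAStringSet(seqs))
}

# write explicit paired records to a sorted indexed BAM; `frags` needs
# chrom/start/end (0-based half-open) and may carry mapq, dup, qcfail
write_records_bam <- function(frags, chrom_lengths,
                              prefix = tempfile("rec")) {
  n <- nrow(frags)
  mapq <- if ("mapq" %in% names(frags)) frags$mapq else rep(60, n)
  dup <- if ("dup" %in% names(frags)) frags$dup else rep(FALSE, n)
  qcfail <- if ("qcfail" %in% names(frags)) frags$qcfail else rep(FALSE, n)
  len <- frags$end - frags$start
  rlen <- pmin(100, len)
  f1 <- 99 + dup * 1024 + qcfail * 512
  f2 <- 147 + dup * 1024 + qcfail * 512
  r1 <- sprintf("q%04d\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                seq_len(n), f1, frags$chrom, frags$start + 1, mapq, rlen,
                frags$end - rlen + 1, len)
  r2 <- sprintf("q%04d\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                seq_len(n), f2, frags$chrom, frags$end - rlen + 1, mapq,
                rlen, frags$start + 1, -len)
  recs <- c(rbind(r1, r2))
  pos <- c(rbind(frags$start + 1, frags$end - rlen + 1))
  chrom <- c(rbind(frags$chrom, frags$chrom))
  ord <- order(chrom, pos)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, recs[ord]), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# build a trimmed CompositeProfile directly from values on the default
# trimmed grid (133 bins, centers within +/-1 kb)
make_trimmed_profile <- function(values = NULL, fill = 1,
                                 config = griffin_config()) {
  grid <- bin_grid(config$window, config$bin_size)
  keep <- abs(grid$centers) <= config$trim_halfwidth
  offs <- grid$starts[keep]
  if (is.null(values)) values <- rep(fill, sum(keep))
  stopifnot(length(values) == sum(keep))
  structure(list(offsets = offs, values = values, state = "trimmed",
                 provenance = list()), class = "CompositeProfile")
}

# memoised small end-to-end sample: 400 kb genome, 30 sites, 40k
# fragments with a known accessibility signal, no injected bias
.tiny_sim_env <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (!exists("sim", envir = .tiny_sim_env)) {
    lens <- c(chrT1 = 400000)
    sites <- simulate_site_list(30, lens, seed = 42)
    genome <- simulate_genome(synthetic_genome_spec(lens, gc = 0.45),
                              seed = 43)
    cache <- genome_cache(genome)
    valid <- region_set(names(lens), 0, lens)
    tumor <- site_accessibility_spec(dip = 0.6, amplitude = 0.15)
    bg <- site_accessibility_spec(dip = 0, amplitude = 0.05)
    sp <- sample_spec(tumor_fraction = 0.5, n_fragments = 8e4, seed = 44)
    sim <- simulate_fragments(cache, sites, tumor, bg, sp,
                              prefix = tempfile("tiny"))
    assign("sim", list(lens = lens, sites = sites, cache = cache,
                       valid = valid, tumor = tumor, bg = bg, sim = sim),
           envir = .tiny_sim_env)
  }
  get("sim", envir = .tiny_sim_env)
}

scenario_env <- new.env(parent = globalenv())
load_scenarios <- function() {
  if (!exists("loaded", envir = scenario_env)) {
    sys.source(system.file("scenarios", "scenarios.R", package = "griffin"),
               envir = scenario_env)
    assign("loaded", TRUE, envir = scenario_env)
  }
  scenario_env
}
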