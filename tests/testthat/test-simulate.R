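# Ground-truth generator and read samplers.

test_that("generation is deterministic and honours timing fractions", {
  cfg <- sim_config(genome_length = 120000L, n_chroms = 1L, n_genes = 48L,
                    n_origins = 8L, min_origin_spacing = 3000L, seed = 5L)
  a <- generate_genome_and_annotations(cfg)
  b <- generate_genome_and_annotations(cfg)
  expect_identical(unclass(a$genome)[1], unclass(b$genome)[1])
  expect_identical(a$origins, b$origins)
  expect_identical(a$architecture$dyads, b$architecture$dyads)

  cfg2 <- sim_config(genome_length = 120000L, n_chroms = 1L, n_genes = 48L,
                     n_origins = 8L, min_origin_spacing = 3000L,
                     fraction_early = 1, seed = 5L)
  all_early <- generate_genome_and_annotations(cfg2)
  expect_true(all(all_early$origins$timing == "early"))
})

test_that("planted class widths are recorded exactly and origins sit in IGRs", {
  sim <- fx_sim()
  ct <- default_class_table()
  expect_equal(range(ct$ndr_width), c(129L, 193L))
  arch <- sim$architecture
  expect_equal(sort(unique(arch$ndr_width[arch$class_id == 1])), 193L)
  expect_equal(sort(unique(arch$ndr_width[arch$class_id == 6])), 129L)
  # every ACS midpoint lies in an intergenic region
  igrs <- build_igrs(sim$genes)
  cats <- origin_igr_category(sim$origins, igrs)
  expect_false(any(cats$category == "intragenic"))
  # adjacent planted dyads keep at least a footprint of separation
  gaps <- unlist(lapply(arch$dyads, diff))
  expect_true(all(gaps >= 147))
})

test_that("requesting more origins than available IGRs errors", {
  cfg <- sim_config(genome_length = 50000L, n_chroms = 1L, n_genes = 20L,
                    n_origins = 40L, seed = 2L)
  expect_error(generate_genome_and_annotations(cfg), "not enough intergenic")
})

test_that("idealized sampling piles 5' ends at the planted fragment edges", {
  cfg <- sim_config(genome_length = 60000L, n_chroms = 1L, n_genes = 25L,
                    n_origins = 2L, min_origin_spacing = 2000L,
                    bg_fuzziness_sd = 0, fragment_length_sd = 0,
                    bg_occupancy = 1,
                    class_table = dplyr::mutate(default_class_table(),
                                                fuzziness_sd = 0, occupancy = 1),
                    seed = 9L)
  sim <- generate_genome_and_annotations(cfg)
  st <- sample_mononucleosome_reads(sim, "G1")
  chr <- names(chrom_lengths(sim$genome))[1]
  d <- sim$architecture$dyads[[1]][4]           # a +1 planted dyad
  expect_gt(st$plus[[chr]][d - 73 + 1], 0)
  expect_gt(st$minus[[chr]][d + 74], 0)
  # and nowhere in between
  expect_equal(sum(st$plus[[chr]][(d - 60):(d + 60)]), 0)

  # empirical boundary spacing equals the footprint in the zero-jitter limit
  sp <- estimate_average_spacing(boundary_peaks(st))
  expect_lte(abs(sp - 147), 1)
})

test_that("planted NDRs contain no dyads and only background coverage", {
  sim <- fx_sim()
  cov <- fx_cov_g1()
  arch <- sim$architecture
  for (i in seq_len(nrow(arch))) {
    expect_false(any(arch$dyads[[i]] >= arch$ndr_start[i] &
                       arch$dyads[[i]] < arch$ndr_end[i]))
    core <- (arch$ndr_start[i] + 30L):(arch$ndr_end[i] - 30L)
    expect_lt(mean(cov$values[[arch$chrom[i]]][core + 1L]), 0.1)
  }
})

test_that("S-phase doubles mononucleosome sampling at early origins only", {
  sim <- fx_sim()
  g1 <- fx_g1(); s <- fx_s()
  lens <- chrom_lengths(sim$genome)
  count_in <- function(st, chr, lo, hi) {
    sum(st$plus[[chr]][lo:hi]) + sum(st$minus[[chr]][lo:hi])
  }
  ratios <- vapply(seq_len(nrow(sim$origins)), function(i) {
    o <- sim$origins[i, ]
    mid <- (o$acs_start + o$acs_end) %/% 2L
    lo <- max(1L, mid - 1500L); hi <- min(lens[[o$chrom]], mid + 1500L)
    count_in(s, o$chrom, lo, hi) / count_in(g1, o$chrom, lo, hi)
  }, 0)
  early <- sim$origins$timing == "early"
  expect_true(all(abs(ratios[early] - 2) < 0.15))
  expect_true(all(abs(ratios[!early] - 1) < 0.15))
})

test_that("zero occupancy with zero background gives an empty read set", {
  cfg <- sim_config(genome_length = 60000L, n_chroms = 1L, n_genes = 25L,
                    n_origins = 2L, min_origin_spacing = 2000L,
                    bg_occupancy = 0, background_rate = 0,
                    class_table = dplyr::mutate(default_class_table(),
                                                occupancy = 0),
                    seed = 3L)
  sim <- generate_genome_and_annotations(cfg)
  st <- sample_mononucleosome_reads(sim, "G1")
  expect_equal(orichrom:::total_reads(st), 0)
})

test_that("naked sampling is uniform at the requested depth and seed-stable", {
  sim <- fx_sim()
  nk <- fx_naked_g1()
  lens <- chrom_lengths(sim$genome)
  rate <- sum(vapply(nk$plus, sum, 0)) / sum(lens)
  expect_lt(abs(rate - 85 / 80) / (85 / 80), 0.05)
  nk2 <- sample_naked_reads(sim, "G1")
  expect_identical(nk$plus, nk2$plus)
  expect_error(sample_naked_reads(sim, "G1", depth = 0), "> 0")
})
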