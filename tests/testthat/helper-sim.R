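# Shared synthetic fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, build) {
  if (!exists(key, envir = .fx)) assign(key, build(), envir = .fx)
  get(key, envir = .fx)
}

# moderate two-chromosome simulation used by several recovery tests
fx_sim <- function() fx_get("sim", function() {
  generate_genome_and_annotations(sim_config(
    genome_length = 300000L, n_chroms = 2L, n_genes = 130L,
    n_origins = 24L, seed = 7L))
})

fx_g1 <- function() fx_get("g1", function() sample_mononucleosome_reads(fx_sim(), "G1"))
fx_s <- function() fx_get("s", function() sample_mononucleosome_reads(fx_sim(), "S"))
fx_naked_g1 <- function() fx_get("naked_g1", function() sample_naked_reads(fx_sim(), "G1"))
fx_naked_s <- function() fx_get("naked_s", function() sample_naked_reads(fx_sim(), "S"))

fx_cov_g1 <- function() fx_get("cov_g1", function()
  normalize_by_genome_mean(starts_to_raw_coverage(fx_g1())))
fx_cov_s <- function() fx_get("cov_s", function()
  normalize_by_genome_mean(starts_to_raw_coverage(fx_s())))

fx_ndr_widths <- function() fx_get("ndr_widths", function() {
  sim <- fx_sim()
  ndrs <- call_ndrs(fx_cov_g1())
  assoc <- associate_ndrs_with_origins(ndrs, sim$origins)
  origin_ndr_width(sim$origins, assoc$origin_ndrs)
})

# single-chromosome start track with idealized fragments planted at given
# dyads: `count` fragments per dyad, footprint 147, no jitter
planted_track <- function(dyads, len, count = 60L, footprint = 147L) {
  plus <- integer(len)
  minus <- integer(len)
  for (d in dyads) {
    left <- d - footprint %/% 2L
    end <- left + footprint
    plus[left + 1L] <- plus[left + 1L] + count
    minus[end] <- minus[end] + count
  }
  start_track(plus = list(chr1 = plus), minus = list(chr1 = minus))
}

one_origin <- function(chrom = "chr1", acs_start = 995L, acs_end = 1006L,
                       strand = "+", timing = "early", name = "ARS_T") {
  tibble::tibble(name = name, chrom = chrom, acs_start = acs_start,
                 acs_end = acs_end, acs_strand = strand, timing = timing)
}
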