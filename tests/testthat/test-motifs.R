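# Strict IUPAC motif scanning, density profiles and the dual-site rule.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# exhaustive sliding-window oracle; N in the subject never matches
oracle_scan <- function(seq, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  match_at <- function(sub, pat) {
    all(mapply(function(ch, pl) ch %in% IUPAC_SETS[[pl]],
               strsplit(sub, "")[[1]], pat))
  }
  k <- length(pat)
  hits <- list()
  for (i in seq_len(nchar(seq) - k + 1)) {
    sub <- substr(seq, i, i + k - 1)
    if (match_at(sub, pat)) hits[[length(hits) + 1]] <- c(i - 1L, 1L)
    if (match_at(revcomp(sub), pat)) hits[[length(hits) + 1]] <- c(i - 1L, 2L)
  }
  if (!length(hits)) return(tibble::tibble(start = integer(0), strand = character(0)))
  m <- do.call(rbind, hits)
  tibble::tibble(start = m[, 1], strand = c("+", "-")[m[, 2]]) |>
    dplyr::arrange(start, strand)
}

mk_genome <- function(...) {
  f <- tempfile(fileext = ".fa")
  seqs <- list(...)
  writeLines(unlist(lapply(seq_along(seqs),
                           function(i) c(paste0(">chr", i), seqs[[i]]))), f)
  read_genome_fasta(f)
}

test_that("RTAAAYA instances and their reverse complements are found", {
  g <- mk_genome("ATAAACAGGGGGGGGG")
  hits <- scan_motif(g)
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")

  g2 <- mk_genome("GGGTGTTTATGGGGGG")       # revcomp(ATAAACA) = TGTTTAT at 3
  hits2 <- scan_motif(g2)
  expect_equal(hits2$start, 3L)
  expect_equal(hits2$strand, "-")

  g3 <- mk_genome("ANAAACAGGGGGGGGG")       # N never matches
  expect_equal(nrow(scan_motif(g3)), 0L)

  expect_error(scan_motif(g, "RTAXAYA"), "invalid IUPAC")
})

test_that("scanner matches the exhaustive oracle on random sequences", {
  set.seed(55)
  for (rep in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 3000,
                        replace = TRUE, prob = c(0.3, 0.18, 0.18, 0.3, 0.04)),
                 collapse = "")
    g <- mk_genome(seq)
    got <- scan_motif(g)[, c("start", "strand")]
    want <- oracle_scan(seq, "RTAAAYA")
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  set.seed(56)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                      prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  a <- scan_motif(mk_genome(seq))
  b <- scan_motif(mk_genome(rc))
  n <- nchar(seq)
  mirrored <- sort(n - 7L - b$start)
  expect_equal(sort(a$start), mirrored)
  expect_equal(as.vector(table(a$strand)), rev(as.vector(table(b$strand))))
})

test_that("motif density is centered on the hit and conserves mass", {
  org <- one_origin(acs_start = 995L, acs_end = 1006L)
  hits <- tibble::tibble(chrom = "chr1", start = 950L, strand = "+")  # offset -50
  d <- motif_density_profile(hits, org, halfwidth = 600L, smoothing_bw = 10)
  expect_equal(d$offset[which.max(d$density)], -50L)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)

  # mass conservation holds with hits at the window edge
  hits2 <- tibble::tibble(chrom = "chr1", start = c(405L, 950L, 1595L),
                          strand = "+")
  d2 <- motif_density_profile(hits2, org, halfwidth = 600L, smoothing_bw = 25)
  expect_equal(sum(d2$density), 3, tolerance = 1e-9)

  d3 <- motif_density_profile(hits[0, ], org, halfwidth = 600L)
  expect_true(all(d3$density == 0))
  expect_error(motif_density_profile(hits, org[0, ]), "empty")
})

test_that("dual-site separation bounds are inclusive at 60 and 120", {
  org <- one_origin(acs_start = 995L, acs_end = 1006L)  # mid 1000
  mk_hits <- function(offsets) tibble::tibble(chrom = "chr1",
                                              start = 1000L + offsets,
                                              strand = "+")
  expect_true(dual_site_configuration(org, mk_hits(c(10L, 100L))))    # sep 90
  expect_false(dual_site_configuration(org, mk_hits(c(10L, 55L))))    # sep 45
  expect_false(dual_site_configuration(org, mk_hits(c(10L, 140L))))   # sep 130
  expect_false(dual_site_configuration(org, mk_hits(c(10L, 69L))))    # sep 59
  expect_true(dual_site_configuration(org, mk_hits(c(10L, 70L))))     # sep 60
  expect_true(dual_site_configuration(org, mk_hits(c(10L, 130L))))    # sep 120
  expect_false(dual_site_configuration(org, mk_hits(c(10L, 131L))))   # sep 121
  expect_false(dual_site_configuration(org, mk_hits(10L)))            # single
  # neither site proximal -> no configuration
  expect_false(dual_site_configuration(org, mk_hits(c(200L, 280L))))
})

test_that("planted dual-site fraction is recovered exactly", {
  sim <- fx_sim()
  hits <- scan_motif(sim$genome)
  fr <- fraction_with_configuration(sim$origins, hits)
  truth <- mean(sim$architecture$fkh_dual[sim$origins$timing == "early"])
  expect_equal(fr, truth)
  expect_error(fraction_with_configuration(
    dplyr::mutate(sim$origins, timing = "late"), hits), "no early")
})

test_that("hit count is invariant to chromosome order", {
  sim <- fx_sim()
  hits <- scan_motif(sim$genome)
  g_rev <- orichrom:::genome_seq(rev(unclass(sim$genome)[seq_along(sim$genome)]))
  hits2 <- scan_motif(g_rev)
  expect_equal(nrow(hits), nrow(hits2))
})
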