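# Synthetic genomes with planted origin chromatin architectures, and
# stranded mononucleosome / naked-DNA read sampling for G1 and
# hydroxyurea-arrested S-phase samples.

#' Default per-class architecture table
#'
#' Six origin classes whose mean NDR width decreases linearly from 193 bp
#' (class 1) to 129 bp (class 6), with graded flanking-nucleosome occupancy,
#' dyad fuzziness and NDR asymmetry relative to the ACS. Width extremes follow
#' the observed class-1/class-6 range; the occupancy and fuzziness ladders are
#' free design parameters chosen for clear class separation.
#'
#' @return tibble with `class_id`, `ndr_width`, `occupancy`, `fuzziness_sd`,
#'   `ndr_center_offset`.
#' @export
default_class_table <- function() {
  tibble::tibble(
    class_id = 1:6,
    ndr_width = c(193L, 180L, 167L, 154L, 141L, 129L),
    occupancy = c(0.95, 0.88, 0.80, 0.72, 0.62, 0.52),
    fuzziness_sd = c(2, 4, 6, 8, 10, 12),
    ndr_center_offset = c(50L, 30L, 10L, -10L, -30L, -50L)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the design of the study system: a compact budding-yeast-
#' like genome, single-end 40-nt mononucleosome boundary reads at high
#' (85-fold) coverage, a 147-bp nucleosome footprint, hydroxyurea-limited
#' replication extending 2250 bp on either side of early origins, and a
#' compliant dual Forkhead-site configuration planted at 25.6% of early
#' origins.
#'
#' @param genome_length total genome size in bp.
#' @param n_chroms number of chromosomes (genome split evenly).
#' @param n_genes number of genes; strands drawn independently and
#'   equiprobably.
#' @param n_origins number of replication origins, placed in intergenic
#'   regions.
#' @param fraction_early fraction of origins labeled `early`.
#' @param mean_coverage target genome-wide read coverage (fold).
#' @param read_length sequenced read length in bp.
#' @param nucleosome_footprint protected fragment size in bp.
#' @param nucleosome_spacing background dyad-to-dyad repeat length in bp.
#' @param bg_occupancy,bg_fuzziness_sd occupancy and dyad jitter (bp, sd) of
#'   background (non-origin) nucleosomes.
#' @param fragment_length_sd sd (bp) of fragment-length noise around the
#'   footprint.
#' @param background_rate fold-coverage of unpositioned (linker/naked-like)
#'   background reads; 0 disables them.
#' @param replicated_halfwidth bp replicated on either side of each early
#'   origin in the S sample (planted as exactly 2x copy number).
#' @param fraction_fkh_dual fraction of early origins planted with a
#'   compliant dual Forkhead-site configuration.
#' @param fkh_proximal_offset oriented offset (bp from the ACS midpoint) of
#'   the ACS-proximal planted site.
#' @param fkh_separation separation (bp) between the two planted site starts.
#' @param fraction_fkh_single fraction of early origins planted with a single
#'   (non-compliant) site.
#' @param min_origin_spacing minimum distance between origin ACS midpoints.
#' @param class_table per-class architecture parameters; see
#'   [default_class_table()].
#' @param class_assignment `"timing_biased"` (default) assigns classes with
#'   the observed timing association — 60% of early origins in classes 1-2
#'   (40% in class 1) and 65% of late origins in classes 5-6 (40% in class
#'   6), with classes 3-4 sparsely populated; `"balanced"` assigns classes
#'   independently of timing in equal numbers.
#' @param seed integer seed; all draws of the generator flow from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 500000L,
                       n_chroms = 2L,
                       n_genes = 200L,
                       n_origins = 40L,
                       fraction_early = 0.5,
                       mean_coverage = 85,
                       read_length = 40L,
                       nucleosome_footprint = 147L,
                       nucleosome_spacing = 165L,
                       bg_occupancy = 0.85,
                       bg_fuzziness_sd = 10,
                       fragment_length_sd = 2,
                       background_rate = 0,
                       replicated_halfwidth = 2250L,
                       fraction_fkh_dual = 0.256,
                       fkh_proximal_offset = 15L,
                       fkh_separation = 90L,
                       fraction_fkh_single = 0.2,
                       min_origin_spacing = 5000L,
                       class_table = default_class_table(),
                       class_assignment = c("timing_biased", "balanced"),
                       seed = 1L) {
  class_assignment <- match.arg(class_assignment)
  cfg <- list(genome_length = as.integer(genome_length), n_chroms = as.integer(n_chroms),
              n_genes = as.integer(n_genes), n_origins = as.integer(n_origins),
              fraction_early = fraction_early, mean_coverage = mean_coverage,
              read_length = as.integer(read_length),
              nucleosome_footprint = as.integer(nucleosome_footprint),
              nucleosome_spacing = as.integer(nucleosome_spacing),
              bg_occupancy = bg_occupancy, bg_fuzziness_sd = bg_fuzziness_sd,
              fragment_length_sd = fragment_length_sd, background_rate = background_rate,
              replicated_halfwidth = as.integer(replicated_halfwidth),
              fraction_fkh_dual = fraction_fkh_dual,
              fkh_proximal_offset = as.integer(fkh_proximal_offset),
              fkh_separation = as.integer(fkh_separation),
              fraction_fkh_single = fraction_fkh_single,
              min_origin_spacing = as.integer(min_origin_spacing),
              class_table = class_table, class_assignment = class_assignment,
              seed = as.integer(seed))
  with(cfg, {
    assert_that(genome_length > 0 && n_chroms > 0 && n_genes > 0 && n_origins >= 0,
                "genome_length, n_chroms, n_genes must be positive")
    assert_that(fraction_early >= 0 && fraction_early <= 1, "fraction_early must be in [0,1]")
    assert_that(mean_coverage > 0, "mean_coverage must be > 0")
    assert_that(read_length > 0 && nucleosome_footprint > 0 && nucleosome_spacing > 0,
                "read/footprint/spacing must be positive")
    assert_that(nucleosome_spacing >= nucleosome_footprint,
                "nucleosome_spacing must be >= footprint (adjacent dyads cannot overlap)")
    assert_that(bg_occupancy >= 0 && bg_occupancy <= 1 &&
                  all(class_table$occupancy >= 0 & class_table$occupancy <= 1),
                "occupancies must be in [0,1]")
    assert_that(all(class_table$ndr_width > 0), "ndr_width must be > 0")
    assert_that(fraction_fkh_dual >= 0 && fraction_fkh_dual <= 1 &&
                  fraction_fkh_single >= 0 && fraction_fkh_single <= 1,
                "Forkhead planting fractions must be in [0,1]")
  })
  structure(cfg, class = "sim_config")
}

FKH_INSTANCES <- c("ATAAACA", "GTAAATA", "ATAAATA", "GTAAACA")
ACS_TRICH <- "TTTTATGTTTT"  # T-rich ACS stand-in written on acs_strand

revcomp_chr <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# place genes sequentially along a chromosome; lengths and gaps are uniform
# draws; returns tibble of 0-based half-open intervals
place_genes <- function(chrom, len, n, rng_min_gap = 250, rng_max_gap = 900) {
  starts <- ends <- integer(0)
  pos <- round(stats::runif(1, 200, 600))
  while (length(starts) < n) {
    glen <- round(stats::runif(1, 900, 2000))
    if (pos + glen + 200 > len) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + glen)
    pos <- pos + glen + round(stats::runif(1, rng_min_gap, rng_max_gap))
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

plant_string <- function(seq, at0, what) {
  # at0: 0-based leftmost position
  substr(seq, at0 + 1L, at0 + nchar(what)) <- what
  seq
}

# remove RTAAAYA matches (both strands) from `seq` within [lo0, hi0),
# except positions listed in keep0 (0-based starts of planted 7-mers, either
# strand). Mutates one base per spurious hit, avoiding protected intervals.
scrub_fkh <- function(seq, lo0, hi0, keep0) {
  protected <- unlist(lapply(keep0, function(s) s:(s + 6L)))
  for (pass in 1:12) {
    win <- substr(seq, lo0 + 1L, hi0)
    hits <- scan_iupac_one(win, "RTAAAYA")
    hit0 <- lo0 + hits$start
    spurious <- setdiff(hit0, keep0)
    if (length(spurious) == 0) return(seq)
    for (s in spurious) {
      cand <- setdiff(s:(s + 6L), protected)
      if (length(cand) == 0) next
      p <- cand[ceiling(length(cand) / 2)]
      cur <- substr(seq, p + 1L, p + 1L)
      repl <- if (cur == "C") "G" else "C"   # C/G kill any RTAAAYA overlap
      substr(seq, p + 1L, p + 1L) <- repl
    }
  }
  seq
}

#' Generate a synthetic genome with planted origin architectures
#'
#' Builds chromosome sequences, gene annotations (independent equiprobable
#' strands), replication origins placed in intergenic regions with a T-rich
#' ACS written on the ACS strand, a per-origin planted architecture (class,
#' NDR interval, flanking dyads at positions -3..+3, occupancy, fuzziness),
#' planted Forkhead sites at the chosen early origins, and the background
#' nucleosome tiling. Within +/-650 bp of every ACS, spurious Forkhead-
#' consensus matches are scrubbed so that planted sites are the complete
#' ground truth there. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return an `origin_sim` list with elements `genome`, `genes`, `origins`,
#'   `architecture` (planted truth), `bg_dyads`, `config`.
#' @export
generate_genome_and_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  foot <- config$nucleosome_footprint
  half <- foot %/% 2L

  clens <- rep(config$genome_length %/% config$n_chroms, config$n_chroms)
  clens[1] <- clens[1] + config$genome_length %% config$n_chroms
  chroms <- paste0("chr", utils::as.roman(seq_len(config$n_chroms)))
  names(clens) <- chroms

  # gene layout
  quota <- round(config$n_genes * clens / sum(clens))
  quota[1] <- quota[1] + config$n_genes - sum(quota)
  genes <- purrr::map_dfr(seq_along(chroms), function(i) {
    place_genes(chroms[i], clens[i], quota[i])
  })
  assert_that(nrow(genes) == config$n_genes,
              "genome too small to place the requested number of genes")
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]

  # candidate IGRs wide enough to host an origin
  igrs <- build_igrs(genes)
  cand <- igrs[igrs$end - igrs$start >= 340, ]
  cand <- cand[sample(nrow(cand)), ]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    mid <- (cand$start[i] + cand$end[i]) %/% 2L
    same <- sel[cand$chrom[sel] == cand$chrom[i]]
    if (length(same) == 0 ||
        all(abs((cand$start[same] + cand$end[same]) %/% 2L - mid) >= config$min_origin_spacing)) {
      sel <- c(sel, i)
    }
    if (length(sel) == config$n_origins) break
  }
  assert_that(length(sel) == config$n_origins,
              "not enough intergenic regions for the requested origins; enlarge the genome or reduce min_origin_spacing")
  ocand <- cand[sel, ]
  ord <- order(ocand$chrom, ocand$start)
  ocand <- ocand[ord, ]

  n <- config$n_origins
  acs_mid <- (ocand$start + ocand$end) %/% 2L
  acs_strand <- sample(c("+", "-"), n, replace = TRUE)
  n_early <- round(config$fraction_early * n)
  timing <- sample(rep(c("early", "late"), c(n_early, n - n_early)))
  origins <- tibble::tibble(
    name = sprintf("ARS%03d", seq_len(n)),
    chrom = ocand$chrom,
    acs_start = acs_mid - nchar(ACS_TRICH) %/% 2L,
    acs_end = acs_mid - nchar(ACS_TRICH) %/% 2L + nchar(ACS_TRICH),
    acs_strand = acs_strand,
    timing = timing
  )

  # planted architecture; class assignment either balanced or reproducing the
  # observed timing association (60% of early in classes 1-2, 65% of late in
  # classes 5-6)
  ct <- config$class_table
  k <- nrow(ct)
  largest_remainder <- function(probs, total) {
    raw <- probs * total
    cnt <- floor(raw)
    rem <- total - sum(cnt)
    if (rem > 0) {
      add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[add] <- cnt[add] + 1L
    }
    as.integer(cnt)
  }
  shuffle <- function(x) x[sample.int(length(x))]   # safe for length-1 input
  if (config$class_assignment == "balanced" || k != 6L) {
    class_id <- shuffle(rep_len(ct$class_id, n))
  } else {
    probs <- list(early = c(0.40, 0.20, 0.06, 0.06, 0.14, 0.14),
                  late = c(0.08, 0.07, 0.10, 0.10, 0.25, 0.40),
                  unknown = rep(1 / 6, 6))
    class_id <- integer(n)
    for (tm in unique(timing)) {
      idx <- which(timing == tm)
      cnt <- largest_remainder(probs[[tm]], length(idx))
      class_id[idx] <- shuffle(rep.int(ct$class_id, cnt))
    }
  }
  arch <- ct[match(class_id, ct$class_id), ]
  sgn <- ifelse(acs_strand == "+", 1L, -1L)
  ndr_center <- acs_mid + sgn * arch$ndr_center_offset
  ndr_start <- as.integer(ndr_center - arch$ndr_width %/% 2L)
  ndr_end <- ndr_start + arch$ndr_width
  dyads <- lapply(seq_len(n), function(i) {
    right <- ndr_end[i] + (half + 1L) + (0:2) * config$nucleosome_spacing
    left <- ndr_start[i] - (half + 1L) - (0:2) * config$nucleosome_spacing
    sort(c(left, right))
  })

  # Forkhead planting (oriented offsets are relative to the ACS midpoint and
  # read along the T-rich strand)
  early_idx <- which(timing == "early")
  n_dual <- round(config$fraction_fkh_dual * length(early_idx))
  dual_idx <- sort(sample(early_idx, n_dual))
  rest <- setdiff(early_idx, dual_idx)
  n_single <- round(config$fraction_fkh_single * length(early_idx))
  single_idx <- sort(sample(rest, min(n_single, length(rest))))
  fkh_offsets <- vector("list", n)
  for (i in dual_idx) {
    fkh_offsets[[i]] <- c(config$fkh_proximal_offset,
                          config$fkh_proximal_offset + config$fkh_separation)
  }
  for (i in single_idx) fkh_offsets[[i]] <- config$fkh_proximal_offset

  architecture <- tibble::tibble(
    name = origins$name, chrom = origins$chrom,
    class_id = class_id, ndr_width = arch$ndr_width,
    ndr_center_offset = arch$ndr_center_offset,
    ndr_start = ndr_start, ndr_end = ndr_end,
    occupancy = arch$occupancy, fuzziness_sd = arch$fuzziness_sd,
    dyads = dyads, fkh_offsets = fkh_offsets,
    fkh_dual = seq_len(n) %in% dual_idx
  )

  # sequences: random background, then ACS and Forkhead sites, then scrub
  seqs <- vapply(clens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  planted_by_chr <- stats::setNames(vector("list", length(chroms)), chroms)
  for (i in seq_len(n)) {
    chr <- origins$chrom[i]
    acs_seq <- if (acs_strand[i] == "+") ACS_TRICH else revcomp_chr(ACS_TRICH)
    seqs[[chr]] <- plant_string(seqs[[chr]], origins$acs_start[i], acs_seq)
    offs <- fkh_offsets[[i]]
    for (o in offs) {
      inst <- sample(FKH_INSTANCES, 1)
      if (acs_strand[i] == "+") {
        at0 <- acs_mid[i] + o
        seqs[[chr]] <- plant_string(seqs[[chr]], at0, inst)
      } else {
        at0 <- acs_mid[i] - o - 7L
        seqs[[chr]] <- plant_string(seqs[[chr]], at0, revcomp_chr(inst))
      }
      planted_by_chr[[chr]] <- c(planted_by_chr[[chr]], at0)
    }
  }
  for (i in seq_len(n)) {
    chr <- origins$chrom[i]
    lo <- max(0L, acs_mid[i] - 650L)
    hi <- min(clens[[chr]], acs_mid[i] + 650L)
    seqs[[chr]] <- scrub_fkh(seqs[[chr]], lo, hi, planted_by_chr[[chr]] %||% integer(0))
  }

  # background tiling outside planted origin regions
  excl_pad <- config$nucleosome_spacing
  bg_dyads <- lapply(seq_along(chroms), function(ci) {
    chr <- chroms[ci]
    d <- seq(half + 10L, clens[ci] - half - 10L, by = config$nucleosome_spacing)
    oi <- which(origins$chrom == chr)
    for (i in oi) {
      lo <- min(architecture$dyads[[i]]) - excl_pad
      hi <- max(architecture$dyads[[i]]) + excl_pad
      d <- d[d < lo | d > hi]
    }
    d
  })
  names(bg_dyads) <- chroms

  structure(list(genome = genome_seq(seqs), genes = genes, origins = origins,
                 architecture = architecture, bg_dyads = bg_dyads,
                 config = config),
            class = "origin_sim")
}

#' @export
print.origin_sim <- function(x, ...) {
  cat("<origin_sim> ", sum(chrom_lengths(x$genome)), " bp, ",
      nrow(x$genes), " genes, ", nrow(x$origins), " origins\n", sep = "")
  invisible(x)
}

# per-chromosome S-phase copy-number factor (2 within replicated windows of
# early origins, 1 elsewhere)
replication_factor <- function(sim, phase) {
  lens <- chrom_lengths(sim$genome)
  fac <- lapply(lens, function(L) rep(1, L))
  if (phase == "S") {
    hw <- sim$config$replicated_halfwidth
    early <- sim$origins[sim$origins$timing == "early", ]
    for (i in seq_len(nrow(early))) {
      chr <- early$chrom[i]
      mid <- (early$acs_start[i] + early$acs_end[i]) %/% 2L
      lo <- max(1L, mid - hw + 1L)
      hi <- min(lens[[chr]], mid + hw)
      fac[[chr]][lo:hi] <- 2
    }
  }
  fac
}

#' Sample stranded mononucleosome boundary reads
#'
#' For every nucleosome instance a dyad is drawn as planted dyad plus
#' Gaussian jitter and included with probability equal to its occupancy
#' (folded into a Poisson fragment count); the protected fragment is the
#' footprint around the dyad with small length noise, and one plus-strand 5'
#' end at the fragment's left edge plus one minus-strand 5' end at its right
#' edge are emitted. In S phase the sampling rate is doubled within the
#' replicated window of early origins only, reflecting checkpoint inhibition
#' of late-origin firing under hydroxyurea.
#'
#' @param sim an `origin_sim`.
#' @param phase `"G1"` or `"S"`.
#' @param seed optional integer; defaults to a seed derived from the
#'   simulation seed and the phase.
#' @return a `start_track`.
#' @export
sample_mononucleosome_reads <- function(sim, phase = c("G1", "S"), seed = NULL) {
  phase <- match.arg(phase)
  cfg <- sim$config
  assert_that(cfg$mean_coverage > 0, "coverage must be > 0")
  set.seed(seed %||% derive_seed(cfg$seed, paste0("mnase-", phase)))
  lens <- chrom_lengths(sim$genome)
  foot <- cfg$nucleosome_footprint

  # dyad catalogue: background tiling + planted origin flanks
  dyad_tb <- purrr::map_dfr(names(lens), function(chr) {
    bg <- tibble::tibble(chrom = chr, pos = sim$bg_dyads[[chr]],
                         occupancy = cfg$bg_occupancy, fuzz = cfg$bg_fuzziness_sd)
    oi <- which(sim$architecture$chrom == chr)
    pl <- purrr::map_dfr(oi, function(i) {
      tibble::tibble(chrom = chr, pos = sim$architecture$dyads[[i]],
                     occupancy = sim$architecture$occupancy[i],
                     fuzz = sim$architecture$fuzziness_sd[i])
    })
    dplyr::bind_rows(bg, pl)
  })

  fac <- replication_factor(sim, phase)
  dyad_tb$factor <- purrr::map2_dbl(dyad_tb$chrom, dyad_tb$pos, function(chr, p) {
    fac[[chr]][min(max(p, 1L), lens[[chr]])]
  })

  # fragments per nucleosome: Poisson with rate proportional to occupancy and
  # copy number, scaled so the G1 genome-wide read coverage hits the target
  target_frags <- cfg$mean_coverage * sum(lens) / (2 * cfg$read_length)
  occ_total <- sum(dyad_tb$occupancy)
  lambda0 <- if (occ_total > 0) target_frags / occ_total else 0
  counts <- stats::rpois(nrow(dyad_tb), lambda0 * dyad_tb$occupancy * dyad_tb$factor)

  idx <- rep.int(seq_len(nrow(dyad_tb)), counts)
  dy <- round(dyad_tb$pos[idx] + stats::rnorm(length(idx), 0, dyad_tb$fuzz[idx]))
  L <- foot + round(stats::rnorm(length(idx), 0, cfg$fragment_length_sd))
  L[L < 20L] <- 20L
  left <- dy - L %/% 2L
  end <- left + L
  chrv <- dyad_tb$chrom[idx]

  plus <- minus <- stats::setNames(vector("list", length(lens)), names(lens))
  for (chr in names(lens)) {
    n <- lens[[chr]]
    sel <- chrv == chr & left >= 0L & end <= n
    plus[[chr]] <- tabulate(left[sel] + 1L, nbins = n)
    minus[[chr]] <- tabulate(end[sel], nbins = n)
    if (cfg$background_rate > 0) {
      r <- cfg$background_rate / (2 * cfg$read_length) * fac[[chr]]
      plus[[chr]] <- plus[[chr]] + stats::rpois(n, r)
      minus[[chr]] <- minus[[chr]] + stats::rpois(n, r)
    }
  }
  start_track(plus, minus)
}

#' Sample naked-DNA control reads
#'
#' Uniform read starts at the stated depth; in S phase the rate doubles
#' within the replicated windows of early origins, matching the
#' mononucleosome sampler's copy-number model.
#'
#' @param sim an `origin_sim`.
#' @param phase `"G1"` or `"S"`.
#' @param depth target fold coverage (default: the simulation's
#'   `mean_coverage`).
#' @param seed optional integer seed.
#' @return a `start_track`.
#' @export
sample_naked_reads <- function(sim, phase = c("G1", "S"), depth = NULL, seed = NULL) {
  phase <- match.arg(phase)
  cfg <- sim$config
  depth <- depth %||% cfg$mean_coverage
  assert_that(is_scalar_number(depth) && depth > 0, "`depth` must be > 0")
  set.seed(seed %||% derive_seed(cfg$seed, paste0("naked-", phase)))
  lens <- chrom_lengths(sim$genome)
  fac <- replication_factor(sim, phase)
  rate <- depth / (2 * cfg$read_length)
  plus <- minus <- stats::setNames(vector("list", length(lens)), names(lens))
  for (chr in names(lens)) {
    plus[[chr]] <- stats::rpois(lens[[chr]], rate * fac[[chr]])
    minus[[chr]] <- stats::rpois(lens[[chr]], rate * fac[[chr]])
  }
  start_track(plus, minus)
}
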