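# Positioning-profile construction: per-strand boundary peaks, average
# boundary spacing, discrete midpoint (dyad) calls, and the combined smoothed
# positioning profile used by all downstream origin analyses.

# local maxima of v strictly above `floor`; plateaus yield their leftmost
# index; returns 1-based indices
local_maxima <- function(v, floor = -Inf) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > floor]
  cand
}

#' Per-strand boundary peaks of the smoothed 5'-end profiles
#'
#' Each strand's read 5'-end count vector is wavelet-smoothed and local maxima
#' above a noise floor (mean + one sd of the smoothed strand profile) are
#' reported. Plus-strand peaks sit near fragment left edges; minus-strand
#' peaks are fragment end coordinates.
#'
#' @param starts a `start_track`.
#' @param smoothing_level wavelet level for [wavelet_smooth()].
#' @param floor_sd_mult multiplier on the sd term of the noise floor.
#' @return tibble with `chrom`, `strand`, `pos` (plus: 0-based 5'-end
#'   position; minus: fragment end coordinate), `height`.
#' @export
boundary_peaks <- function(starts, smoothing_level = 3L, floor_sd_mult = 1) {
  if (total_reads(starts) == 0) {
    rlang::warn("empty start track: no boundary peaks")
    return(tibble::tibble(chrom = character(), strand = character(),
                          pos = integer(), height = numeric()))
  }
  one <- function(chr, v, strand) {
    sm <- wavelet_smooth(v, level = smoothing_level)
    flo <- mean(sm) + floor_sd_mult * stats::sd(sm)
    idx <- local_maxima(sm, floor = flo)
    pos <- if (strand == "+") idx - 1L else idx
    tibble::tibble(chrom = chr, strand = strand, pos = pos, height = sm[idx])
  }
  purrr::map_dfr(names(starts$plus), function(chr) {
    dplyr::bind_rows(one(chr, starts$plus[[chr]], "+"),
                     one(chr, starts$minus[[chr]], "-"))
  })
}

# pair each plus peak with the nearest downstream minus peak at separation
# within [lo, hi]; greedy left-to-right, each minus peak used once
pair_peaks <- function(plus_pos, minus_pos, lo = 100L, hi = 200L) {
  plus_pos <- sort(plus_pos)
  minus_pos <- sort(minus_pos)
  pi_ <- mi <- integer(0)
  j <- 1L
  for (i in seq_along(plus_pos)) {
    while (j <= length(minus_pos) && minus_pos[j] < plus_pos[i] + lo) j <- j + 1L
    if (j > length(minus_pos)) break
    if (minus_pos[j] <= plus_pos[i] + hi) {
      pi_ <- c(pi_, i); mi <- c(mi, j)
      j <- j + 1L
    }
  }
  tibble::tibble(plus = plus_pos[pi_], minus = minus_pos[mi])
}

#' Average spacing between paired boundary peaks
#'
#' Pairs each plus-strand peak with the nearest downstream minus-strand peak
#' within the pairing window and returns the mean separation, an estimate of
#' the protected fragment length.
#'
#' @param peaks tibble from [boundary_peaks()].
#' @param pair_lo,pair_hi pairing window in bp around the canonical footprint.
#' @return average spacing in bp.
#' @export
estimate_average_spacing <- function(peaks, pair_lo = 100L, pair_hi = 200L) {
  seps <- purrr::map_dfr(unique(peaks$chrom), function(chr) {
    pair_peaks(peaks$pos[peaks$chrom == chr & peaks$strand == "+"],
               peaks$pos[peaks$chrom == chr & peaks$strand == "-"],
               pair_lo, pair_hi)
  })
  assert_that(nrow(seps) > 0,
              "no boundary-peak pairs in the pairing window; coverage may be too shallow")
  mean(seps$minus - seps$plus)
}

#' Call nucleosome midpoints from paired boundary peaks
#'
#' Each paired (plus, minus) boundary peak yields a call at the pair midpoint
#' (even spans round down); the score is the smaller of the two peak heights
#' and `width_support` the pair separation. Calls closer than `merge_dist`
#' are sub-footprint duplicates and are merged to their score-weighted mean
#' position.
#'
#' @param starts a `start_track`.
#' @param spacing average boundary spacing from [estimate_average_spacing()].
#' @param smoothing_level wavelet level for the per-strand profiles.
#' @param pair_lo,pair_hi pairing window in bp.
#' @param merge_dist merge radius for duplicate calls, bp.
#' @return tibble with `chrom`, `dyad`, `score`, `width_support`.
#' @export
call_nucleosomes <- function(starts, spacing, smoothing_level = 3L,
                             pair_lo = 100L, pair_hi = 200L, merge_dist = 60L) {
  assert_that(is_scalar_number(spacing) && spacing > 0, "`spacing` must be > 0")
  peaks <- boundary_peaks(starts, smoothing_level = smoothing_level)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(chrom = character(), dyad = integer(),
                          score = numeric(), width_support = numeric()))
  }
  purrr::map_dfr(unique(peaks$chrom), function(chr) {
    pk <- peaks[peaks$chrom == chr, ]
    pr <- pair_peaks(pk$pos[pk$strand == "+"], pk$pos[pk$strand == "-"],
                     pair_lo, pair_hi)
    if (nrow(pr) == 0) return(NULL)
    hp <- pk$height[pk$strand == "+"][match(pr$plus, pk$pos[pk$strand == "+"])]
    hm <- pk$height[pk$strand == "-"][match(pr$minus, pk$pos[pk$strand == "-"])]
    calls <- tibble::tibble(chrom = chr,
                            dyad = (pr$plus + pr$minus) %/% 2L,
                            score = pmin(hp, hm),
                            width_support = pr$minus - pr$plus)
    calls <- calls[order(calls$dyad), ]
    grp <- cumsum(c(1L, as.integer(diff(calls$dyad) >= merge_dist)))
    calls |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$chrom, .data$.grp) |>
      dplyr::summarise(
        dyad = as.integer(floor(sum(.data$dyad * .data$score) / sum(.data$score))),
        score = max(.data$score),
        width_support = mean(.data$width_support),
        .groups = "drop") |>
      dplyr::select(-".grp")
  })
}

#' Combined nucleosome positioning profile
#'
#' Shifts the plus-strand 5'-end counts downstream by half the boundary
#' spacing and the minus-strand end-coordinate counts upstream by the other
#' half so both strands pile up at the dyad, sums them, wavelet-smooths the
#' combination once, and normalizes to genome mean 1. This is the positioning
#' profile consumed by the origin-architecture analyses.
#'
#' @param starts a `start_track`.
#' @param spacing boundary spacing in bp.
#' @param smoothing_level wavelet level.
#' @return a normalized `coverage_track`.
#' @export
combined_profile <- function(starts, spacing, smoothing_level = 3L) {
  assert_that(is_scalar_number(spacing) && spacing > 0, "`spacing` must be > 0")
  s1 <- as.integer(floor(spacing / 2))
  s2 <- as.integer(ceiling(spacing / 2))
  values <- lapply(names(starts$plus), function(chr) {
    p <- starts$plus[[chr]]
    m <- starts$minus[[chr]]
    n <- length(p)
    comb <- numeric(n)
    ip <- which(p > 0)
    tp <- ip + s1
    ok <- tp >= 1L & tp <= n
    comb[tp[ok]] <- comb[tp[ok]] + p[ip[ok]]
    im <- which(m > 0)
    tm <- im - s2 + 1L
    ok <- tm >= 1L & tm <= n
    comb[tm[ok]] <- comb[tm[ok]] + m[im[ok]]
    wavelet_smooth(comb, level = smoothing_level)
  })
  names(values) <- names(starts$plus)
  normalize_by_genome_mean(coverage_track(values))
}

#' Export nucleosome calls as BED6
#' @param calls tibble from [call_nucleosomes()].
#' @param path output file.
#' @param halfwidth half-width of the written interval around each dyad.
#' @export
write_nucleosome_bed <- function(calls, path, halfwidth = 73L) {
  writeLines(sprintf("%s\t%d\t%d\tnuc%d\t%.3f\t.",
                     calls$chrom, pmax(calls$dyad - halfwidth, 0L),
                     calls$dyad + halfwidth + 1L,
                     seq_len(nrow(calls)), calls$score), path)
  invisible(path)
}
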