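# Replication dynamics: S-vs-G1 differential signal, naked-DNA copy-number
# correction, replicated-extent measurement around origins, and per-group
# nucleosome-feature shift reports.

#' S minus G1 differential track
#'
#' Elementwise subtraction of two tracks over the same genome. When both
#' inputs are mean-1 normalized profiles the differential has genome mean
#' approximately 0; it is positive over regions with extra S-phase signal
#' (replicated DNA).
#'
#' @param s_track,g1_track `coverage_track`s on the same chromosomes.
#' @return a `coverage_track` of differences (not mean-normalized).
#' @export
differential_track <- function(s_track, g1_track) {
  assert_that(identical(names(s_track$values), names(g1_track$values)),
              "tracks cover different chromosomes")
  values <- lapply(names(s_track$values), function(chr) {
    a <- s_track$values[[chr]]
    b <- g1_track$values[[chr]]
    assert_that(length(a) == length(b), paste0("length mismatch on ", chr))
    a - b
  })
  names(values) <- names(s_track$values)
  coverage_track(values)
}

#' Copy-number correction against a naked-DNA control
#'
#' Both tracks are rescaled to genome mean 1 (positions with zero naked
#' signal are masked as missing and logged); the nucleosomal track is divided
#' by the naked track base by base; and the ratio is smoothed with a sliding
#' 1000-bp mean at 1-bp step. Masked positions propagate as missing through
#' the smoothing, whose edge windows shrink symmetrically. Correcting a track
#' against itself therefore yields a flat track of 1.
#'
#' @param nuc_track raw nucleosomal `coverage_track`.
#' @param naked_track raw naked-DNA `coverage_track` on the same genome.
#' @param window smoothing window in bp.
#' @return a `coverage_track`; masked bases are `NA`.
#' @export
copy_number_correct <- function(nuc_track, naked_track, window = 1000L) {
  assert_that(identical(names(nuc_track$values), names(naked_track$values)),
              "tracks cover different chromosomes")
  mu <- track_mean(naked_track)
  assert_that(is.finite(mu) && mu > 0, "naked-DNA track is all zero")
  mu_nuc <- track_mean(nuc_track)
  assert_that(is.finite(mu_nuc) && mu_nuc > 0, "nucleosomal track is all zero")
  values <- lapply(names(nuc_track$values), function(chr) {
    naked <- naked_track$values[[chr]] / mu
    nuc <- nuc_track$values[[chr]] / mu_nuc
    assert_that(length(nuc) == length(naked), paste0("length mismatch on ", chr))
    ratio <- nuc / naked
    ratio[naked == 0] <- NA_real_
    sliding_mean(ratio, window)
  })
  names(values) <- names(nuc_track$values)
  masked <- sum(vapply(naked_track$values, function(v) sum(v == 0), 0L))
  if (masked > 0) {
    rlang::inform(paste0(masked, " base(s) with zero naked-DNA signal masked as missing"))
  }
  coverage_track(values)
}

#' Replicated extent around one origin
#'
#' Window-averages the S-minus-G1 differential and measures the maximal
#' contiguous region containing the ACS whose averaged differential exceeds
#' the threshold. The threshold defaults to one quarter of the origin's peak
#' window-averaged differential (searched within `search_halfwidth` of the
#' ACS midpoint); the extent is 0 when that peak does not exceed `min_peak`
#' or when the ACS itself is not elevated, so an inactive origin near an
#' active one does not inherit its neighbour's signal.
#'
#' @param diff a differential `coverage_track`.
#' @param origin one-row origin tibble.
#' @param threshold absolute threshold on the averaged differential;
#'   `NULL` (default) uses `0.25 * peak`.
#' @param window averaging window in bp.
#' @param search_halfwidth peak search half-width around the ACS, bp.
#' @param min_peak minimum peak height (normalized-signal units) for a region
#'   to count as elevated.
#' @return total span in bp (0 when no elevated region covers the origin).
#' @export
replicated_extent <- function(diff, origin, threshold = NULL, window = 1000L,
                              search_halfwidth = 6000L, min_peak = 0.2) {
  v <- diff$values[[origin$chrom]]
  assert_that(!is.null(v), paste0("track lacks chromosome ", origin$chrom))
  w <- sliding_mean(v, window)
  mid <- (origin$acs_start + origin$acs_end) %/% 2L
  lo <- max(1L, mid + 1L - search_halfwidth)
  hi <- min(length(w), mid + 1L + search_halfwidth)
  seg <- w[lo:hi]
  if (all(is.na(seg))) return(0L)
  peak <- max(seg, na.rm = TRUE)
  if (!is.finite(peak) || peak < min_peak) return(0L)
  thr <- threshold %||% (0.25 * peak)
  mid_idx <- min(max(mid + 1L, 1L), length(w))
  above <- !is.na(w) & w > thr
  if (!above[mid_idx]) return(0L)
  left <- mid_idx
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- mid_idx
  while (right < length(w) && above[right + 1L]) right <- right + 1L
  as.integer(right - left + 1L)
}

# features of one aggregate profile: ACS-proximal minimum, flanking -1/+1
# peaks, and NDR width under the run-length rule
profile_features <- function(prof, threshold = 0.4, center_search = 200L,
                             peak_search = 300L) {
  prof <- unname(prof)
  n <- length(prof)
  if (n >= 8) prof <- wavelet_smooth(prof, level = 2)
  c0 <- (n + 1L) %/% 2L                       # offset 0
  win <- max(1L, c0 - center_search):min(n, c0 + center_search)
  min_idx <- win[which.min(prof[win])]
  # flanking nucleosome peaks must rise above the depletion threshold,
  # so sub-threshold noise bumps inside the NDR are never picked
  peaks <- local_maxima(prof, floor = threshold)
  left_pk <- peaks[peaks < min_idx & peaks >= min_idx - peak_search]
  right_pk <- peaks[peaks > min_idx & peaks <= min_idx + peak_search]
  m1 <- if (length(left_pk)) max(left_pk) else NA_integer_
  p1 <- if (length(right_pk)) min(right_pk) else NA_integer_
  runs <- logical_runs(prof < threshold)
  at_min <- runs[runs$start < min_idx & runs$end >= min_idx, , drop = FALSE]
  ndr_w <- if (nrow(at_min)) unname(at_min$end[1] - at_min$start[1]) else 0L
  list(min_offset = min_idx - c0,
       ndr_width = ndr_w,
       m1_offset = if (is.na(m1)) NA_real_ else m1 - c0,
       p1_offset = if (is.na(p1)) NA_real_ else p1 - c0,
       m1_height = if (is.na(m1)) NA_real_ else prof[m1],
       p1_height = if (is.na(p1)) NA_real_ else prof[p1])
}

#' Per-timing-group nucleosome-feature shifts between G1 and S
#'
#' Aggregates matched G1 and S origin profile matrices within each timing
#' group and reports S-minus-G1 deltas of the aggregate NDR width, of the
#' -1/+1 nucleosome peak offsets, and of their heights. The -1/+1 peaks are
#' the local maxima nearest the ACS-proximal minimum on either side.
#'
#' @param g1_matrix,s_matrix origin profile matrices over the same origins.
#' @param origins origin tibble with timing labels.
#' @param threshold NDR signal threshold for the aggregate profiles.
#' @return tibble with one row per timing group and delta columns.
#' @export
origin_shift_report <- function(g1_matrix, s_matrix, origins, threshold = 0.4) {
  common <- intersect(rownames(g1_matrix), rownames(s_matrix))
  assert_that(length(common) > 0 &&
                setequal(rownames(g1_matrix), rownames(s_matrix)),
              "G1 and S matrices cover different origin sets")
  purrr::map_dfr(c("early", "late"), function(tm) {
    nm <- intersect(common, origins$name[origins$timing == tm])
    if (length(nm) == 0) return(NULL)
    f_g1 <- profile_features(aggregate_profile(g1_matrix, nm), threshold)
    f_s <- profile_features(aggregate_profile(s_matrix, nm), threshold)
    tibble::tibble(
      timing = tm, n = length(nm),
      g1_ndr_width = f_g1$ndr_width, s_ndr_width = f_s$ndr_width,
      delta_ndr_width = f_s$ndr_width - f_g1$ndr_width,
      delta_m1_offset = f_s$m1_offset - f_g1$m1_offset,
      delta_p1_offset = f_s$p1_offset - f_g1$p1_offset,
      delta_m1_height = f_s$m1_height - f_g1$m1_height,
      delta_p1_height = f_s$p1_height - f_g1$p1_height)
  })
}
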