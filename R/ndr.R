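# Nucleosome-depleted regions: maximal runs of at least `min_len` bases with
# normalized signal strictly below `threshold`, their association with
# replication origins, and per-origin NDR widths.

#' Call nucleosome-depleted regions
#'
#' An NDR is a maximal run of consecutive bases whose normalized signal is
#' strictly lower than `threshold`, kept if the run spans at least `min_len`
#' bases. No gaps are tolerated inside a run: a single base at or above the
#' threshold splits it.
#'
#' @param track a normalized `coverage_track` (genome mean 1).
#' @param min_len minimum run length in bp (default 80).
#' @param threshold strict upper signal bound (default 0.4).
#' @return tibble with `chrom`, `start`, `end` (0-based half-open), `width`,
#'   `mean_signal`, `origin_associated` (`NA` until associated),
#'   `origin_name`.
#' @export
call_ndrs <- function(track, min_len = 80L, threshold = 0.4) {
  assert_that(is_scalar_number(min_len) && min_len >= 1, "`min_len` must be >= 1")
  assert_that(is_scalar_number(threshold) && threshold > 0, "`threshold` must be > 0")
  purrr::map_dfr(names(track$values), function(chr) {
    v <- track$values[[chr]]
    runs <- logical_runs(v < threshold)
    runs <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    tibble::tibble(
      chrom = chr, start = as.integer(runs$start), end = as.integer(runs$end),
      width = as.integer(runs$end - runs$start),
      mean_signal = purrr::map2_dbl(runs$start, runs$end,
                                    function(s, e) mean(v[(s + 1L):e])),
      origin_associated = NA, origin_name = NA_character_)
  })
}

# gap between an interval [s,e) and a point or interval; 0 when overlapping
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2 + 1L, s2 - e1 + 1L))
}

#' Associate NDRs with replication origins
#'
#' An NDR is origin-associated when it overlaps the ACS interval or lies
#' within `max_dist` of it. Each origin claims at most one NDR: the one
#' nearest its ACS midpoint, ties broken by larger ACS overlap and then lower
#' start coordinate.
#'
#' @param ndrs tibble from [call_ndrs()].
#' @param origins origin tibble.
#' @param max_dist association distance in bp.
#' @return list with `origin_ndrs` (claimed NDRs, `origin_name` filled) and
#'   `nonorigin_ndrs`.
#' @export
associate_ndrs_with_origins <- function(ndrs, origins, max_dist = 150L) {
  claimed <- rep(NA_character_, nrow(ndrs))
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    mid <- (o$acs_start + o$acs_end) %/% 2L
    on_chr <- which(ndrs$chrom == o$chrom)
    if (length(on_chr) == 0) next
    gap <- interval_gap(ndrs$start[on_chr], ndrs$end[on_chr], o$acs_start, o$acs_end)
    near <- on_chr[gap <= max_dist]
    if (length(near) == 0) next
    dmid <- ifelse(mid >= ndrs$start[near] & mid < ndrs$end[near], 0L,
                   pmin(abs(ndrs$start[near] - mid), abs(ndrs$end[near] - 1L - mid)))
    ov <- pmax(0L, pmin(ndrs$end[near], o$acs_end) - pmax(ndrs$start[near], o$acs_start))
    pick <- near[order(dmid, -ov, ndrs$start[near])][1]
    if (is.na(claimed[pick])) claimed[pick] <- o$name
  }
  ndrs$origin_associated <- !is.na(claimed)
  ndrs$origin_name <- claimed
  list(origin_ndrs = ndrs[ndrs$origin_associated, , drop = FALSE],
       nonorigin_ndrs = ndrs[!ndrs$origin_associated, , drop = FALSE])
}

#' Per-origin NDR width
#'
#' Width of the NDR claimed by each origin. Origins with no claimed NDR
#' within the association distance are reported as closed (`closed = TRUE`,
#' width `NA`) — a distinct sentinel, never 0, so averages exclude them
#' explicitly.
#'
#' @param origins origin tibble.
#' @param origin_ndrs claimed-NDR tibble from
#'   [associate_ndrs_with_origins()].
#' @return tibble with `name`, `ndr_width`, `closed`.
#' @export
origin_ndr_width <- function(origins, origin_ndrs) {
  w <- origin_ndrs$width[match(origins$name, origin_ndrs$origin_name)]
  tibble::tibble(name = origins$name,
                 ndr_width = as.integer(w),
                 closed = is.na(w))
}

#' Export NDRs as BED (width in the score column)
#' @param ndrs NDR tibble.
#' @param path output file.
#' @export
write_ndr_bed <- function(ndrs, path) {
  nm <- ifelse(is.na(ndrs$origin_name), "NDR", ndrs$origin_name)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", ndrs$chrom, ndrs$start,
                     ndrs$end, nm, ndrs$width), path)
  invisible(path)
}
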