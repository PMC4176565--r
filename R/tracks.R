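# Per-base track containers.
#
# A start_track holds, per chromosome, two integer vectors of read 5'-end
# counts: `plus[i]` counts plus-strand 5' ends at 0-based position i-1, and
# `minus[i]` counts minus-strand 5' ends whose fragment's half-open end
# coordinate is i. A coverage_track holds one real-valued vector per
# chromosome.

#' Construct a stranded read-start track
#'
#' @param plus,minus named lists of non-negative integer vectors, one element
#'   per chromosome, all of length equal to the chromosome length.
#' @return an object of class `start_track`.
#' @export
start_track <- function(plus, minus) {
  assert_that(identical(names(plus), names(minus)) && !is.null(names(plus)),
              "plus/minus must be named lists over identical chromosomes")
  for (chr in names(plus)) {
    assert_that(length(plus[[chr]]) == length(minus[[chr]]),
                paste0("length mismatch on ", chr))
    assert_that(all(plus[[chr]] >= 0) && all(minus[[chr]] >= 0),
                "start counts must be non-negative")
  }
  structure(list(plus = plus, minus = minus), class = "start_track")
}

#' @export
print.start_track <- function(x, ...) {
  n <- sum(vapply(x$plus, sum, 0)) + sum(vapply(x$minus, sum, 0))
  cat("<start_track> ", length(x$plus), " chromosome(s), ",
      format(n, big.mark = ","), " read 5' ends\n", sep = "")
  invisible(x)
}

track_chroms <- function(x) names(x$plus %||% x$values)

total_reads <- function(starts) {
  sum(vapply(starts$plus, sum, 0)) + sum(vapply(starts$minus, sum, 0))
}

#' Construct a coverage track
#'
#' @param values named list of finite numeric vectors, one per chromosome.
#' @param normalized logical; `TRUE` once the genome-wide mean has been
#'   scaled to 1.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(values, normalized = FALSE) {
  assert_that(!is.null(names(values)) && !anyDuplicated(names(values)),
              "values must be a uniquely named list")
  structure(list(values = values, normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", length(x$values), " chromosome(s), genome mean ",
      signif(track_mean(x), 4),
      if (isTRUE(x$normalized)) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

# genome-wide mean over all non-missing bases (not a mean of per-chromosome
# means)
track_mean <- function(track) {
  tot <- sum(vapply(track$values, function(v) sum(v, na.rm = TRUE), 0))
  n <- sum(vapply(track$values, function(v) sum(!is.na(v)), 0L))
  tot / n
}

#' Convert a coverage track to a long tibble
#'
#' @param x a `coverage_track`.
#' @param ... unused.
#' @return a tibble with columns `chrom`, `pos` (0-based) and `signal`.
#' @exportS3Method tibble::as_tibble
as_tibble.coverage_track <- function(x, ...) {
  purrr::map2_dfr(names(x$values), x$values, function(chr, v) {
    tibble::tibble(chrom = chr, pos = seq_along(v) - 1L, signal = v)
  })
}

#' Tabulate stranded read intervals into a start track
#'
#' Takes reads as a tibble (`chrom`, `start`, `end`, `strand`; 0-based
#' half-open) and counts plus-strand 5' ends at `start` and minus-strand 5'
#' ends at the fragment end coordinate `end`.
#'
#' @param reads tibble of stranded reads.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a `start_track`.
#' @export
reads_to_start_track <- function(reads, chrom_lengths) {
  assert_that(all(c("chrom", "start", "end", "strand") %in% names(reads)),
              "reads need chrom/start/end/strand columns")
  assert_that(all(reads$strand %in% c("+", "-")), "strand must be '+' or '-'")
  assert_that(all(reads$chrom %in% names(chrom_lengths)),
              "reads reference chromosomes absent from chrom_lengths")
  plus <- minus <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    p <- reads[reads$chrom == chr & reads$strand == "+", ]
    m <- reads[reads$chrom == chr & reads$strand == "-", ]
    assert_that(all(p$start >= 0 & p$start < len) && all(m$end >= 1 & m$end <= len),
                paste0("read coordinates outside ", chr))
    plus[[chr]] <- tabulate(p$start + 1L, nbins = len)
    minus[[chr]] <- tabulate(m$end, nbins = len)
  }
  start_track(plus, minus)
}

#' Convert a start track back to a read tibble
#'
#' Inverse of [reads_to_start_track()] given the read length: each plus 5'
#' end at `s` becomes `[s, s + read_length)` and each minus end coordinate
#' `e` becomes `[e - read_length, e)` (clipped at chromosome edges).
#'
#' @param starts a `start_track`.
#' @param read_length read length in bp.
#' @return a tibble with `chrom`, `start`, `end`, `strand`.
#' @export
start_track_to_reads <- function(starts, read_length = 40L) {
  purrr::map_dfr(names(starts$plus), function(chr) {
    len <- length(starts$plus[[chr]])
    p <- starts$plus[[chr]]
    m <- starts$minus[[chr]]
    pp <- rep.int(seq_along(p) - 1L, p)
    me <- rep.int(seq_along(m), m)
    dplyr::bind_rows(
      tibble::tibble(chrom = chr, start = pp,
                     end = pmin(pp + read_length, len), strand = "+"),
      tibble::tibble(chrom = chr, start = pmax(me - read_length, 0L),
                     end = me, strand = "-")
    )
  })
}
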