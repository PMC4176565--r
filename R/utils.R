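#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All genomic coordinates are
# 0-based half-open; conversions to 1-based file dialects happen only in io.R.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Sliding-window mean with symmetrically shrinking edge windows
#'
#' Each position is averaged over `[i - h, i + h]` where
#' `h = min(floor(window/2), distance to either end)`, so edge windows shrink
#' symmetrically and the value at every position is the exact arithmetic mean
#' of the covered, non-missing bases. `NA` values are excluded from both the
#' sum and the count; a window with no usable base yields `NA`.
#'
#' @param x numeric vector (may contain `NA`).
#' @param window window size in bases; the half-width used is `floor(window/2)`.
#' @return numeric vector of the same length as `x`.
#' @export
sliding_mean <- function(x, window = 1000L) {
  assert_that(is_scalar_number(window) && window >= 1, "`window` must be a positive number")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  k <- as.integer(window) %/% 2L
  pos <- seq_len(n)
  h <- pmin(k, pos - 1L, n - pos)
  ok <- !is.na(x)
  cs <- cumsum(c(0, ifelse(ok, x, 0)))
  cn <- cumsum(c(0L, as.integer(ok)))
  lo <- pos - h
  hi <- pos + h
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0L] <- NA_real_
  out
}

# maximal runs of TRUE in a logical vector -> tibble(start, end) 0-based half-open
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# deterministic child seed derived from a user seed and a stage tag,
# kept below 2^31
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435L + h) %% 2147483647)
}

`%not_in%` <- function(x, table) !(x %in% table)
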