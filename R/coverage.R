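# From stranded read 5'-ends to the normalized nucleosome occupancy signal.

#' Build raw fragment coverage from read starts
#'
#' Each plus-strand 5' end at position `s` contributes +1 over
#' `[s, s + extension)`; each minus-strand fragment end coordinate `e`
#' contributes +1 over `[e - extension, e)`. Reads only mark fragment
#' boundaries, so the extension (default one nucleosome footprint, 147 bp)
#' reconstructs the protected fragment rather than the sequenced read.
#' Intervals are clipped at chromosome edges.
#'
#' @param starts a `start_track`.
#' @param extension fragment extension in bp (> 0).
#' @return a raw (unnormalized) `coverage_track`.
#' @export
starts_to_raw_coverage <- function(starts, extension = 147L) {
  assert_that(is_scalar_number(extension) && extension > 0, "`extension` must be > 0")
  extension <- as.integer(extension)
  values <- lapply(names(starts$plus), function(chr) {
    p <- starts$plus[[chr]]
    m <- starts$minus[[chr]]
    n <- length(p)
    ip <- which(p > 0)
    im <- which(m > 0)
    # difference-array construction; edge clipping creates duplicate indices,
    # so contributions are accumulated with rowsum before assignment
    idx <- c(ip,                                   # plus adds at start
             pmin(ip - 1L + extension, n) + 1L,    # plus ends (clipped)
             pmax(im - extension, 0L) + 1L,        # minus adds (clipped)
             im + 1L)                              # minus ends
    w <- c(p[ip], -p[ip], m[im], -m[im])
    d <- numeric(n + 1L)
    if (length(idx)) {
      agg <- rowsum(w, idx)
      at <- as.integer(rownames(agg))
      d[at] <- agg[, 1]
    }
    cumsum(d[seq_len(n)])
  })
  names(values) <- names(starts$plus)
  coverage_track(values, normalized = FALSE)
}

#' Normalize a track by its genome-wide mean
#'
#' Every base is divided by the mean over all bases of all chromosomes (not
#' per-chromosome means), so the returned track has genome mean exactly 1.
#'
#' @param track a `coverage_track`.
#' @return a normalized `coverage_track`.
#' @export
normalize_by_genome_mean <- function(track) {
  mu <- track_mean(track)
  assert_that(is.finite(mu) && mu > 0, "cannot normalize: genome mean is not positive")
  coverage_track(lapply(track$values, function(v) v / mu), normalized = TRUE)
}

# B3-spline biorthogonal lowpass; sums to 1 so constants are preserved.
BSPLINE3_KERNEL <- c(1, 4, 6, 4, 1) / 16

# reflect 1-based indices into [1, n] (whole-point symmetric extension)
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    under <- i < 1L
    over <- i > n
    if (!any(under) && !any(over)) return(i)
    i[under] <- 2L - i[under]
    i[over] <- 2L * n - i[over]
  }
}

# one stationary-wavelet smoothing pass at scale 2^(level-1)
atrous_pass <- function(x, hole, boundary) {
  n <- length(x)
  taps <- seq_along(BSPLINE3_KERNEL) - (length(BSPLINE3_KERNEL) + 1L) %/% 2L
  out <- numeric(n)
  base <- seq_len(n)
  for (k in seq_along(taps)) {
    idx <- base + taps[k] * hole
    idx <- if (boundary == "periodic") ((idx - 1L) %% n) + 1L else reflect_idx(idx, n)
    out <- out + BSPLINE3_KERNEL[k] * x[idx]
  }
  out
}

#' Multilevel biorthogonal wavelet smoothing
#'
#' Stationary (a-trous) multilevel wavelet decomposition with a biorthogonal
#' B3-spline scaling filter: the signal is split into detail layers at dyadic
#' scales plus a residual smooth, the `level` finest detail layers are
#' suppressed, and the reconstruction is returned at the original length.
#' Because detail suppression is the identity minus a fixed convolution, the
#' operator is linear and preserves constants.
#'
#' @param signal numeric vector, length at least `2^level`.
#' @param level number of finest dyadic scales to suppress (>= 1). The default
#'   3 removes structure below roughly 20 bp, well under one nucleosome
#'   footprint.
#' @param boundary `"symmetric"` (default) or `"periodic"` extension.
#' @return smoothed numeric vector of the same length.
#' @export
wavelet_smooth <- function(signal, level = 3L, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  assert_that(is_scalar_number(level) && level >= 1, "`level` must be >= 1")
  level <- as.integer(level)
  assert_that(length(signal) >= 2^level,
              "signal shorter than 2^level; reduce the decomposition level")
  out <- signal
  for (j in seq_len(level)) {
    out <- atrous_pass(out, hole = 2L^(j - 1L), boundary = boundary)
  }
  out
}

#' Wavelet-smooth every chromosome of a coverage track
#' @param track a `coverage_track`.
#' @inheritParams wavelet_smooth
#' @return a `coverage_track` with the same normalization flag.
#' @export
smooth_track <- function(track, level = 3L, boundary = "symmetric") {
  coverage_track(lapply(track$values, wavelet_smooth, level = level, boundary = boundary),
                 normalized = track$normalized)
}
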