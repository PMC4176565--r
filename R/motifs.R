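# Forkhead (Fkh1/2) consensus scanning and ACS-anchored motif geometry:
# strict IUPAC matching of RTAAAYA on both strands, oriented motif-density
# profiles, and the dual-site spacing rule for early origins.

# exact IUPAC scan of one sequence string, both strands; 0-based starts
scan_iupac_one <- function(seq, pattern) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(pattern)
  fwd <- Biostrings::matchPattern(pat, subj, fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = "subject")
  tibble::tibble(
    start = c(IRanges::start(fwd) - 1L, IRanges::start(rev) - 1L),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

#' Scan a genome for strict IUPAC consensus matches
#'
#' Exact IUPAC matching on both strands (for `RTAAAYA`, R = A/G and
#' Y = C/T). An `N` in the genome never matches. Hits are reported as the
#' 0-based leftmost base of the match in plus-strand coordinates and sorted.
#'
#' @param genome a `genome_seq`.
#' @param pattern IUPAC DNA consensus (default the Forkhead motif
#'   `"RTAAAYA"`).
#' @return tibble with `chrom`, `start`, `strand`.
#' @export
scan_motif <- function(genome, pattern = "RTAAAYA") {
  letters <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, IUPAC_DNA)
  assert_that(length(bad) == 0,
              paste0("invalid IUPAC letter(s) in pattern: ", paste(bad, collapse = ", ")))
  out <- purrr::map_dfr(names(genome), function(chr) {
    hits <- scan_iupac_one(genome[[chr]], toupper(pattern))
    if (nrow(hits) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(chrom = chr), hits)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character()))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

# oriented offsets of motif starts relative to the ACS midpoint of one origin
oriented_hit_offsets <- function(hits, origin, halfwidth = 600L) {
  mid <- (origin$acs_start + origin$acs_end) %/% 2L
  h <- hits[hits$chrom == origin$chrom, ]
  off <- if (origin$acs_strand == "+") h$start - mid else mid - h$start
  sort(off[abs(off) <= halfwidth])
}

#' ACS-anchored motif density profile
#'
#' Counts motif starts at each oriented offset across the origin set and
#' smooths them with a Gaussian kernel renormalized at the window edges so
#' each hit contributes exactly unit mass: total mass is preserved by the
#' smoothing.
#'
#' @param hits tibble from [scan_motif()].
#' @param origins origin tibble (T-rich orientation applied per origin).
#' @param halfwidth window half-width in bp.
#' @param smoothing_bw Gaussian kernel sd in bp; 0 disables smoothing.
#' @return tibble with `offset` (-halfwidth..halfwidth) and `density`.
#' @export
motif_density_profile <- function(hits, origins, halfwidth = 600L,
                                  smoothing_bw = 10) {
  assert_that(nrow(origins) > 0, "empty origin set")
  n_off <- 2L * halfwidth + 1L
  counts <- numeric(n_off)
  for (i in seq_len(nrow(origins))) {
    off <- oriented_hit_offsets(hits, origins[i, ], halfwidth)
    if (length(off)) {
      t <- tabulate(off + halfwidth + 1L, nbins = n_off)
      counts <- counts + t
    }
  }
  offsets <- seq(-halfwidth, halfwidth)
  if (smoothing_bw > 0) {
    r <- ceiling(4 * smoothing_bw)
    kern <- stats::dnorm(-r:r, sd = smoothing_bw)
    kern <- kern / sum(kern)
    # per-position kernel mass remaining inside the window, for edge
    # renormalization (each hit keeps exactly unit mass)
    inside <- stats::filter(rep(1, n_off), kern, sides = 2)
    inside[is.na(inside)] <- vapply(which(is.na(inside)), function(j) {
      lo <- max(1L, j - r); hi <- min(n_off, j + r)
      sum(kern[(lo - j + r + 1L):(hi - j + r + 1L)])
    }, 0)
    adj <- counts / as.numeric(inside)
    dens <- numeric(n_off)
    for (k in seq_along(kern)) {
      sh <- k - r - 1L
      src <- seq_len(n_off) - sh
      ok <- src >= 1L & src <= n_off
      dens[ok] <- dens[ok] + kern[k] * adj[src[ok]]
    }
  } else {
    dens <- counts
  }
  tibble::tibble(offset = offsets, density = dens)
}

#' Dual Forkhead-site configuration at one origin
#'
#' `TRUE` when two motif hits exist such that at least one lies within
#' `proximal_max` of the ACS midpoint and their separation is between
#' `sep_min` and `sep_max` inclusive ("not less than / not more than").
#' Separations are measured between oriented motif start offsets.
#'
#' @param origin one-row origin tibble.
#' @param hits tibble from [scan_motif()].
#' @param proximal_max maximum |offset| of the ACS-proximal site, bp.
#' @param sep_min,sep_max inclusive separation bounds, bp.
#' @param halfwidth search half-width around the ACS, bp.
#' @param origin_ndrs optional claimed-NDR tibble from
#'   [associate_ndrs_with_origins()]; when given, both sites must also lie
#'   inside the origin's claimed NDR (stricter mode; origins with a closed
#'   NDR return `FALSE`).
#' @return logical scalar.
#' @export
dual_site_configuration <- function(origin, hits, proximal_max = 50L,
                                    sep_min = 60L, sep_max = 120L,
                                    halfwidth = 600L, origin_ndrs = NULL) {
  off <- oriented_hit_offsets(hits, origin, halfwidth)
  if (!is.null(origin_ndrs)) {
    nd <- origin_ndrs[!is.na(origin_ndrs$origin_name) &
                        origin_ndrs$origin_name == origin$name, ]
    if (nrow(nd) == 0) return(FALSE)
    mid <- (origin$acs_start + origin$acs_end) %/% 2L
    pos <- if (origin$acs_strand == "+") mid + off else mid - off
    off <- off[pos >= nd$start[1] & pos < nd$end[1]]
  }
  if (length(off) < 2) return(FALSE)
  for (i in seq_along(off)) {
    if (abs(off[i]) > proximal_max) next
    sep <- abs(off - off[i])
    if (any(sep >= sep_min & sep <= sep_max)) return(TRUE)
  }
  FALSE
}

#' Fraction of early origins with the dual-site configuration
#'
#' @param origins origin tibble with timing labels.
#' @param hits tibble from [scan_motif()].
#' @param ... passed to [dual_site_configuration()].
#' @return fraction in [0, 1].
#' @export
fraction_with_configuration <- function(origins, hits, ...) {
  early <- origins[origins$timing == "early", ]
  assert_that(nrow(early) > 0, "no early origins")
  has <- vapply(seq_len(nrow(early)), function(i)
    dual_site_configuration(early[i, ], hits, ...), TRUE)
  mean(has)
}

#' Export motif hits as BED6
#' @param hits tibble from [scan_motif()].
#' @param path output file.
#' @param width motif length in bp.
#' @export
write_motif_bed <- function(hits, path, width = 7L) {
  writeLines(sprintf("%s\t%d\t%d\tfkh%d\t0\t%s", hits$chrom, hits$start,
                     hits$start + width, seq_len(nrow(hits)), hits$strand), path)
  invisible(path)
}
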