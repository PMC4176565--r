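# Intergenic regions and their orientation categories: tandem (co-directional
# flanking genes), divergent ((-,+) left to right) or convergent ((+,-));
# origin placement within them and observed-vs-expected category frequencies.

categorize_igr <- function(left_strand, right_strand) {
  dplyr::case_when(
    left_strand == right_strand ~ "tandem",
    left_strand == "-" & right_strand == "+" ~ "divergent",
    TRUE ~ "convergent"
  )
}

#' Build intergenic regions from gene annotations
#'
#' Genes are sorted per chromosome; overlapping genes are merged into a
#' single blocking interval (logged) whose flank strands are taken from the
#' rightmost-reaching gene on the left and the leftmost-starting gene on the
#' right. One IGR is emitted between each adjacent pair; chromosome-terminal
#' gaps are excluded.
#'
#' @param genes gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return tibble with `chrom`, `start`, `end`, `left_gene`, `right_gene`,
#'   `left_strand`, `right_strand`, `category`.
#' @export
build_igrs <- function(genes) {
  purrr::map_dfr(unique(genes$chrom), function(chr) {
    g <- genes[genes$chrom == chr, ]
    g <- g[order(g$start, g$end), ]
    if (nrow(g) < 2) {
      rlang::warn(paste0("fewer than 2 genes on ", chr, ": no IGRs there"))
      return(NULL)
    }
    # merge overlapping genes into blocking intervals
    block_id <- cumsum(c(1L, as.integer(g$start[-1] >= cummax(g$end)[-nrow(g)])))
    if (max(block_id) < nrow(g)) {
      rlang::inform(paste0("merged ", nrow(g) - max(block_id),
                           " overlapping gene(s) on ", chr, " for IGR construction"))
    }
    blocks <- g |>
      dplyr::mutate(.b = block_id) |>
      dplyr::group_by(.data$.b) |>
      dplyr::summarise(
        right_reach_gene = .data$gene_id[which.max(.data$end)],
        right_reach_strand = .data$strand[which.max(.data$end)],
        left_start_gene = .data$gene_id[which.min(.data$start)],
        left_start_strand = .data$strand[which.min(.data$start)],
        start = min(.data$start), end = max(.data$end),
        .groups = "drop")
    nb <- nrow(blocks)
    if (nb < 2) return(NULL)
    i <- seq_len(nb - 1L)
    tibble::tibble(
      chrom = chr,
      start = blocks$end[i], end = blocks$start[i + 1L],
      left_gene = blocks$right_reach_gene[i],
      right_gene = blocks$left_start_gene[i + 1L],
      left_strand = blocks$right_reach_strand[i],
      right_strand = blocks$left_start_strand[i + 1L]
    ) |>
      dplyr::filter(.data$end > .data$start) |>
      dplyr::mutate(category = categorize_igr(.data$left_strand, .data$right_strand))
  })
}

#' Expected IGR category frequencies under random gene strands
#'
#' With gene strands drawn independently and equiprobably, tandem IGRs
#' (`++` or `--`) occur with probability 1/2 and divergent and convergent
#' IGRs with probability 1/4 each.
#'
#' @return named numeric vector `(tandem = 0.5, divergent = 0.25,
#'   convergent = 0.25)`.
#' @export
expected_category_frequencies <- function() {
  c(tandem = 0.5, divergent = 0.25, convergent = 0.25)
}

#' IGR category of each origin
#'
#' The category of the IGR containing the ACS midpoint (half-open
#' containment: a midpoint exactly at an IGR start belongs to that IGR);
#' `"intragenic"` when no IGR contains it.
#'
#' @param origins origin tibble.
#' @param igrs tibble from [build_igrs()].
#' @return tibble with `name`, `category`.
#' @export
origin_igr_category <- function(origins, igrs) {
  cat <- vapply(seq_len(nrow(origins)), function(i) {
    mid <- (origins$acs_start[i] + origins$acs_end[i]) %/% 2L
    hit <- which(igrs$chrom == origins$chrom[i] &
                   igrs$start <= mid & mid < igrs$end)
    if (length(hit) == 0) "intragenic" else igrs$category[hit[1]]
  }, "")
  tibble::tibble(name = origins$name, category = cat)
}

#' Observed vs expected IGR-category composition of origins
#'
#' Observed fractions are computed over categorized (non-intragenic) origins;
#' the ratio is observed/expected.
#'
#' @param origin_categories tibble from [origin_igr_category()].
#' @param expected named expected frequencies; defaults to
#'   [expected_category_frequencies()].
#' @return tibble with `category`, `n`, `observed`, `expected`, `ratio`.
#' @export
category_enrichment <- function(origin_categories,
                                expected = expected_category_frequencies()) {
  oc <- origin_categories[origin_categories$category != "intragenic", ]
  assert_that(nrow(oc) > 0, "no origin falls inside an IGR")
  counts <- table(factor(oc$category, levels = names(expected)))
  tibble::tibble(category = names(expected),
                 n = as.integer(counts),
                 observed = as.numeric(counts) / nrow(oc),
                 expected = as.numeric(expected)) |>
    dplyr::mutate(ratio = .data$observed / .data$expected)
}

#' Chi-square goodness of fit of origin IGR categories
#'
#' Optional test of the categorized-origin counts against the expected
#' tandem/divergent/convergent frequencies.
#'
#' @inheritParams category_enrichment
#' @return the `htest` object from [stats::chisq.test()].
#' @export
category_gof_test <- function(origin_categories,
                              expected = expected_category_frequencies()) {
  oc <- origin_categories[origin_categories$category != "intragenic", ]
  assert_that(nrow(oc) > 0, "no origin falls inside an IGR")
  counts <- table(factor(oc$category, levels = names(expected)))
  stats::chisq.test(as.integer(counts), p = as.numeric(expected))
}

#' Export IGRs as BED with the category in the name field
#' @param igrs IGR tibble.
#' @param path output file.
#' @export
write_igr_bed <- function(igrs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", igrs$chrom, igrs$start,
                     igrs$end, igrs$category), path)
  invisible(path)
}
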