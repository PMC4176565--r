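# ACS-anchored, T-rich-oriented origin windows; aggregate profiles; k-means
# classification into classes ordered by decreasing NDR width; early/late
# composition.

#' Extract an oriented ACS-anchored window for one origin
#'
#' The window covers offsets `-halfwidth..halfwidth` around the ACS midpoint
#' (position 0). When `acs_strand` is `-` the vector is reversed so the
#' T-rich strand reads left to right.
#'
#' @param track a `coverage_track`.
#' @param origin one-row origin tibble.
#' @param halfwidth window half-width in bp.
#' @return numeric vector of length `2*halfwidth + 1`, or `NULL` (with a
#'   warning) when the window would run past a chromosome end.
#' @export
extract_origin_window <- function(track, origin, halfwidth = 600L) {
  v <- track$values[[origin$chrom]]
  assert_that(!is.null(v), paste0("track lacks chromosome ", origin$chrom))
  mid <- (origin$acs_start + origin$acs_end) %/% 2L
  if (mid - halfwidth < 0L || mid + halfwidth >= length(v)) {
    rlang::warn(paste0("origin ", origin$name,
                       " excluded: window extends past a chromosome end"))
    return(NULL)
  }
  w <- v[(mid - halfwidth + 1L):(mid + halfwidth + 1L)]
  if (origin$acs_strand == "-") w <- rev(w)
  w
}

#' Build the origin profile matrix
#'
#' One oriented window per usable origin; origins whose window would be
#' edge-truncated are excluded with a warning.
#'
#' @param track a `coverage_track` (normally the combined positioning
#'   profile).
#' @param origins origin tibble.
#' @param halfwidth window half-width in bp.
#' @return numeric matrix, rows named by origin, columns named by offset
#'   `-halfwidth..halfwidth`.
#' @export
origin_profile_matrix <- function(track, origins, halfwidth = 600L) {
  rows <- lapply(seq_len(nrow(origins)), function(i)
    extract_origin_window(track, origins[i, ], halfwidth))
  keep <- !vapply(rows, is.null, TRUE)
  assert_that(any(keep), "no origin window fits inside the genome")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- origins$name[keep]
  colnames(m) <- as.character(seq(-halfwidth, halfwidth))
  m
}

#' Column-wise mean profile over a subset of origins
#'
#' @param matrix origin profile matrix.
#' @param subset row names (or logical/integer index); default all rows.
#' @return named numeric vector over offsets.
#' @export
aggregate_profile <- function(matrix, subset = NULL) {
  m <- if (is.null(subset)) matrix else matrix[subset, , drop = FALSE]
  assert_that(nrow(m) > 0, "empty origin subset")
  colMeans(m)
}

#' Cluster origin profiles into ordered architecture classes
#'
#' Euclidean k-means on the window rows (best of `restarts` seeded
#' initializations by total within-cluster sum of squares, each run capped at
#' `iterations` iterations). Class labels are then re-assigned so that the
#' class-mean NDR width decreases strictly from class 1 to class k (ties:
#' larger classes first). Rows are not rescaled before clustering.
#'
#' @param matrix origin profile matrix.
#' @param ndr_widths named vector (origin -> NDR width in bp, `NA` for closed
#'   origins) used for class ordering, typically from [origin_ndr_width()].
#' @param k number of classes.
#' @param iterations maximum k-means iterations per restart.
#' @param restarts number of random initializations.
#' @param seed integer seed controlling the initializations.
#' @return an `origin_classes` object: `assignment` tibble (`name`,
#'   `class_id`), `centroids` (k x window matrix), `class_mean_ndr_width`,
#'   `sizes`, `tot_withinss`, `k`.
#' @export
cluster_origin_profiles <- function(matrix, ndr_widths, k = 6L,
                                    iterations = 10000L, restarts = 10L,
                                    seed = 1L) {
  assert_that(nrow(matrix) >= k, "fewer origin rows than requested classes")
  assert_that(!is.null(names(ndr_widths)) || length(ndr_widths) == nrow(matrix),
              "ndr_widths must be named or match the matrix rows")
  if (!is.null(names(ndr_widths))) ndr_widths <- ndr_widths[rownames(matrix)]
  set.seed(as.integer(seed))
  n_distinct <- nrow(unique(matrix))
  k_eff <- min(k, n_distinct)
  if (k_eff < k) {
    rlang::warn(paste0("only ", n_distinct, " distinct profiles; collapsing to ",
                       k_eff, " class(es)"))
  }
  km <- stats::kmeans(matrix, centers = k_eff, iter.max = iterations,
                      nstart = restarts)
  mean_w <- vapply(seq_len(k_eff), function(c) {
    w <- ndr_widths[km$cluster == c]
    if (all(is.na(w))) -Inf else mean(w, na.rm = TRUE)
  }, 0)
  sizes <- tabulate(km$cluster, nbins = k_eff)
  ord <- order(-mean_w, -sizes)          # widest first; ties -> more members
  relabel <- match(seq_len(k_eff), ord)
  cls <- relabel[km$cluster]
  structure(list(
    assignment = tibble::tibble(name = rownames(matrix), class_id = cls),
    centroids = km$centers[ord, , drop = FALSE],
    class_mean_ndr_width = mean_w[ord],
    sizes = sizes[ord],
    tot_withinss = km$tot.withinss,
    k = k_eff
  ), class = "origin_classes")
}

#' @export
print.origin_classes <- function(x, ...) {
  cat("<origin_classes> k = ", x$k, "; sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  cat("class mean NDR width: ",
      paste(round(x$class_mean_ndr_width, 1), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Early/late composition of architecture classes
#'
#' For each timing group, the fraction of its origins falling in each class.
#'
#' @param classes an `origin_classes` object (or its `assignment` tibble).
#' @param origins origin tibble with timing labels.
#' @return tibble with `timing`, `class_id`, `n`, `fraction`; fractions sum
#'   to 1 within each timing group.
#' @export
class_timing_composition <- function(classes, origins) {
  asg <- if (inherits(classes, "origin_classes")) classes$assignment else classes
  k <- max(asg$class_id)
  tb <- dplyr::inner_join(asg, origins[, c("name", "timing")], by = "name")
  tb <- tb[tb$timing %in% c("early", "late"), ]
  assert_that(nrow(tb) > 0, "no origins with early/late timing labels")
  tb |>
    dplyr::count(.data$timing, .data$class_id, name = "n") |>
    tidyr::complete(timing = unique(tb$timing), class_id = seq_len(k),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$timing) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.origin_classes <- function(x, ...) {
  x$assignment |>
    dplyr::group_by(.data$class_id) |>
    dplyr::mutate(class_size = dplyr::n()) |>
    dplyr::ungroup()
}

#' Tidiers for fitted origin classifications
#'
#' `tidy()` returns the per-origin assignment; `glance()` a one-row model
#' summary.
#'
#' @param x an `origin_classes` object.
#' @param ... unused.
#' @name tidiers
#' @rdname tidiers
#' @exportS3Method generics::glance
glance.origin_classes <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignment),
                 tot_withinss = x$tot_withinss,
                 width_range = diff(range(x$class_mean_ndr_width)))
}
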