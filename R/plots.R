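# ggplot2 views of the main result types.

#' Aggregate origin profiles per architecture class
#'
#' @param matrix origin profile matrix.
#' @param classes optional `origin_classes`; one line per class when given,
#'   otherwise a single aggregate.
#' @return a ggplot object.
#' @export
plot_aggregate_profiles <- function(matrix, classes = NULL) {
  offs <- as.integer(colnames(matrix))
  df <- if (is.null(classes)) {
    tibble::tibble(offset = offs, signal = aggregate_profile(matrix),
                   class_id = factor(1))
  } else {
    purrr::map_dfr(seq_len(classes$k), function(c) {
      nm <- classes$assignment$name[classes$assignment$class_id == c]
      tibble::tibble(offset = offs,
                     signal = aggregate_profile(matrix, nm),
                     class_id = factor(c))
    })
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$signal,
                                   colour = .data$class_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from ACS (bp, T-rich orientation)",
                  y = "normalized nucleosome signal", colour = "class") +
    ggplot2::theme_minimal()
}

#' Heatmap of classified origin windows
#'
#' Rows are origins ordered by class and then by decreasing NDR width,
#' mirroring the usual presentation of origin architecture classes.
#'
#' @param object an `origin_classes` object.
#' @param matrix the origin profile matrix that was clustered.
#' @param ndr_widths optional named widths used for within-class ordering.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.origin_classes <- function(object, matrix, ndr_widths = NULL, ...) {
  asg <- object$assignment
  w <- if (is.null(ndr_widths)) stats::setNames(rep(0, nrow(asg)), asg$name)
  else ndr_widths[asg$name]
  ord <- asg$name[order(asg$class_id, -ifelse(is.na(w), -Inf, w))]
  df <- tibble::as_tibble(matrix, rownames = "name") |>
    tidyr::pivot_longer(-"name", names_to = "offset", values_to = "signal") |>
    dplyr::mutate(offset = as.integer(.data$offset),
                  name = factor(.data$name, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$name,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "darkorange", midpoint = 1) +
    ggplot2::labs(x = "offset from ACS (bp)", y = NULL, fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Motif density against the aggregate nucleosome profile
#'
#' @param density tibble from [motif_density_profile()].
#' @param profile optional aggregate profile vector over the same offsets.
#' @return a ggplot object.
#' @export
plot_motif_density <- function(density, profile = NULL) {
  g <- ggplot2::ggplot(density, ggplot2::aes(.data$offset, .data$density)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "offset from ACS (bp, T-rich orientation)",
                  y = "Fkh motif density") +
    ggplot2::theme_minimal()
  if (!is.null(profile)) {
    sc <- max(density$density) / max(profile)
    df <- tibble::tibble(offset = density$offset, signal = profile * sc)
    g <- g + ggplot2::geom_line(data = df,
                                ggplot2::aes(.data$offset, .data$signal),
                                colour = "steelblue", alpha = 0.7)
  }
  g
}
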