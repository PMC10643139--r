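#' Heatmap of a peak-centered signal matrix
#'
#' Rows are ordered by increasing mean signal (the standard heatmap ranking);
#' signal is shown on an intensity color scale.
#'
#' @param object An `ssx_matrix`.
#' @param trim Upper quantile at which values are winsorized for display
#'   (default 0.98).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ssx_matrix
#' @export
autoplot.ssx_matrix <- function(object, trim = 0.98, ...) {
  ord <- rank_rows(object)
  df <- tidy(object)
  df$row <- match(df$region_id, object$region_id[ord])
  cap <- quantile(df$value, trim, names = FALSE)
  df$value <- pmin(df$value, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "distance from peak midpoint (bp)",
                  y = "peaks (ranked by increasing signal)") +
    ggplot2::theme_minimal()
}

#' Metaprofile of one or more signal matrices
#'
#' Mean signal per offset bin across regions, one line per matrix.
#'
#' @param matrices A named list of `ssx_matrix` objects on the same grid.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(matrices) {
  if (inherits(matrices, "ssx_matrix")) matrices <- list(signal = matrices)
  df <- purrr::imap(matrices, function(m, nm) {
    tibble::tibble(
      sample = nm,
      offset = (seq_len(ncol(m$values)) - 1L) * m$bin - m$flank,
      mean_signal = colMeans(m$values)
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_signal,
                                   color = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from peak midpoint (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Histogram of per-region log2 ratios colored by cluster
#'
#' @param ratios Tibble from [log2_ratio()].
#' @param model Optional `ssx_kmeans` fit on the same regions.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_ratio_clusters <- function(ratios, model = NULL, bins = 60) {
  df <- ratios
  if (!is.null(model)) {
    df <- dplyr::left_join(df, model$assignments, by = "region_id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio))
  p <- if (is.null(model)) {
    p + ggplot2::geom_histogram(bins = bins)
  } else {
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$cluster), bins = bins)
  }
  p + ggplot2::labs(x = "log2 ratio", y = "peaks") + ggplot2::theme_minimal()
}

#' Heatmap of a track correlation matrix
#'
#' @param m Symmetric correlation matrix from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(m) {
  df <- tibble::tibble(
    a = rep(rownames(m) %||% paste0("track", seq_len(nrow(m))), times = ncol(m)),
    b = rep(colnames(m) %||% paste0("track", seq_len(ncol(m))), each = nrow(m)),
    rho = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of salt-fraction percentages
#'
#' @param profile Tibble from [salt_percentages()].
#' @return A ggplot object.
#' @export
plot_salt_profile <- function(profile) {
  profile$fraction <- factor(profile$fraction, levels = profile$fraction)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$fraction, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "salt fraction", y = "% of total protein") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
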