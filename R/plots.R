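#' Group means of the mNC indices
#'
#' Bar-with-error-bar figure of the four mNC indices per group (error bars
#' are one standard error of the mean), the standard presentation of
#' hemispheric mean-network-connectivity differences.
#'
#' @param mnc mNC tibble with `group` and the index columns.
#' @param indices Index columns to plot.
#' @return A ggplot object.
#' @export
plot_mnc_groups <- function(mnc, indices = c("lFCw", "rFCw", "FCb", "FCg")) {
  long <- mnc |>
    tidyr::pivot_longer(dplyr::all_of(indices),
                        names_to = "index", values_to = "value") |>
    dplyr::mutate(index = factor(.data$index, levels = indices)) |>
    dplyr::group_by(.data$group, .data$index) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean network connectivity (Fisher z)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ln_mnc_anova <- function(object, ...) {
  plot_mnc_groups(object$data, object$indices)
}

#' Tumor volume versus mNC scatter plots
#'
#' Per-subgroup scatter of each mNC index against tumor volume with a
#' least-squares line — the lesion-volume association figure.
#'
#' @param mnc Patient mNC tibble with `tumor_volume_cm3`.
#' @param indices Index columns to plot.
#' @return A ggplot object.
#' @export
plot_tv_correlation <- function(mnc, indices = c("lFCw", "rFCw", "FCb", "FCg")) {
  pats <- mnc[!is.na(mnc$tumor_volume_cm3), ]
  long <- pats |>
    tidyr::pivot_longer(dplyr::all_of(indices),
                        names_to = "index", values_to = "value") |>
    dplyr::mutate(index = factor(.data$index, levels = indices))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tumor_volume_cm3,
                                     y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "firebrick") +
    ggplot2::facet_grid(index ~ group, scales = "free_y") +
    ggplot2::labs(x = "tumor volume (cm³)",
                  y = "mean network connectivity (Fisher z)") +
    ggplot2::theme_minimal()
}

#' Axial montage of a lesion overlap map
#'
#' @param density 3-D density array from [overlap_map()].
#' @param slices Axial (third-axis) slice indices to show; defaults to four
#'   evenly spaced slices with nonzero density.
#' @return A ggplot object.
#' @export
plot_overlap_map <- function(density, slices = NULL) {
  d <- dim(density)
  if (is.null(slices)) {
    nz <- which(apply(density, 3, sum) > 0)
    if (length(nz) == 0) nz <- seq_len(d[3])
    slices <- unique(round(seq(min(nz), max(nz), length.out = min(4, length(nz)))))
  }
  df <- purrr::map_dfr(slices, function(k) {
    sl <- density[, , k]
    tibble::tibble(i = rep(seq_len(d[1]), d[2]),
                   j = rep(seq_len(d[2]), each = d[1]),
                   n = as.vector(sl), slice = paste0("z = ", k))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$n)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "lesions / voxel") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
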