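#' Difference-vs-density curve for one region
#'
#' The figure-style view of a contrast: observed mean nodal-degree
#' difference (points) across the density grid, the permutation
#' confidence band (ribbon), and filled markers where the cell is
#' FDR-significant.
#'
#' @param result An `nd_contrast` table from [permutation_test()].
#' @param region Region label to plot.
#' @param file Optional output path (`.png`, `.svg`, `.pdf`); written via
#'   [ggplot2::ggsave()].
#' @param width,height Device size in inches when writing to file.
#' @return The ggplot object, invisibly when writing to file.
#' @export
plot_difference_curves <- function(result, region, file = NULL,
                                   width = 7, height = 4) {
  stopifnot(is.data.frame(result))
  if (!region %in% result$region) {
    stop("unknown region: ", region, call. = FALSE)
  }
  dat <- result[result$region == region, , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$diff,
                                     shape = .data$significant),
                        colour = "black", size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "FDR significant") +
    ggplot2::labs(x = "Density (%)",
                  y = "Mean nodal-degree difference",
                  title = sprintf("%s: %s", dat$contrast[1], region)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Nodal degree versus density for both sides of a contrast
#'
#' @param result An `nd_contrast` table.
#' @param region Region label.
#' @return A ggplot object with one curve per side (cohort means).
#' @export
plot_nd_curves <- function(result, region) {
  stopifnot(is.data.frame(result))
  if (!region %in% result$region) {
    stop("unknown region: ", region, call. = FALSE)
  }
  dat <- result[result$region == region, , drop = FALSE]
  spec <- attr(result, "spec")
  sides <- if (!is.null(spec)) {
    c(side_key(spec$side_a), side_key(spec$side_b))
  } else c("side_a", "side_b")
  long <- data.frame(
    density = rep(dat$density, 2),
    nd = c(dat$mean_a, dat$mean_b),
    side = rep(sides, each = nrow(dat)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$density, y = .data$nd,
                                     colour = .data$side)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Density (%)", y = "Mean nodal degree",
                  title = region, colour = NULL) +
    ggplot2::theme_minimal()
}
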