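#' Plot a height map
#'
#' @param map A `height_map` (or `afm_scene`).
#' @param ... Unused.
#' @return A ggplot raster of the topograph (nm scale bar).
#' @export
plot_height_map <- function(map, ...) {
  if (inherits(map, "afm_scene")) map <- map$height_map
  px <- pixel_size(map)
  df <- tidyr::expand_grid(y = (seq_len(nrow(map)) - 0.5) * px,
                           x = (seq_len(ncol(map)) - 0.5) * px)
  df$height <- as.vector(t(unclass(map)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)", option = "magma") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.height_map <- function(object, ...) plot_height_map(object, ...)

#' @export
autoplot.afm_scene <- function(object, ...) {
  p <- plot_height_map(object$height_map)
  if (nrow(object$truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$truth,
      ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      shape = 1, colour = "cyan", size = 3)
  }
  p
}

#' @export
autoplot.position_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$mid, .data$counts_per_dna)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey60") +
    ggplot2::labs(x = "position (% DNA length, folded)",
                  y = "complexes / DNA") +
    ggplot2::theme_classic()
  if (!is.null(fit) && inherits(fit, "position_fit") && fit$converged) {
    bw <- attr(object, "bin_width")
    n_dna <- attr(object, "n_dna")
    xx <- seq(0, 50, length.out = 400)
    yy <- (fit$background_level + fit$A_sp * bw *
             reflected_dnorm(xx, fit$components$center, fit$components$sd)) /
      n_dna
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(mid = xx, counts_per_dna = yy),
      colour = "firebrick", linewidth = 0.8)
  }
  p
}

#' @export
autoplot.bend_fit <- function(object, ...) {
  h <- object$histogram
  bw <- h$mid[2] - h$mid[1]
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$mid, .data$counts)) +
    ggplot2::geom_col(width = bw, fill = "grey60") +
    ggplot2::coord_cartesian(xlim = c(0, 120)) +
    ggplot2::labs(x = "DNA bend angle (deg)", y = "count") +
    ggplot2::theme_classic()
  if (object$converged) {
    xx <- seq(0, 120, length.out = 400)
    comp <- object$components
    curves <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
      tibble::tibble(
        mid = xx,
        counts = comp$area[i] * bw * (dnorm(xx, comp$center[i], comp$sd[i]) +
                                        dnorm(xx, -comp$center[i], comp$sd[i])),
        state = factor(i))
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$mid, .data$counts, colour = .data$state),
      linewidth = 0.8)
  }
  p
}

#' @export
autoplot.hill_fit <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "polarisation") +
    ggplot2::theme_classic()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_point(
      data = curve,
      ggplot2::aes(.data$concentration_nM, .data$polarisation))
  }
  if (is.finite(object$KD)) {
    lims <- if (!is.null(curve)) range(curve$concentration_nM[
      curve$concentration_nM > 0]) else c(object$KD / 50, object$KD * 50)
    cc <- 10^seq(log10(lims[1]), log10(lims[2]), length.out = 200)
    fitted <- object$baseline + object$amplitude * cc^object$hill_n /
      (object$KD^object$hill_n + cc^object$hill_n)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(concentration_nM = cc, polarisation = fitted),
      ggplot2::aes(.data$concentration_nM, .data$polarisation),
      colour = "firebrick")
  }
  p
}
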