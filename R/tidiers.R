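#' Tidy a position fit
#'
#' @param x A `position_fit`.
#' @param ... Unused.
#' @return One row per fitted component: `term`, `center`, `sd`, `area`.
#' @export
tidy.position_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$components, term = "site_gaussian", .before = 1),
    tibble::tibble(term = "background", center = NA_real_, sd = NA_real_,
                   area = x$A_nsp)
  )
}

#' @rdname tidy.position_fit
#' @return For `glance()`: one row with `A_sp`, `A_nsp`, `background_level`,
#'   `residual_rss`, `converged`.
#' @export
glance.position_fit <- function(x, ...) {
  tibble::tibble(A_sp = x$A_sp, A_nsp = x$A_nsp,
                 background_level = x$background_level,
                 residual_rss = x$residual_rss, converged = x$converged)
}

#' Tidy a bend-state decomposition
#'
#' @param x A `bend_fit`.
#' @param ... Unused.
#' @return One row per state: `term`, `center`, `sd`, `area`.
#' @export
tidy.bend_fit <- function(x, ...) {
  dplyr::mutate(x$components,
                term = paste0("state_", seq_len(nrow(x$components))),
                .before = 1)
}

#' @rdname tidy.bend_fit
#' @export
glance.bend_fit <- function(x, ...) {
  tibble::tibble(k = nrow(x$components), residual_rss = x$residual_rss,
                 converged = x$converged)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("KD", "hill_n", "baseline", "amplitude"),
                 estimate = c(x$KD, x$hill_n, x$baseline, x$amplitude))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(KD = x$KD, hill_n = x$hill_n, r_squared = x$r_squared,
                 accepted = x$accepted, reason = x$reason)
}

#' Tidy an occupancy result
#'
#' @param x An `occupancy_result`.
#' @param ... Unused.
#' @return The per-replicate tibble.
#' @export
tidy.occupancy_result <- function(x, ...) x$per_replicate

#' @rdname tidy.occupancy_result
#' @export
glance.occupancy_result <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd,
                 n_replicates = nrow(x$per_replicate),
                 bin_lo = x$bin[1], bin_hi = x$bin[2])
}

#' Tidy a replicate comparison
#'
#' @param x A `replicate_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `t_statistic`, `degrees_freedom`, `p_value`,
#'   `stars`.
#' @export
tidy.replicate_comparison <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic,
                 degrees_freedom = x$degrees_freedom,
                 p_value = x$p_value, stars = x$stars)
}
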