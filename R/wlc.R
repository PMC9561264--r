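#' Sample a surface-equilibrated worm-like chain conformation
#'
#' Draws one DNA molecule as a discrete 2D worm-like chain (WLC) in the
#' surface-equilibrated regime appropriate for DNA deposited on mica from low
#' ionic strength buffer: per-step turning angles are independent zero-mean
#' Gaussians with variance `segment_length / persistence_length`, giving the
#' 2D tangent correlation exp(-s / 2P).
#'
#' The chain is discretised so that `contour_length = n_segments *
#' segment_length` holds exactly.
#'
#' @param config An [afm_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed (callers seed once and draw many chains).
#' @return A tibble of class `wlc_chain` with columns `x`, `y` (nm) and
#'   `arclength` (cumulative nm), and attributes `contour_length` and
#'   `segment_length`.
#' @examples
#' ch <- sample_wlc_chain(afm_config(), seed = 1)
#' attr(ch, "contour_length")
#' @export
sample_wlc_chain <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$contour_length_nm
  P <- config$persistence_length
  if (!is.finite(L) || L <= 0 || !is.finite(P) || P <= 0) {
    abort("chain lengths and persistence length must be positive",
          class = "afmdna_invalid_config")
  }
  n_seg <- max(2L, as.integer(round(L / config$segment_length)))
  seg <- L / n_seg
  # headings: cumulative sum of Gaussian turning angles; first heading random
  turns <- rnorm(n_seg - 1L, mean = 0, sd = sqrt(seg / P))
  theta <- cumsum(c(runif(1, 0, 2 * pi), turns))
  x <- cumsum(c(0, seg * cos(theta)))
  y <- cumsum(c(0, seg * sin(theta)))
  new_wlc_chain(x, y, seg)
}

new_wlc_chain <- function(x, y, seg) {
  n <- length(x)
  out <- tibble::tibble(x = x, y = y, arclength = seg * (seq_len(n) - 1))
  attr(out, "contour_length") <- seg * (n - 1L)
  attr(out, "segment_length") <- seg
  class(out) <- c("wlc_chain", class(out))
  out
}

#' Theoretical mean squared end-to-end distance of a 2D worm-like chain
#'
#' Closed form for a surface-equilibrated chain with tangent correlation
#' exp(-s / 2P): `4 P L (1 - (2P/L) (1 - exp(-L / 2P)))`.
#'
#' @param contour_length Contour length L in nm.
#' @param persistence_length Persistence length P in nm.
#' @return Mean squared end-to-end distance in nm^2.
#' @examples
#' wlc_msd_theory(171.7, 50)
#' @export
wlc_msd_theory <- function(contour_length, persistence_length) {
  L <- contour_length
  P <- persistence_length
  4 * P * L * (1 - (2 * P / L) * (1 - exp(-L / (2 * P))))
}

chain_headings <- function(chain) {
  dx <- diff(chain$x)
  dy <- diff(chain$y)
  atan2(dy, dx)
}

rebuild_chain <- function(chain, theta) {
  seg <- attr(chain, "segment_length")
  x <- cumsum(c(chain$x[1], seg * cos(theta)))
  y <- cumsum(c(chain$y[1], seg * sin(theta)))
  new_wlc_chain(x, y, seg)
}

#' Impose a defined bend angle at an interior chain node
#'
#' Rigidly rotates the downstream arm of the chain about the given node so
#' that the local deflection from collinearity at that node equals
#' `angle_deg` (signed; the magnitude is the DNA bend angle, 0 deg meaning
#' locally straight DNA). Arclengths are preserved exactly.
#'
#' @param chain A `wlc_chain`.
#' @param node_index Interior node (2 .. n-1) at which to set the bend.
#' @param angle_deg Target deflection in degrees.
#' @return The modified `wlc_chain`.
#' @examples
#' cfg <- afm_config(persistence_length = 1e9)
#' ch <- sample_wlc_chain(cfg, seed = 1)          # effectively straight
#' bent <- impose_bend(ch, 86, 70)
#' @export
impose_bend <- function(chain, node_index, angle_deg) {
  n <- nrow(chain)
  if (node_index <= 1L || node_index >= n) {
    abort("bend site must be an interior chain node",
          class = "afmdna_invalid_site")
  }
  theta <- chain_headings(chain)
  current <- theta[node_index] - theta[node_index - 1L]
  current <- atan2(sin(current), cos(current))  # wrap to (-pi, pi]
  delta <- angle_deg * pi / 180 - current
  theta[node_index:length(theta)] <- theta[node_index:length(theta)] + delta
  rebuild_chain(chain, theta)
}

#' Straighten a chain locally around a node
#'
#' Sets all turning angles within `half_width_nm` of the node to zero,
#' emulating local stiffening of the DNA by a bound protein; the rest of the
#' conformation is carried along rigidly and arclengths are preserved.
#'
#' @param chain A `wlc_chain`.
#' @param node_index Centre node of the straightened window.
#' @param half_width_nm Half-width of the window in nm (default 15).
#' @return The modified `wlc_chain`.
#' @export
straighten_chain <- function(chain, node_index, half_width_nm = 15) {
  seg <- attr(chain, "segment_length")
  k <- max(1L, as.integer(ceiling(half_width_nm / seg)))
  theta <- chain_headings(chain)
  lo <- max(2L, node_index - k)
  hi <- min(length(theta), node_index + k)
  if (hi >= lo) {
    # zero the turning angles in the window; downstream headings shift rigidly
    turns <- diff(theta)
    turns[(lo - 1L):(hi - 1L)] <- 0
    theta <- cumsum(c(theta[1], turns))
  }
  rebuild_chain(chain, theta)
}

#' Interpolate a point (and local tangent) at a given arclength
#'
#' @param chain A `wlc_chain`.
#' @param s Arclength in nm, in `[0, contour_length]`.
#' @return A list with `x`, `y`, `node` (nearest node index) and `tangent`
#'   (unit vector).
#' @keywords internal
chain_point_at <- function(chain, s) {
  L <- attr(chain, "contour_length")
  s <- min(max(s, 0), L)
  seg <- attr(chain, "segment_length")
  i <- min(nrow(chain) - 1L, max(1L, as.integer(floor(s / seg)) + 1L))
  t <- (s - chain$arclength[i]) / seg
  list(
    x = chain$x[i] + t * (chain$x[i + 1L] - chain$x[i]),
    y = chain$y[i] + t * (chain$y[i + 1L] - chain$y[i]),
    node = if (t < 0.5) i else i + 1L,
    tangent = {
      v <- c(chain$x[i + 1L] - chain$x[i], chain$y[i + 1L] - chain$y[i])
      v / sqrt(sum(v^2))
    }
  )
}
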