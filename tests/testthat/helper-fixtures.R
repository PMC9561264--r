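# small configurations and hand-built geometry used across tests

quiet_cfg <- function(...) {
  afm_config(molecules_per_scene = 1, nonspecific_rate = 0,
             occupancy_specific = 0, ...)
}

# a straight chain of given length/orientation positioned in scene nm coords
straight_chain <- function(length_nm = 171.7, angle_deg = 0,
                           x0 = 250, y0 = 250, seg = 1) {
  n <- round(length_nm / seg)
  seg <- length_nm / n
  th <- angle_deg * pi / 180
  afmdna:::new_wlc_chain(x0 + seg * (0:n) * cos(th),
                         y0 + seg * (0:n) * sin(th), seg)
}

# a closed circular chain (loop) in scene coordinates
circle_chain <- function(radius_nm = 30, x0 = 250, y0 = 250, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  x <- x0 + radius_nm * cos(th)
  y <- y0 + radius_nm * sin(th)
  seg <- sqrt(diff(x)^2 + diff(y)^2)[1]
  afmdna:::new_wlc_chain(x, y, seg)
}

# an afm_trace built directly from a polyline (no imaging involved)
polyline_trace <- function(x, y) {
  seglens <- sqrt(diff(x)^2 + diff(y)^2)
  afmdna:::new_afm_trace(
    tibble::tibble(x = x, y = y, arclength = c(0, cumsum(seglens))),
    qc_status = "ok")
}

# a polyline with a kink of the given deflection at its midpoint
kinked_polyline <- function(angle_deg, arm_nm = 40, step = 0.5) {
  s <- seq(0, arm_nm, by = step)
  th <- angle_deg * pi / 180
  x <- c(-rev(s), s * cos(th))[-(length(s) + 1)]
  y <- c(rep(0, length(s)), s * sin(th))[-(length(s) + 1)]
  polyline_trace(x + 100, y + 100)
}

empty_complexes <- function() place_complexes(0, afm_config())

render_chains <- function(chains, cfg, complexes = NULL) {
  if (is.null(complexes)) complexes <- empty_complexes()
  render_scene(chains, complexes, cfg)
}
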