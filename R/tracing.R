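#' Flatten an AFM height map
#'
#' Removes per-scanline polynomial background, the standard first step of AFM
#' topograph processing. The background is fit per image row on pixels below a
#' molecule-exclusion threshold (median + 3 robust sd of the whole image) and
#' subtracted. Rows where fewer than `order + 2` background pixels remain fall
#' back to the global (pooled) fit, with a warning.
#'
#' @param map A `height_map`.
#' @param polynomial_order Background polynomial order per scanline, 0-3.
#' @return The flattened `height_map` (median background approximately 0).
#' @export
flatten <- function(map, polynomial_order = 1) {
  if (!polynomial_order %in% 0:3) {
    abort("polynomial_order must be one of 0, 1, 2, 3",
          class = "afmdna_invalid_input")
  }
  m <- unclass(map)
  thr <- median(m) + 3 * mad(m)
  mask <- m <= thr  # background pixels
  nc <- ncol(m)
  tt <- seq_len(nc) / nc  # scaled column coordinate
  basis <- outer(tt, 0:polynomial_order, "^")
  # pooled fallback fit over all background pixels
  gl_idx <- which(mask, arr.ind = TRUE)
  gb <- basis[gl_idx[, 2], , drop = FALSE]
  g_coef <- stats::.lm.fit(gb, m[mask])$coefficients
  warned <- FALSE
  for (i in seq_len(nrow(m))) {
    sel <- mask[i, ]
    if (sum(sel) < polynomial_order + 2) {
      coefs <- g_coef
      if (!warned) {
        warn("scanline(s) fully masked; using global background fit")
        warned <- TRUE
      }
    } else {
      coefs <- stats::.lm.fit(basis[sel, , drop = FALSE], m[i, sel])$coefficients
    }
    m[i, ] <- m[i, ] - drop(basis %*% coefs)
  }
  height_map(m, pixel_size(map))
}

robust_noise_sd <- function(map) {
  m <- unclass(map)
  mad(m[m <= median(m) + 3 * mad(m)])
}

#' Segment candidate molecules in a height map
#'
#' Applies a light matched-filter Gaussian smoothing (pixel noise is white,
#' the molecules are already tip-broadened, so smoothing raises the
#' signal-to-noise ratio several-fold at little signal cost), thresholds the
#' smoothed map and labels connected regions (8-connectivity). Regions
#' touching the image border are flagged `edge_touching`; tiny regions below
#' `min_area_px` are dropped as noise specks.
#'
#' @param map A flattened `height_map`.
#' @param threshold_nm Height threshold on the smoothed map; default is 3
#'   robust noise sd above the background median, with a 0.05 nm floor for
#'   noiseless data.
#' @param min_area_px Minimum region area in pixels.
#' @param smooth_sigma_nm Matched-filter smoothing sd in nm (default 2; 0
#'   disables).
#' @return List with `labels` (integer matrix, 0 = background), `regions`
#'   (tibble: `region_id`, `area_px`, `touches_border`), `threshold_nm`, and
#'   `smoothed` (the smoothed `height_map` used for thresholding).
#' @export
segment_molecules <- function(map, threshold_nm = NULL, min_area_px = 20,
                              smooth_sigma_nm = 2) {
  px <- pixel_size(map)
  sm <- if (smooth_sigma_nm > 0) {
    height_map(gaussian_blur(unclass(map), smooth_sigma_nm / px), px)
  } else map
  m <- unclass(sm)
  if (is.null(threshold_nm)) {
    threshold_nm <- median(m) + max(3 * robust_noise_sd(sm), 0.05)
  }
  bw <- m > threshold_nm
  labels <- EBImage::bwlabel(bw)
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  if (max(labels) == 0) {
    return(list(labels = labels,
                regions = tibble::tibble(region_id = integer(),
                                         area_px = integer(),
                                         touches_border = logical()),
                threshold_nm = threshold_nm, smoothed = sm))
  }
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area_px)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  regions <- tibble::tibble(
    region_id = seq_along(keep),
    area_px = areas[keep],
    touches_border = seq_along(keep) %in% border_ids
  )
  list(labels = labels, regions = regions, threshold_nm = threshold_nm,
       smoothed = sm)
}

# ---- skeletonization (Zhang-Suen thinning) --------------------------------

zhang_suen_thin <- function(bw) {
  pad <- function(m) {
    r <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    r[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    r
  }
  m <- pad(bw)
  nr <- nrow(m); nc <- ncol(m)
  core_i <- 2:(nr - 1L); core_j <- 2:(nc - 1L)
  shift <- function(m, di, dj) m[core_i + di, core_j + dj]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- m[core_i, core_j]
      p2 <- shift(m, -1L, 0L); p3 <- shift(m, -1L, 1L)
      p4 <- shift(m, 0L, 1L);  p5 <- shift(m, 1L, 1L)
      p6 <- shift(m, 1L, 0L);  p7 <- shift(m, 1L, -1L)
      p8 <- shift(m, 0L, -1L); p9 <- shift(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        m[core_i, core_j] <- p
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[core_i, core_j]
}

# ring of 8-neighbour offsets in circular order (N, NE, E, SE, S, SW, W, NW)
ring_offsets <- function(nr) c(-1L, nr - 1L, nr, nr + 1L, 1L, -nr + 1L, -nr, -nr - 1L)

# crossing number: connected neighbour groups around the 8-ring; robust to
# the staircase artefacts of thinning (where plain 8-degree over-counts).
# 1 = endpoint, 2 = path pixel, >= 3 = branch point
crossing_number <- function(skel, idx, nr) {
  ring <- ring_offsets(nr)
  vapply(idx, function(i) {
    v <- skel[i + ring]
    sum(v & !c(v[-1], v[1]))
  }, integer(1))
}

# prune spurs shorter than prune_px (in pixels) from a skeleton mask
prune_skeleton <- function(skel, prune_px) {
  nr <- nrow(skel)
  ring <- ring_offsets(nr)
  repeat {
    idx <- which(skel)
    if (length(idx) == 0) break
    cn <- crossing_number(skel, idx, nr)
    endpoints <- idx[cn == 1L]
    branch <- idx[cn >= 3L]
    if (length(endpoints) == 0 || length(branch) == 0) break
    removed_any <- FALSE
    for (ep in endpoints) {
      if (!skel[ep]) next
      path <- ep
      prev <- -1L
      cur <- ep
      hit_branch <- FALSE
      while (length(path) <= prune_px) {
        nb <- cur + ring
        nb <- nb[skel[nb] & nb != prev & !(nb %in% path)]
        if (length(nb) == 0) break
        # prefer a 4-connected continuation
        d4 <- nb[abs(nb - cur) == 1L | abs(nb - cur) == nr]
        nxt <- if (length(d4) > 0) d4[1] else nb[1]
        if (nxt %in% branch) { hit_branch <- TRUE; break }
        prev <- cur
        cur <- nxt
        path <- c(path, cur)
      }
      if (hit_branch && length(path) <= prune_px) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

order_skeleton_path <- function(skel, start, nr) {
  # walk from an endpoint, preferring 4-connected steps
  offs4 <- c(-1L, 1L, -nr, nr)
  offs8 <- c(-nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  path <- integer(sum(skel))
  k <- 0L
  cur <- start
  visited <- skel & FALSE
  repeat {
    k <- k + 1L
    path[k] <- cur
    visited[cur] <- TRUE
    nb4 <- cur + offs4
    nb4 <- nb4[skel[nb4] & !visited[nb4]]
    if (length(nb4) > 0) { cur <- nb4[1]; next }
    nb8 <- cur + offs8
    nb8 <- nb8[skel[nb8] & !visited[nb8]]
    if (length(nb8) > 0) { cur <- nb8[1]; next }
    break
  }
  path[seq_len(k)]
}

# Gaussian-weighted local quadratic fits (Savitzky-Golay style): straight and
# gently curved stretches are reproduced faithfully, while the 2-3 px
# staircase zigzag of the discrete skeleton - which inflates polyline
# length - is strongly attenuated
smooth_path <- function(ij, half = 3L) {
  n <- nrow(ij)
  if (n < 2L * half + 1L) return(ij)
  sigma <- max(half * 0.5, 0.75)
  out <- ij
  for (p in seq_len(n)) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    t <- (lo:hi) - p
    wt <- dnorm(t, 0, sigma)
    deg <- if (hi - lo >= 4L) 2L else 1L
    basis <- outer(t, 0:deg, "^") * sqrt(wt)
    out[p, 1] <- stats::.lm.fit(basis, ij[lo:hi, 1] * sqrt(wt))$coefficients[1]
    out[p, 2] <- stats::.lm.fit(basis, ij[lo:hi, 2] * sqrt(wt))$coefficients[1]
  }
  out
}

#' Bilinearly interpolate heights at arbitrary nm coordinates
#'
#' @param map A `height_map`.
#' @param x,y Coordinates in nm (pixel (i, j) centre is at
#'   ((j - 0.5) px, (i - 0.5) px)).
#' @return Heights in nm (NA outside the grid).
#' @keywords internal
interp_height <- function(map, x, y) {
  m <- unclass(map)
  px <- pixel_size(map)
  cj <- x / px + 0.5
  ci <- y / px + 0.5
  j0 <- floor(cj); i0 <- floor(ci)
  fj <- cj - j0; fi <- ci - i0
  nr <- nrow(m); nc <- ncol(m)
  get <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- rep(NA_real_, length(i))
    v[ok] <- m[cbind(i[ok], j[ok])]
    v
  }
  v <- (1 - fi) * ((1 - fj) * get(i0, j0) + fj * get(i0, j0 + 1)) +
    fi * ((1 - fj) * get(i0 + 1, j0) + fj * get(i0 + 1, j0 + 1))
  v
}

#' Trace the contour of one segmented molecule
#'
#' Skeletonises the region (Zhang-Suen thinning), prunes spurs shorter than
#' `prune_nm`, classifies the topology (`closed_loop` if no endpoints remain,
#' `branched` if more than two), orders the skeleton end-to-end, smooths it to
#' subpixel resolution by sliding local quadratic fits, and extends both ends
#' along the local tangent while the underlying height stays above the
#' segmentation threshold (the skeleton of a ribbon stops about half a ribbon
#' width short of each true end). The contour length is the polyline length of
#' the smoothed subpixel path.
#'
#' @param region_id Region label to trace.
#' @param segmentation Result of [segment_molecules()].
#' @param map The flattened `height_map` the segmentation came from.
#' @param prune_nm Spur-prune length in nm (default 6).
#' @param smooth_window Sliding-fit window in skeleton points (odd, default 7).
#' @return An `afm_trace`: tibble `x`, `y`, `arclength` (nm) with attributes
#'   `qc_status` (`ok`, `closed_loop`, `branched`, or `edge_touching`),
#'   `contour_length`, `region_id`.
#' @export
trace_contour <- function(region_id, segmentation, map,
                          prune_nm = 6, smooth_window = 7) {
  labels <- segmentation$labels
  px <- pixel_size(map)
  mask <- labels == region_id
  # isolate with a clear 1-px margin so neighbour lookups never wrap
  idx <- which(mask, arr.ind = TRUE)
  i_rng <- range(idx[, 1]); j_rng <- range(idx[, 2])
  sub <- matrix(FALSE, diff(i_rng) + 5L, diff(j_rng) + 5L)
  sub[cbind(idx[, 1] - i_rng[1] + 3L, idx[, 2] - j_rng[1] + 3L)] <- TRUE
  off_i <- i_rng[1] - 3L
  off_j <- j_rng[1] - 3L

  qc <- if (isTRUE(segmentation$regions$touches_border[
    segmentation$regions$region_id == region_id])) "edge_touching" else "ok"

  skel <- zhang_suen_thin(sub)
  skel <- prune_skeleton(skel, max(1L, as.integer(round(prune_nm / px))))
  nr <- nrow(skel)
  sk_idx <- which(skel)
  if (length(sk_idx) < 3) {
    return(new_afm_trace(tibble::tibble(x = numeric(), y = numeric(),
                                        arclength = numeric()),
                         qc_status = "branched", region_id = region_id))
  }
  cn <- crossing_number(skel, sk_idx, nr)
  n_end <- sum(cn == 1L)
  n_branch <- sum(cn >= 3L)
  if (qc == "ok" && n_end == 0L) qc <- "closed_loop"
  if (qc == "ok" && (n_end > 2L || n_branch > 0L)) qc <- "branched"

  start <- if (n_end >= 1L) sk_idx[which(cn == 1L)[1]] else sk_idx[1]
  path_idx <- order_skeleton_path(skel, start, nr)
  ii <- ((path_idx - 1L) %% nr) + 1L
  jj <- ((path_idx - 1L) %/% nr) + 1L
  ij <- cbind(ii + off_i, jj + off_j)  # back to full-image pixel coords
  ij <- smooth_path(ij, half = (smooth_window - 1L) %/% 2L)
  xy <- cbind((ij[, 2] - 0.5) * px, (ij[, 1] - 0.5) * px)

  if (qc == "ok") {
    xy <- extend_trace_ends(xy, segmentation$smoothed %||% map,
                            segmentation$threshold_nm, px)
  }
  seglens <- sqrt(rowSums(diff(xy)^2))
  path <- tibble::tibble(x = xy[, 1], y = xy[, 2],
                         arclength = c(0, cumsum(seglens)))
  new_afm_trace(path, qc_status = qc, region_id = region_id)
}

new_afm_trace <- function(path, qc_status, region_id = NA_integer_) {
  attr(path, "qc_status") <- qc_status
  attr(path, "contour_length") <-
    if (nrow(path) > 0) path$arclength[nrow(path)] else 0
  attr(path, "region_id") <- region_id
  class(path) <- c("afm_trace", class(path))
  path
}

# extend both polyline ends along the terminal tangent up to the point where
# the height falls to half the ridge level: a blurred ridge end crosses 50%
# of its plateau height at the true end position, while the skeleton itself
# stops about half a ribbon width short of it
extend_trace_ends <- function(xy, map, threshold_nm, px) {
  n <- nrow(xy)
  mid <- max(1L, floor(n * 0.25)):min(n, ceiling(n * 0.75))
  ridge <- median(interp_height(map, xy[mid, 1], xy[mid, 2]), na.rm = TRUE)
  stop_h <- max(ridge / 2, threshold_nm)
  extend_one <- function(xy, head_end) {
    n <- nrow(xy)
    if (head_end) {
      p0 <- xy[1, ]; pref <- xy[min(4, n), ]
    } else {
      p0 <- xy[n, ]; pref <- xy[max(1, n - 3), ]
    }
    v <- p0 - pref
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) return(xy)
    v <- v / nv
    step <- 0.25 * px
    max_steps <- as.integer(ceiling(5 * px / step))
    last_ok <- NULL
    for (k in seq_len(max_steps)) {
      p <- p0 + k * step * v
      h <- interp_height(map, p[1], p[2])
      if (is.na(h) || h < stop_h) break
      last_ok <- p
    }
    if (is.null(last_ok)) return(xy)
    if (head_end) rbind(last_ok, xy) else rbind(xy, last_ok)
  }
  xy <- extend_one(xy, TRUE)
  extend_one(xy, FALSE)
}

#' Trace all molecules in a height map
#'
#' Convenience wrapper: [flatten()] (optional), [segment_molecules()], then
#' [trace_contour()] per region, followed by [filter_traces()].
#'
#' @param map A `height_map`.
#' @param flatten_order Per-scanline background order, or `NULL` to skip
#'   flattening.
#' @param threshold_nm Segmentation threshold (default: automatic).
#' @param expected_length_nm Expected full-substrate contour length for the
#'   length filter (default 505 bp x 0.34 nm = 171.7 nm).
#' @param tolerance_fraction Length filter half-width as a fraction of the
#'   expected length (default 0.2).
#' @param prune_nm,smooth_window Passed to [trace_contour()].
#' @param smooth_sigma_nm Matched-filter smoothing for segmentation; see
#'   [segment_molecules()].
#' @return A tibble with one row per region: `molecule_id`,
#'   `contour_length_nm`, `qc_status`, and a list-column `trace` of
#'   `afm_trace` objects.
#' @export
trace_molecules <- function(map, flatten_order = 1, threshold_nm = NULL,
                            expected_length_nm = 505 * 0.34,
                            tolerance_fraction = 0.2,
                            prune_nm = 6, smooth_window = 7,
                            smooth_sigma_nm = 2) {
  if (!is.null(flatten_order)) map <- flatten(map, flatten_order)
  seg <- segment_molecules(map, threshold_nm,
                           smooth_sigma_nm = smooth_sigma_nm)
  if (nrow(seg$regions) == 0) {
    return(tibble::tibble(molecule_id = integer(),
                          contour_length_nm = numeric(),
                          qc_status = character(), trace = list()))
  }
  traces <- purrr::map(seg$regions$region_id, trace_contour,
                       segmentation = seg, map = map,
                       prune_nm = prune_nm, smooth_window = smooth_window)
  out <- tibble::tibble(
    molecule_id = seg$regions$region_id,
    contour_length_nm = purrr::map_dbl(traces, ~ attr(.x, "contour_length")),
    qc_status = purrr::map_chr(traces, ~ attr(.x, "qc_status")),
    trace = traces
  )
  filter_traces(out, expected_length_nm, tolerance_fraction)
}

#' Flag traces whose contour length is off the expected substrate length
#'
#' Restricts downstream analysis to complete substrate molecules: `ok` traces
#' with `|contour_length - expected| > tolerance * expected` are re-flagged
#' `off_length`.
#'
#' @param traces Tibble from [trace_molecules()] (columns
#'   `contour_length_nm`, `qc_status`).
#' @param expected_length_nm Expected contour length in nm.
#' @param tolerance_fraction Relative tolerance in (0, 1).
#' @return The tibble with `qc_status` updated.
#' @export
filter_traces <- function(traces, expected_length_nm = 505 * 0.34,
                          tolerance_fraction = 0.2) {
  if (tolerance_fraction <= 0 || tolerance_fraction >= 1) {
    abort("tolerance_fraction must lie in (0, 1)",
          class = "afmdna_invalid_input")
  }
  off <- traces$qc_status == "ok" &
    abs(traces$contour_length_nm - expected_length_nm) >
      tolerance_fraction * expected_length_nm
  traces$qc_status[off] <- "off_length"
  traces
}
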