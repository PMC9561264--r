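#' Detect bound complexes along a traced DNA contour
#'
#' Samples the height profile along the contour, takes the profile median as
#' the bare-DNA ridge level, and reports local maxima exceeding the ridge by
#' at least `min_peak_height_nm`, with non-maximum suppression inside a
#' `nms_window_nm` window (tip-broadened blobs span roughly that width).
#'
#' @param trace An `afm_trace` with `qc_status = "ok"`.
#' @param map The flattened `height_map`.
#' @param min_peak_height_nm Minimum peak prominence above the DNA ridge
#'   (default 0.4 nm).
#' @param nms_window_nm Non-maximum-suppression window in nm (default 10).
#' @param step_nm Profile sampling step in nm (default 0.5).
#' @param smooth_sigma_nm Matched-filter smoothing applied to the map before
#'   profiling (default 2 nm; pass 0 when the map is already smoothed or
#'   noiseless).
#' @return Tibble with `arclength` (nm along the contour) and `height_nm`
#'   (profile height at the peak); zero rows if the molecule is bare.
#' @export
detect_complexes <- function(trace, map, min_peak_height_nm = 0.4,
                             nms_window_nm = 10, step_nm = 0.5,
                             smooth_sigma_nm = 2) {
  if (!identical(attr(trace, "qc_status"), "ok")) {
    abort("complex detection requires an ok trace",
          class = "afmdna_invalid_input")
  }
  if (smooth_sigma_nm > 0) {
    map <- height_map(gaussian_blur(unclass(map),
                                    smooth_sigma_nm / pixel_size(map)),
                      pixel_size(map))
  }
  L <- attr(trace, "contour_length")
  s <- seq(0, L, by = step_nm)
  xs <- approx(trace$arclength, trace$x, xout = s)$y
  ys <- approx(trace$arclength, trace$y, xout = s)$y
  h <- interp_height(map, xs, ys)
  ridge <- median(h, na.rm = TRUE)
  n <- length(h)
  is_max <- h > c(-Inf, h[-n]) & h >= c(h[-1], -Inf) & !is.na(h)
  cand <- which(is_max & (h - ridge) > min_peak_height_nm)
  if (length(cand) == 0) {
    return(tibble::tibble(arclength = numeric(), height_nm = numeric()))
  }
  cand <- cand[order(h[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(s[i] - s[kept]) > nms_window_nm)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  tibble::tibble(arclength = s[kept], height_nm = h[kept])
}

#' Fractional binding position, folded to the nearer DNA end
#'
#' Since the two DNA ends cannot be distinguished, the position is the
#' arclength distance to the nearer end as a percentage of the contour:
#' `100 * min(s, L - s) / L`, in `[0, 50]`.
#'
#' @param trace An `afm_trace`.
#' @param peak_arclength Arclength of the complex in nm, in `[0, L]`.
#' @return Folded position in percent of DNA length.
#' @examples
#' # a peak at the midpoint of any trace maps to 50
#' @export
fractional_position <- function(trace, peak_arclength) {
  L <- attr(trace, "contour_length")
  if (any(peak_arclength < 0 | peak_arclength > L)) {
    abort("peak arclength outside the contour", class = "afmdna_invalid_input")
  }
  100 * pmin(peak_arclength, L - peak_arclength) / L
}

#' Measure the DNA bend angle at a bound complex
#'
#' Fits straight lines (principal directions) to the contour over the two arm
#' windows `[s - arm, s)` and `(s, s + arm]` flanking the complex and reports
#' the deflection from collinearity: 180 deg minus the angle between the two
#' outward arm directions, so collinear arms give 0 deg (straight DNA).
#'
#' @param trace An `afm_trace`.
#' @param peak_arclength Complex arclength in nm.
#' @param arm_length_nm Arm window length per side in nm (default 10).
#' @param gap_nm Offset of the arm windows from the peak in nm (default 4 on
#'   traced images, where the skeleton through the protein blob itself is
#'   rounded; use 0 for geometric polylines).
#' @param step_nm Arm resampling step in nm.
#' @return Bend angle in degrees, or `NA` if the complex lies within
#'   `gap_nm + arm_length_nm` of a DNA end (geometrically undefined there).
#' @export
measure_bend_angle <- function(trace, peak_arclength, arm_length_nm = 10,
                               gap_nm = 4, step_nm = 0.5) {
  L <- attr(trace, "contour_length")
  reach <- gap_nm + arm_length_nm
  if (peak_arclength < reach || peak_arclength > L - reach) {
    return(NA_real_)
  }
  arm_dir <- function(s_from, s_to) {
    s <- seq(s_from, s_to, by = step_nm * sign(s_to - s_from))
    xs <- approx(trace$arclength, trace$x, xout = s)$y
    ys <- approx(trace$arclength, trace$y, xout = s)$y
    pc <- prcomp(cbind(xs, ys), center = TRUE)
    v <- pc$rotation[, 1]
    # orient away from the peak: from first (near-peak) to last sample
    away <- c(xs[length(xs)] - xs[1], ys[length(ys)] - ys[1])
    if (sum(v * away) < 0) v <- -v
    v
  }
  gap <- max(gap_nm, 0.5)
  v1 <- arm_dir(peak_arclength - gap, peak_arclength - reach)
  v2 <- arm_dir(peak_arclength + gap, peak_arclength + reach)
  # v1, v2 point outward; straight DNA has v1 antiparallel to v2
  cosang <- max(-1, min(1, sum(v1 * v2)))
  180 - acos(cosang) * 180 / pi
}

#' Measure the volume of a complex from the topograph
#'
#' Integrates height above local background around the peak. The footprint at
#' half the peak prominence (connected pixels above background + prominence/2)
#' sets the blob scale: its area gives an effective Gaussian width
#' `sigma = sqrt(area / (2 pi ln 2))`, and the volume is the sum of
#' (height - background) over the disk of radius `3 sigma`, which holds 98.9%
#' of a Gaussian blob's integral. The local background is the median height
#' of an annulus well outside that disk. Gaussian tip convolution conserves
#' the integral, so the measurement is insensitive to blur. The map should be
#' noiseless or pre-smoothed; on a raw noisy map the summed pixel noise adds
#' variance but no bias.
#'
#' For complexes bound on DNA the disk also contains DNA ridge material; when
#' `ridge_lambda` (ridge volume per nm of contour, measured on bare stretches
#' of the molecule) is supplied, the ridge contribution over the disk
#' diameter is subtracted.
#'
#' @param map The flattened `height_map`.
#' @param peak_xy Numeric length-2: complex centre (nm).
#' @param other_peaks_xy Optional matrix of other detected peak centres (nm);
#'   if the footprint reaches one, the measurement is flagged ambiguous.
#' @param window_nm Half-size of the analysis window around the peak.
#' @param ridge_lambda DNA ridge volume per contour length (nm^3/nm), or 0
#'   for an isolated blob.
#' @param exclude_xy Optional n x 2 matrix of points (nm) marking the DNA
#'   path; background-ring pixels within `exclude_radius_nm` of any of them
#'   are not used for the background estimate.
#' @param exclude_radius_nm Exclusion radius around `exclude_xy` (default 6).
#' @return A tibble with one row: `volume_nm3`, `max_height_nm`,
#'   `background_nm`, `footprint_px`, `ambiguous`.
#' @export
measure_volume <- function(map, peak_xy, other_peaks_xy = NULL,
                           window_nm = 40, ridge_lambda = 0,
                           exclude_xy = NULL, exclude_radius_nm = 6) {
  m <- unclass(map)
  px <- pixel_size(map)
  nr <- nrow(m); nc <- ncol(m)
  ci <- as.integer(round(peak_xy[2] / px + 0.5))
  cj <- as.integer(round(peak_xy[1] / px + 0.5))
  r <- as.integer(ceiling(window_nm / px))
  ii <- max(1L, ci - r):min(nr, ci + r)
  jj <- max(1L, cj - r):min(nc, cj + r)
  w <- m[ii, jj, drop = FALSE]
  # snap to the local maximum near the nominal centre
  li <- ci - ii[1] + 1L; lj <- cj - jj[1] + 1L
  s_ii <- max(1L, li - 2L):min(nrow(w), li + 2L)
  s_jj <- max(1L, lj - 2L):min(ncol(w), lj + 2L)
  sub <- w[s_ii, s_jj, drop = FALSE]
  amax <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  li <- s_ii[amax[1]]; lj <- s_jj[amax[2]]
  peak_h <- w[li, lj]

  # pixel distances from the (snapped) peak
  dist_px <- sqrt(outer((seq_len(nrow(w)) - li)^2,
                        (seq_len(ncol(w)) - lj)^2, "+"))

  bg <- 0
  footprint <- NULL
  for (iter in 1:2) {
    thr <- bg + 0.5 * (peak_h - bg)
    lab <- EBImage::bwlabel(w > thr)
    id <- lab[li, lj]
    if (id == 0) break
    footprint <- lab == id
    # background annulus well clear of the blob: the tail of a half-max
    # footprint still carries weight for several sigma
    ring_out <- EBImage::dilate(footprint, EBImage::makeBrush(19, "box"))
    ring_in <- EBImage::dilate(footprint, EBImage::makeBrush(11, "box"))
    ann <- ring_out & !ring_in
    if (sum(ann) >= 8) bg <- median(w[ann])
  }
  if (is.null(footprint) || peak_h <= bg) {
    return(tibble::tibble(volume_nm3 = 0, max_height_nm = peak_h,
                          background_nm = bg, footprint_px = 0L,
                          ambiguous = FALSE))
  }
  sigma_px <- sqrt(sum(footprint) / (2 * pi * log(2)))
  r_int <- 3 * sigma_px
  disk <- dist_px <= r_int
  # final background from a ring just outside the integration disk, where
  # the blob tail is negligible; pixels on the DNA path would shift the
  # median and are excluded when the path is known
  ring <- dist_px > r_int + 1 & dist_px <= r_int + 5
  if (!is.null(exclude_xy) && any(ring)) {
    rg <- which(ring, arr.ind = TRUE)
    gx <- (rg[, 2] + jj[1] - 1 - 0.5) * px
    gy <- (rg[, 1] + ii[1] - 1 - 0.5) * px
    d2 <- outer(gx, exclude_xy[, 1], "-")^2 + outer(gy, exclude_xy[, 2], "-")^2
    near <- apply(d2, 1, min) < exclude_radius_nm^2
    ring[ring] <- !near
  }
  if (sum(ring) >= 16) bg <- median(w[ring])
  vol <- sum(w[disk] - bg) * px^2
  if (ridge_lambda > 0) {
    vol <- vol - ridge_lambda * 2 * r_int * px
  }
  vol <- max(0, vol)

  ambiguous <- FALSE
  if (!is.null(other_peaks_xy) && length(other_peaks_xy) > 0) {
    op <- matrix(other_peaks_xy, ncol = 2)
    oi <- as.integer(round(op[, 2] / px + 0.5)) - ii[1] + 1L
    oj <- as.integer(round(op[, 1] / px + 0.5)) - jj[1] + 1L
    inside <- oi >= 1 & oi <= nrow(w) & oj >= 1 & oj <= ncol(w)
    if (any(inside)) {
      ambiguous <- any(dist_px[cbind(oi[inside], oj[inside])] <= r_int + 2)
    }
  }
  tibble::tibble(volume_nm3 = vol, max_height_nm = peak_h,
                 background_nm = bg, footprint_px = sum(footprint),
                 ambiguous = ambiguous)
}

#' Classify a complex as quantum-dot labelled by its height
#'
#' QD-labelled complexes image much taller (~4.5 nm) than bare protein
#' complexes (~1.5 nm); the selection criterion is a maximum height of at
#' least `cutoff_nm` (boundary inclusive).
#'
#' @param max_height_nm Measured maximum height(s) in nm.
#' @param cutoff_nm Height cutoff in nm (default 3).
#' @return Logical vector: `TRUE` for QD-labelled.
#' @examples
#' classify_qd(c(1.5, 3, 4.5))
#' @export
classify_qd <- function(max_height_nm, cutoff_nm = 3) {
  max_height_nm >= cutoff_nm
}

# ridge volume per nm of contour, from perpendicular integration of the
# height profile at probe points well away from any detected peak
ridge_line_density <- function(map, trace, peak_arclengths,
                               clear_nm = 15, half_nm = 8, n_probe = 7) {
  L <- attr(trace, "contour_length")
  s_cand <- seq(10, L - 10, length.out = 50)
  if (length(peak_arclengths) > 0) {
    dmin <- vapply(s_cand, function(s) min(abs(s - peak_arclengths)),
                   numeric(1))
    s_cand <- s_cand[dmin > clear_nm]
  }
  if (length(s_cand) == 0) return(0)
  s_cand <- s_cand[round(seq(1, length(s_cand), length.out =
                               min(n_probe, length(s_cand))))]
  lam <- vapply(s_cand, function(s0) {
    p <- chain_point_at_trace(trace, s0)
    nrm <- c(-p$tangent[2], p$tangent[1])
    d <- seq(-half_nm, half_nm, by = 0.5)
    h <- interp_height(map, p$x + d * nrm[1], p$y + d * nrm[2])
    sum(h, na.rm = TRUE) * 0.5
  }, numeric(1))
  max(0, median(lam))
}

# point + tangent on a trace at a given arclength
chain_point_at_trace <- function(trace, s) {
  x <- approx(trace$arclength, trace$x, xout = s)$y
  y <- approx(trace$arclength, trace$y, xout = s)$y
  eps <- 1
  x2 <- approx(trace$arclength, trace$x, xout = min(s + eps,
               attr(trace, "contour_length")))$y
  y2 <- approx(trace$arclength, trace$y, xout = min(s + eps,
               attr(trace, "contour_length")))$y
  v <- c(x2 - x, y2 - y)
  nv <- sqrt(sum(v^2))
  list(x = x, y = y, tangent = if (nv > 0) v / nv else c(1, 0))
}

#' Measure all complexes on the ok traces of a scene
#'
#' Runs [detect_complexes()], [fractional_position()],
#' [measure_bend_angle()], [measure_volume()] and [classify_qd()] over every
#' `ok` trace and assembles the shared per-complex measurement table.
#'
#' @param map The flattened `height_map`.
#' @param traces Tibble from [trace_molecules()].
#' @param min_peak_height_nm,arm_length_nm,qd_cutoff_nm Measurement
#'   parameters; see the underlying functions.
#' @param smooth_sigma_nm Matched-filter smoothing (nm) used for detection
#'   and volume integration; max heights are always read off the unsmoothed
#'   map.
#' @param condition,replicate Labels recorded in the table.
#' @return A measurement tibble in the shared schema (see
#'   [validate_measurements()]), with attribute `n_dna` = number of ok
#'   traces.
#' @export
measure_scene <- function(map, traces, min_peak_height_nm = 0.4,
                          arm_length_nm = 10, qd_cutoff_nm = 3,
                          smooth_sigma_nm = 2,
                          condition = "image", replicate = "r1") {
  px <- pixel_size(map)
  smoothed <- if (smooth_sigma_nm > 0) {
    height_map(gaussian_blur(unclass(map), smooth_sigma_nm / px), px)
  } else map
  raw <- unclass(map)
  ok <- traces[traces$qc_status == "ok", ]
  rows <- purrr::pmap(list(ok$molecule_id, ok$trace), function(id, tr) {
    peaks <- detect_complexes(tr, smoothed, min_peak_height_nm,
                              smooth_sigma_nm = 0)
    if (nrow(peaks) == 0) return(NULL)
    peak_xy <- cbind(approx(tr$arclength, tr$x, xout = peaks$arclength)$y,
                     approx(tr$arclength, tr$y, xout = peaks$arclength)$y)
    lambda <- ridge_line_density(smoothed, tr, peaks$arclength)
    s_path <- seq(0, attr(tr, "contour_length"), by = 2)
    path_xy <- cbind(approx(tr$arclength, tr$x, xout = s_path)$y,
                     approx(tr$arclength, tr$y, xout = s_path)$y)
    purrr::map_dfr(seq_len(nrow(peaks)), function(k) {
      vol <- measure_volume(smoothed, peak_xy[k, ],
                            other_peaks_xy = peak_xy[-k, , drop = FALSE],
                            ridge_lambda = lambda, exclude_xy = path_xy)
      # max height from the unsmoothed map: QD/protein height contrast must
      # not be attenuated by the matched filter
      ci <- as.integer(round(peak_xy[k, 2] / px + 0.5))
      cj <- as.integer(round(peak_xy[k, 1] / px + 0.5))
      ii <- max(1L, ci - 2L):min(nrow(raw), ci + 2L)
      jj <- max(1L, cj - 2L):min(ncol(raw), cj + 2L)
      hmax <- max(raw[ii, jj])
      tibble::tibble(
        molecule_id = id,
        position_pct_folded = fractional_position(tr, peaks$arclength[k]),
        bend_angle_deg = measure_bend_angle(tr, peaks$arclength[k],
                                            arm_length_nm),
        volume_nm3 = vol$volume_nm3,
        max_height_nm = hmax,
        is_qd = classify_qd(hmax, qd_cutoff_nm),
        condition = condition,
        replicate = replicate,
        ambiguous = vol$ambiguous
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      molecule_id = integer(), position_pct_folded = numeric(),
      bend_angle_deg = numeric(), volume_nm3 = numeric(),
      max_height_nm = numeric(), is_qd = logical(),
      condition = character(), replicate = character(), ambiguous = logical()
    )
  }
  attr(out, "n_dna") <- sum(traces$qc_status == "ok")
  out
}
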