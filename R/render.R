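#' Construct a height map
#'
#' A height map is a plain numeric matrix of surface heights in nm (rows = y,
#' columns = x; pixel (i, j) is centred at ((j - 0.5) px, (i - 0.5) px)) with
#' the pixel size attached.
#'
#' @param grid Numeric matrix of heights in nm (finite values).
#' @param pixel_size_nm Pixel edge length in nm.
#' @return An object of class `height_map`.
#' @export
height_map <- function(grid, pixel_size_nm) {
  stopifnot(is.matrix(grid), is.numeric(grid))
  if (!all(is.finite(grid))) {
    abort("height map values must be finite", class = "afmdna_invalid_input")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("pixel_size_nm must be positive", class = "afmdna_invalid_input")
  }
  structure(grid, pixel_size_nm = pixel_size_nm, class = c("height_map", "matrix", "array"))
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px at %g nm/px, heights %.3g..%.3g nm\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), min(x), max(x)))
  invisible(x)
}

pixel_size <- function(map) attr(map, "pixel_size_nm")

#' Separable Gaussian blur with replicate padding
#'
#' Used as the tip-broadening forward model. Replicate padding keeps the
#' integrated volume of features away from grid edges conserved.
#'
#' @param mat Numeric matrix.
#' @param sigma_px Gaussian sd in pixels; 0 returns the input unchanged.
#' @return Blurred matrix of the same size.
#' @keywords internal
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- as.integer(ceiling(4 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  blur_1d <- function(m) {  # along columns (i.e. down rows)
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(mat))))
}

# stamp max-composited Gaussian ridge contributions for a set of points
stamp_ridge <- function(grid, xs, ys, height, sigma_px, px) {
  nr <- nrow(grid); nc <- ncol(grid)
  r <- as.integer(ceiling(3 * sigma_px))
  offs <- expand.grid(di = -r:r, dj = -r:r)
  cj <- xs / px + 0.5  # fractional pixel coords (column)
  ci <- ys / px + 0.5
  j0 <- rep(round(cj), each = nrow(offs)) + offs$dj
  i0 <- rep(round(ci), each = nrow(offs)) + offs$di
  dx <- (j0 - 0.5) - rep(cj, each = nrow(offs))
  dy <- (i0 - 0.5) - rep(ci, each = nrow(offs))
  val <- height * exp(-(dx^2 + dy^2) / (2 * sigma_px^2))
  keep <- i0 >= 1L & i0 <= nr & j0 >= 1L & j0 <= nc
  if (!any(keep)) return(grid)
  idx <- i0[keep] + (j0[keep] - 1L) * nr
  val <- val[keep]
  o <- order(idx, -val)
  idx <- idx[o]; val <- val[o]
  first <- !duplicated(idx)
  idx <- idx[first]; val <- val[first]
  grid[idx] <- pmax(grid[idx], val)
  grid
}

#' Render a synthetic AFM scene
#'
#' Forward model for an AFM topograph of deposited DNA-protein samples: each
#' chain is drawn as a ridge of constant height `dna_height_nm` with Gaussian
#' cross-section; each complex as a 2D Gaussian blob whose integrated
#' (height x pixel area) volume equals its `volume_true` before tip
#' convolution, peaking at `qd_height_nm` for QD-labelled complexes and
#' `protein_height_nm` otherwise. Tip broadening is applied as an isotropic
#' Gaussian blur of sd `tip_sigma_nm`, then additive Gaussian pixel noise of
#' sd `noise_sd_nm`.
#'
#' @param chains List of `wlc_chain` objects already positioned in scene
#'   coordinates (nm), indexed by molecule id.
#' @param complexes Tibble as from [place_complexes()]; positions are resolved
#'   to coordinates along the corresponding chain. A complex whose resolved
#'   centre falls outside the grid raises a placement error.
#' @param config An [afm_config()].
#' @param seed Optional seed for the pixel noise.
#' @return An `afm_scene`: list with `height_map`, `truth` (per-complex
#'   ground-truth tibble with scene coordinates) and `molecules` (per-molecule
#'   records).
#' @export
render_scene <- function(chains, complexes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- config$pixel_size_nm
  n <- config$scene_px
  grid <- matrix(0, n, n)
  sigma_dna_px <- config$dna_width_sigma_nm / px

  for (ch in chains) {
    step <- 0.25 * px
    s <- seq(0, attr(ch, "contour_length"), by = step)
    pts_x <- approx(ch$arclength, ch$x, xout = s)$y
    pts_y <- approx(ch$arclength, ch$y, xout = s)$y
    grid <- stamp_ridge(grid, pts_x, pts_y, config$dna_height_nm,
                        sigma_dna_px, px)
  }

  truth <- complexes
  if (nrow(truth) > 0) {
    coords <- purrr::map(seq_len(nrow(truth)), function(i) {
      ch <- chains[[truth$molecule_id[i]]]
      p <- chain_point_at(ch, truth$position_fraction[i] *
                            attr(ch, "contour_length"))
      c(p$x, p$y)
    })
    truth$x <- purrr::map_dbl(coords, 1)
    truth$y <- purrr::map_dbl(coords, 2)
    field_nm <- n * px
    if (any(truth$x < 0 | truth$x > field_nm | truth$y < 0 | truth$y > field_nm)) {
      abort("complex placed off-grid", class = "afmdna_placement_error")
    }
    blob <- matrix(0, n, n)
    for (i in seq_len(nrow(truth))) {
      # the configured height is the composite (blob on DNA) peak height, so
      # the blob amplitude is reduced by the ridge height underneath; sigma
      # then follows from the volume
      h <- max(truth$height_true[i] - config$dna_height_nm,
               0.25 * truth$height_true[i])
      sig_nm <- sqrt(truth$volume_true[i] / (2 * pi * h))
      sig_px <- sig_nm / px
      r <- as.integer(ceiling(4 * sig_px))
      cj <- truth$x[i] / px + 0.5
      ci <- truth$y[i] / px + 0.5
      jj <- max(1L, round(cj) - r):min(n, round(cj) + r)
      ii <- max(1L, round(ci) - r):min(n, round(ci) + r)
      dx <- outer(rep(1, length(ii)), (jj - 0.5) - cj)
      dy <- outer((ii - 0.5) - ci, rep(1, length(jj)))
      blob[ii, jj] <- blob[ii, jj] + h * exp(-(dx^2 + dy^2) / (2 * sig_px^2))
    }
    # complexes sit on top of the DNA: heights add (the analysis subtracts
    # the ridge contribution when measuring volumes)
    grid <- grid + blob
  }

  grid <- gaussian_blur(grid, config$tip_sigma_nm / px)
  if (config$noise_sd_nm > 0) {
    grid <- grid + matrix(rnorm(n * n, 0, config$noise_sd_nm), n, n)
  }

  molecules <- scene_molecule_records(chains, config)
  structure(
    list(height_map = height_map(grid, px), truth = truth,
         molecules = molecules, config = config),
    class = "afm_scene"
  )
}

# distance below which two DNA backbones are unresolvable in the rendered
# image: at the midpoint between two parallel ridges both tip-broadened
# (and matched-filter smoothed) cross-sections add, so they merge into one
# segmented region when 2 * tail(g / 2) still exceeds the noiseless
# segmentation floor of 0.05 nm
resolvability_clearance <- function(config, analysis_smooth_nm = 2,
                                    floor_nm = 0.05) {
  sig2 <- config$dna_width_sigma_nm^2 + config$tip_sigma_nm^2 +
    analysis_smooth_nm^2
  ridge_vis <- config$dna_height_nm * config$dna_width_sigma_nm / sqrt(sig2)
  if (2 * ridge_vis <= floor_nm) return(2 * sqrt(sig2))
  2 * sqrt(2 * sig2 * log(2 * ridge_vis / floor_nm))
}

# per-molecule ground truth: border contact and overlap (with another
# molecule, or of a molecule with its own distant segments) at the imaging
# resolution limit
scene_molecule_records <- function(chains, config, border_nm = 8) {
  clearance_nm <- resolvability_clearance(config)
  field_nm <- config$scene_px * config$pixel_size_nm
  step_nm <- 2
  sub <- purrr::map(chains, function(ch) {
    k <- max(1L, as.integer(round(step_nm / attr(ch, "segment_length"))))
    idx <- seq(1, nrow(ch), by = k)
    cbind(ch$x[idx], ch$y[idx], ch$arclength[idx])
  })
  n <- length(chains)
  touches <- purrr::map_lgl(sub, function(p) {
    any(p[, 1] < border_nm | p[, 1] > field_nm - border_nm |
          p[, 2] < border_nm | p[, 2] > field_nm - border_nm)
  })
  # self-contact: non-adjacent stretches of the same chain closer than the
  # clearance image as loops or branches
  overlaps <- purrr::map_lgl(sub, function(p) {
    d2 <- outer(p[, 1], p[, 1], "-")^2 + outer(p[, 2], p[, 2], "-")^2
    ds <- abs(outer(p[, 3], p[, 3], "-"))
    any(d2 < clearance_nm^2 & ds > 25)
  })
  if (n > 1) {
    bb <- purrr::map(sub, function(p) c(range(p[, 1]), range(p[, 2])))
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (bb[[a]][1] > bb[[b]][2] + clearance_nm ||
            bb[[b]][1] > bb[[a]][2] + clearance_nm ||
            bb[[a]][3] > bb[[b]][4] + clearance_nm ||
            bb[[b]][3] > bb[[a]][4] + clearance_nm) next
        d2 <- outer(sub[[a]][, 1], sub[[b]][, 1], "-")^2 +
          outer(sub[[a]][, 2], sub[[b]][, 2], "-")^2
        if (min(d2) < clearance_nm^2) overlaps[a] <- overlaps[b] <- TRUE
      }
    }
  }
  tibble::tibble(
    molecule_id = seq_len(n),
    contour_length_nm = purrr::map_dbl(chains, ~ attr(.x, "contour_length")),
    touches_border = touches,
    overlaps = overlaps
  )
}

#' @export
print.afm_scene <- function(x, ...) {
  cat(sprintf("<afm_scene> %d molecules, %d complexes\n",
              nrow(x$molecules), nrow(x$truth)))
  print(x$height_map)
  invisible(x)
}

#' Simulate one rendered AFM scene
#'
#' Samples `molecules_per_scene` worm-like chains, places binding events on
#' them, locally straightens each chain over the protein footprint and imposes
#' the drawn bend-state angle at the binding node (bound proteins clamp the
#' DNA locally), deposits the molecules at random positions/orientations in
#' the field, and renders the topograph.
#'
#' @param config An [afm_config()].
#' @param seed Integer seed (defaults to `config$seed`); fully determines the
#'   scene.
#' @param n_molecules Number of molecules in this scene (defaults to
#'   `config$molecules_per_scene`).
#' @return An `afm_scene` (see [render_scene()]); `truth` additionally holds
#'   `position_pct_folded_true`.
#' @examples
#' sc <- simulate_scene(afm_config(molecules_per_scene = 3, seed = 7))
#' sc$molecules
#' @export
simulate_scene <- function(config, seed = config$seed,
                           n_molecules = config$molecules_per_scene) {
  set.seed(seed)
  field_nm <- config$scene_px * config$pixel_size_nm
  margin <- min(110, field_nm / 4)
  complexes <- place_complexes(n_molecules, config)
  chains <- purrr::map(seq_len(n_molecules), function(id) {
    ch <- sample_wlc_chain(config)
    rows <- which(complexes$molecule_id == id)
    for (i in rows) {
      s <- complexes$position_fraction[i] * attr(ch, "contour_length")
      node <- chain_point_at(ch, s)$node
      node <- min(max(node, 2L), nrow(ch) - 1L)
      ch <- straighten_chain(ch, node)
      sign <- if (runif(1) < 0.5) -1 else 1
      ch <- impose_bend(ch, node, sign * complexes$bend_angle_true[i])
    }
    # deposit: centre at a uniform position, random in-plane rotation
    phi <- runif(1, 0, 2 * pi)
    cx <- mean(ch$x); cy <- mean(ch$y)
    xr <- cos(phi) * (ch$x - cx) - sin(phi) * (ch$y - cy)
    yr <- sin(phi) * (ch$x - cx) + cos(phi) * (ch$y - cy)
    tx <- runif(1, margin, field_nm - margin)
    ty <- runif(1, margin, field_nm - margin)
    new_wlc_chain(xr + tx, yr + ty, attr(ch, "segment_length"))
  })
  scene <- render_scene(chains, complexes, config)
  if (nrow(scene$truth) > 0) {
    scene$truth$position_pct_folded_true <-
      fold_position_pct(100 * scene$truth$position_fraction)
  }
  scene$chains <- chains
  scene$seed <- seed
  scene
}

#' Fold a percent position so the two DNA ends are interchangeable
#'
#' AFM cannot distinguish the two ends of the substrate, so positions are
#' reported as distance from the nearer end: `min(p, 100 - p)`, in `[0, 50]`.
#'
#' @param pct Numeric vector of positions in percent of DNA length, `[0, 100]`.
#' @return Folded positions in `[0, 50]`.
#' @export
fold_position_pct <- function(pct) pmin(pct, 100 - pct)

#' Write a height map to disk
#'
#' Writes three sibling files: `<stem>.tif` (32-bit float TIFF; values are
#' heights in nm divided by the recorded `height_scale_nm`), `<stem>.txt`
#' (whitespace-delimited plain-text matrix in nm) and `<stem>.yaml` (sidecar
#' with `pixel_size_nm`, `height_scale_nm` and optionally `seed`).
#'
#' @param map A `height_map` (or an `afm_scene`, whose map is written).
#' @param stem Output path without extension.
#' @param seed Optional seed to record in the sidecar.
#' @return `stem`, invisibly.
#' @export
write_height_map <- function(map, stem, seed = NULL) {
  if (inherits(map, "afm_scene")) {
    if (is.null(seed)) seed <- map$seed
    map <- map$height_map
  }
  # float TIFF storage is defined for [0, 1]: record an affine transform
  offset <- min(map)
  scale <- max(1, 2^ceiling(log2(max(max(map) - offset, 1e-9))))
  m <- (unclass(map) - offset) / scale
  tiff::writeTIFF(m, paste0(stem, ".tif"), bits.per.sample = 32L)
  write(t(unclass(map)), file = paste0(stem, ".txt"), ncolumns = ncol(map))
  side <- list(pixel_size_nm = pixel_size(map), height_scale_nm = scale,
               height_offset_nm = offset)
  if (!is.null(seed)) side$seed <- as.integer(seed)
  yaml::write_yaml(side, paste0(stem, ".yaml"))
  invisible(stem)
}

#' Read a height map written by [write_height_map()]
#'
#' @param path Path to a `.tif` or `.txt` height-map file, or the bare stem.
#' @param pixel_size_nm Pixel size override if no sidecar is present.
#' @return A `height_map` with values in nm.
#' @export
read_height_map <- function(path, pixel_size_nm = NULL) {
  stem <- sub("\\.(tif|tiff|txt)$", "", path)
  side_path <- paste0(stem, ".yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  px <- pixel_size_nm %||% side$pixel_size_nm
  if (is.null(px)) {
    abort("pixel size not given and no sidecar found",
          class = "afmdna_invalid_input")
  }
  tif <- paste0(stem, ".tif")
  txt <- paste0(stem, ".txt")
  use_tif <- grepl("\\.tiff?$", path) || (!grepl("\\.txt$", path) && file.exists(tif))
  if (use_tif && file.exists(tif)) {
    m <- tiff::readTIFF(tif) * (side$height_scale_nm %||% 1) +
      (side$height_offset_nm %||% 0)
  } else {
    m <- as.matrix(utils::read.table(txt))
    dimnames(m) <- NULL
  }
  height_map(m, px)
}
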