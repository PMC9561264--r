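#' Place bound complexes on a set of DNA chains
#'
#' Draws the ground-truth binding events the analysis must later recover: per
#' molecule, one specific-site event with probability `occupancy_specific`
#' (positioned at `site_fraction` with Gaussian jitter of sd
#' `site_jitter_fraction` of the contour, emulating finite localisation
#' precision) plus a Poisson(`nonspecific_rate`) number of nonspecific events
#' uniform on the contour. Each event receives a bend-angle state drawn from
#' the configured Gaussian mixture, a volume, a QD flag, and a nominal peak
#' height.
#'
#' @param n_molecules Number of molecules to populate (molecule ids `1:n`).
#' @param config An [afm_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per placed complex: `molecule_id`,
#'   `position_fraction` (unfolded, in `[0, 1]`), `kind`
#'   (`"specific"`/`"nonspecific"`), `bend_angle_true` (deg, magnitude),
#'   `volume_true` (nm^3), `height_true` (nm), `is_qd`.
#' @examples
#' place_complexes(5, afm_config(occupancy_specific = 1), seed = 1)
#' @export
place_complexes <- function(n_molecules, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$occupancy_specific < 0 || config$nonspecific_rate < 0) {
    abort("binding rates must be non-negative", class = "afmdna_invalid_config")
  }
  rows <- purrr::map(seq_len(n_molecules), function(id) {
    pos <- numeric(0)
    kind <- character(0)
    if (rbinom(1, 1, min(1, config$occupancy_specific)) == 1) {
      p <- config$site_fraction + rnorm(1, 0, config$site_jitter_fraction)
      pos <- c(pos, min(max(p, 0), 1))
      kind <- c(kind, "specific")
    }
    if (!is.null(config$second_site_fraction) &&
        rbinom(1, 1, min(1, config$occupancy_specific)) == 1) {
      p <- config$second_site_fraction + rnorm(1, 0, config$site_jitter_fraction)
      pos <- c(pos, min(max(p, 0), 1))
      kind <- c(kind, "specific2")
    }
    n_nsp <- rpois(1, config$nonspecific_rate)
    if (n_nsp > 0) {
      pos <- c(pos, runif(n_nsp))
      kind <- c(kind, rep("nonspecific", n_nsp))
    }
    if (length(pos) == 0) return(NULL)
    tibble::tibble(molecule_id = id, position_fraction = pos, kind = kind)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      molecule_id = integer(), position_fraction = numeric(),
      kind = character(), bend_angle_true = numeric(),
      volume_true = numeric(), height_true = numeric(), is_qd = logical()
    ))
  }
  n <- nrow(out)
  state <- sample.int(length(config$bend_state_means), n, replace = TRUE,
                      prob = config$bend_state_weights)
  out$bend_angle_true <- abs(config$bend_state_means[state] +
                               rnorm(n, 0, config$bend_state_sd))
  out$is_qd <- runif(n) < config$qd_probability
  out$volume_true <- ifelse(
    out$is_qd,
    config$qd_volume_nm3,
    pmax(10, config$protein_volume_nm3 + rnorm(n, 0, config$volume_sd_nm3))
  )
  out$height_true <- ifelse(out$is_qd, config$qd_height_nm,
                            config$protein_height_nm)
  out
}
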