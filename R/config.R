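#' Configuration for the synthetic AFM scene generator
#'
#' Bundles every parameter of the forward model: DNA geometry (a 505 bp
#' fragment deposited on mica, modelled as a 2D-equilibrated worm-like chain),
#' the specific binding site (an oxoG lesion at 49.8% of the contour, with an
#' optional second site such as an E-box at 51.8%), per-molecule occupancy of
#' the specific site and a uniform nonspecific background, the discrete DNA
#' bend-angle states adopted by bound complexes, blob geometry for rendering
#' protein and quantum-dot (QD) labelled complexes, and the imaging model
#' (pixel size, Gaussian tip broadening, additive height noise).
#'
#' @param n_molecules Number of DNA molecules to simulate.
#' @param dna_length_bp DNA substrate length in base pairs (default 505).
#' @param rise_per_bp Helical rise in nm per base pair (default 0.34), so the
#'   default contour length is 171.7 nm.
#' @param persistence_length Worm-like chain persistence length in nm
#'   (default 50, double-stranded DNA).
#' @param segment_length Target discretisation step of the chain in nm; the
#'   actual step is contour_length / round(contour_length / segment_length) so
#'   that the contour length is exact.
#' @param site_fraction Fractional position of the specific site along the
#'   contour (default 0.498).
#' @param second_site_fraction Optional fractional position of a second site
#'   (e.g. 0.518); `NULL` to disable.
#' @param occupancy_specific Expected specific-site binding events per DNA
#'   (Bernoulli per molecule).
#' @param nonspecific_rate Expected nonspecific events per DNA, placed
#'   uniformly along the contour (Poisson per molecule).
#' @param site_jitter_fraction Gaussian sd of specific-site positional jitter,
#'   as a fraction of contour length (default 0.015), emulating finite
#'   localisation precision.
#' @param bend_state_means Means (deg) of the discrete DNA bend-angle states
#'   at bound complexes (default c(0, 35, 70)).
#' @param bend_state_weights Mixture weights of the bend states; must sum to 1.
#' @param bend_state_sd Within-state Gaussian sd in degrees (default 8).
#' @param protein_volume_nm3 Rendered/emitted protein complex volume in nm^3.
#' @param volume_sd_nm3 Gaussian sd of per-complex volume in nm^3.
#' @param protein_height_nm Peak height of unlabelled protein blobs in nm
#'   (default 1.5).
#' @param qd_height_nm Peak height of QD-labelled blobs in nm (default 4.5).
#' @param qd_volume_nm3 Rendered QD blob volume in nm^3 (default 700; a
#'   QD-antibody sandwich is much larger than a bare protein).
#' @param qd_probability Probability that a complex carries a QD label.
#' @param dna_height_nm Rendered DNA ridge height in nm (default 0.5).
#' @param dna_width_sigma_nm Gaussian cross-section sd of the DNA ridge in nm.
#' @param pixel_size_nm Image pixel size in nm (default 2).
#' @param scene_px Square scene edge length in pixels (default 512).
#' @param molecules_per_scene Molecules deposited per rendered scene
#'   (default 10).
#' @param tip_sigma_nm Isotropic Gaussian tip-broadening sd in nm (default 3).
#' @param noise_sd_nm Additive Gaussian pixel noise sd in nm (default 0.1). In
#'   tabular mode this sd also perturbs the emitted per-complex max heights.
#' @param seed Integer seed; together with the config it fully determines all
#'   generated scenes and tables.
#'
#' @return An object of class `afm_config` (a named list, validated).
#' @examples
#' cfg <- afm_config(n_molecules = 10, seed = 1)
#' cfg$contour_length_nm
#' @export
afm_config <- function(n_molecules = 100,
                       dna_length_bp = 505,
                       rise_per_bp = 0.34,
                       persistence_length = 50,
                       segment_length = 1,
                       site_fraction = 0.498,
                       second_site_fraction = NULL,
                       occupancy_specific = 0.18,
                       nonspecific_rate = 0.5,
                       site_jitter_fraction = 0.015,
                       bend_state_means = c(0, 35, 70),
                       bend_state_weights = c(0.3, 0.4, 0.3),
                       bend_state_sd = 8,
                       protein_volume_nm3 = 100,
                       volume_sd_nm3 = 15,
                       protein_height_nm = 1.5,
                       qd_height_nm = 4.5,
                       qd_volume_nm3 = 700,
                       qd_probability = 0,
                       dna_height_nm = 0.5,
                       dna_width_sigma_nm = 1.6,
                       pixel_size_nm = 2,
                       scene_px = 512,
                       molecules_per_scene = 10,
                       tip_sigma_nm = 3,
                       noise_sd_nm = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_molecules = as.integer(n_molecules),
    dna_length_bp = as.integer(dna_length_bp),
    rise_per_bp = rise_per_bp,
    persistence_length = persistence_length,
    segment_length = segment_length,
    site_fraction = site_fraction,
    second_site_fraction = second_site_fraction,
    occupancy_specific = occupancy_specific,
    nonspecific_rate = nonspecific_rate,
    site_jitter_fraction = site_jitter_fraction,
    bend_state_means = bend_state_means,
    bend_state_weights = bend_state_weights,
    bend_state_sd = bend_state_sd,
    protein_volume_nm3 = protein_volume_nm3,
    volume_sd_nm3 = volume_sd_nm3,
    protein_height_nm = protein_height_nm,
    qd_height_nm = qd_height_nm,
    qd_volume_nm3 = qd_volume_nm3,
    qd_probability = qd_probability,
    dna_height_nm = dna_height_nm,
    dna_width_sigma_nm = dna_width_sigma_nm,
    pixel_size_nm = pixel_size_nm,
    scene_px = as.integer(scene_px),
    molecules_per_scene = as.integer(molecules_per_scene),
    tip_sigma_nm = tip_sigma_nm,
    noise_sd_nm = noise_sd_nm,
    seed = as.integer(seed)
  )
  cfg$contour_length_nm <- cfg$dna_length_bp * cfg$rise_per_bp
  validate_afm_config(cfg)
  structure(cfg, class = "afm_config")
}

validate_afm_config <- function(cfg) {
  chk_pos <- function(name) {
    if (!is.numeric(cfg[[name]]) || length(cfg[[name]]) != 1 ||
        !is.finite(cfg[[name]]) || cfg[[name]] <= 0) {
      abort(sprintf("invalid config: `%s` must be a single positive number", name),
            class = "afmdna_invalid_config")
    }
  }
  for (nm in c("dna_length_bp", "rise_per_bp", "persistence_length",
               "segment_length", "protein_volume_nm3", "protein_height_nm",
               "qd_height_nm", "qd_volume_nm3", "dna_height_nm",
               "dna_width_sigma_nm", "pixel_size_nm", "scene_px")) {
    chk_pos(nm)
  }
  chk_frac <- function(name) {
    v <- cfg[[name]]
    if (is.null(v)) return(invisible())
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      abort(sprintf("invalid config: `%s` must lie in [0, 1]", name),
            class = "afmdna_invalid_config")
    }
  }
  for (nm in c("site_fraction", "second_site_fraction", "qd_probability",
               "site_jitter_fraction")) {
    chk_frac(nm)
  }
  if (cfg$n_molecules < 0 || cfg$occupancy_specific < 0 ||
      cfg$nonspecific_rate < 0 || cfg$noise_sd_nm < 0 || cfg$tip_sigma_nm < 0) {
    abort("invalid config: rates, noise and tip sigma must be non-negative",
          class = "afmdna_invalid_config")
  }
  w <- cfg$bend_state_weights
  if (length(w) != length(cfg$bend_state_means) ||
      abs(sum(w) - 1) > 1e-12 || any(w < 0)) {
    abort("invalid config: bend_state_weights must be non-negative and sum to 1 (within 1e-12)",
          class = "afmdna_invalid_config")
  }
  invisible(cfg)
}

#' @export
print.afm_config <- function(x, ...) {
  cat("<afm_config>\n")
  cat(sprintf("  DNA: %d bp x %.2f nm/bp = %.1f nm contour, P = %g nm\n",
              x$dna_length_bp, x$rise_per_bp, x$contour_length_nm,
              x$persistence_length))
  site2 <- if (is.null(x$second_site_fraction)) "none" else
    sprintf("%.1f%%", 100 * x$second_site_fraction)
  cat(sprintf("  sites: specific %.1f%% (jitter sd %.1f%%), second %s\n",
              100 * x$site_fraction, 100 * x$site_jitter_fraction, site2))
  cat(sprintf("  occupancy: %.3g specific/DNA, %.3g nonspecific/DNA\n",
              x$occupancy_specific, x$nonspecific_rate))
  cat(sprintf("  bend states: %s deg (weights %s, sd %g)\n",
              paste(x$bend_state_means, collapse = "/"),
              paste(x$bend_state_weights, collapse = "/"), x$bend_state_sd))
  cat(sprintf("  imaging: %g nm/px, %d px scene, tip sigma %g nm, noise %g nm\n",
              x$pixel_size_nm, x$scene_px, x$tip_sigma_nm, x$noise_sd_nm))
  cat(sprintf("  n_molecules = %d (%d per scene), seed = %d\n",
              x$n_molecules, x$molecules_per_scene, x$seed))
  invisible(x)
}
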