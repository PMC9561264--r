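#' Assemble a full pipeline run configuration
#'
#' Bundles the generator configuration with tracing, measurement and
#' statistics parameters and a replicate plan. Replicates are realised as
#' independent generator seeds (independent depositions); every random stage
#' receives a seed derived deterministically from the master seed.
#'
#' @param generator An [afm_config()].
#' @param conditions Optional named list of generator overrides, one entry
#'   per experimental condition (e.g. `list(reducing = list(
#'   occupancy_specific = 0.18), oxidising = list(occupancy_specific =
#'   0.10))`). `NULL` runs the generator as a single condition named
#'   `"default"`.
#' @param reference Name of the reference condition for significance stars
#'   (default: the first condition).
#' @param replicates Number of replicate depositions per condition
#'   (default 3).
#' @param mode `"image"` (render, trace, measure) or `"tabular"` (direct
#'   measurement sampling).
#' @param tracing,measurement,stats Parameter lists for the respective
#'   stages; missing entries take the stage defaults.
#' @param write_scenes Write every rendered height map (TIFF + text +
#'   sidecar) under the output directory.
#' @return Object of class `afm_run_config`.
#' @export
afm_run_config <- function(generator = afm_config(),
                           conditions = NULL,
                           reference = NULL,
                           replicates = 3,
                           mode = c("image", "tabular"),
                           tracing = list(),
                           measurement = list(),
                           stats = list(),
                           write_scenes = FALSE) {
  mode <- match.arg(mode)
  if (is.null(conditions)) conditions <- list(default = list())
  if (is.null(reference)) reference <- names(conditions)[1]
  tracing <- modifyList(list(flatten_order = 1, threshold_nm = NULL,
                             expected_length_nm = generator$contour_length_nm,
                             tolerance_fraction = 0.2, prune_nm = 6,
                             smooth_window = 7), tracing)
  measurement <- modifyList(list(min_peak_height_nm = 0.4, arm_length_nm = 10,
                                 qd_cutoff_nm = 3), measurement)
  stats <- modifyList(list(site_pct = 100 * min(generator$site_fraction,
                                                1 - generator$site_fraction),
                           n_sites = generator$dna_length_bp,
                           fit_bin_width = 2, occupancy_bin = c(45, 50)),
                      stats)
  structure(list(generator = generator, conditions = conditions,
                 reference = reference, replicates = as.integer(replicates),
                 mode = mode, tracing = tracing, measurement = measurement,
                 stats = stats, write_scenes = write_scenes),
            class = "afm_run_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic and kept below 2^31 so it is a valid R integer.
#' @param master Master seed (integer).
#' @param ... Integer stage indices.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 48271 + k) %% 2147483647
  as.integer(s)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file holds the same nested sections as [afm_run_config()]
#' (`generator`, `conditions`, `tracing`, `measurement`, `stats`,
#' `replicates`, `mode`, `reference`).
#'
#' @param path Path to the YAML configuration.
#' @return An `afm_run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(afm_config, y$generator %||% list())
  afm_run_config(
    generator = gen,
    conditions = y$conditions,
    reference = y$reference,
    replicates = y$replicates %||% 3,
    mode = y$mode %||% "image",
    tracing = y$tracing %||% list(),
    measurement = y$measurement %||% list(),
    stats = y$stats %||% list(),
    write_scenes = isTRUE(y$write_scenes)
  )
}

measure_one_replicate <- function(config, cond_name, cond_overrides,
                                  rep_index, seed, out_dir = NULL) {
  gen <- do.call(afm_config,
                 modifyList(config$generator[setdiff(names(config$generator),
                                                     "contour_length_nm")],
                            as.list(cond_overrides)))
  rep_label <- paste0("r", rep_index)
  if (config$mode == "tabular") {
    m <- simulate_measurements(gen, seed = seed, condition = cond_name,
                               replicate = rep_label)
    return(list(measurements = m, n_dna = attr(m, "n_dna"),
                rejects = tibble::tibble()))
  }
  n_scenes <- ceiling(gen$n_molecules / gen$molecules_per_scene)
  ms <- list(); rejects <- list(); n_dna <- 0L
  for (sc in seq_len(n_scenes)) {
    n_mol <- min(gen$molecules_per_scene,
                 gen$n_molecules - (sc - 1L) * gen$molecules_per_scene)
    scene <- simulate_scene(gen, seed = derive_seed(seed, sc), n_molecules = n_mol)
    if (isTRUE(config$write_scenes) && !is.null(out_dir)) {
      write_height_map(scene, file.path(out_dir, sprintf(
        "scene_%s_%s_%03d", cond_name, rep_label, sc)))
    }
    tr <- config$tracing
    map <- flatten(scene$height_map, tr$flatten_order)
    traces <- trace_molecules(map, flatten_order = NULL,
                              threshold_nm = tr$threshold_nm,
                              expected_length_nm = tr$expected_length_nm,
                              tolerance_fraction = tr$tolerance_fraction,
                              prune_nm = tr$prune_nm,
                              smooth_window = tr$smooth_window)
    mm <- config$measurement
    meas <- measure_scene(map, traces,
                          min_peak_height_nm = mm$min_peak_height_nm,
                          arm_length_nm = mm$arm_length_nm,
                          qd_cutoff_nm = mm$qd_cutoff_nm,
                          condition = cond_name, replicate = rep_label)
    if (nrow(meas) > 0) meas$molecule_id <- meas$molecule_id + 10000L * sc
    ms[[sc]] <- meas
    n_dna <- n_dna + attr(meas, "n_dna")
    bad <- traces[traces$qc_status != "ok",
                  c("molecule_id", "contour_length_nm", "qc_status")]
    if (nrow(bad) > 0) {
      bad$scene <- sc; bad$condition <- cond_name; bad$replicate <- rep_label
      rejects[[length(rejects) + 1L]] <- bad
    }
  }
  list(measurements = dplyr::bind_rows(ms), n_dna = n_dna,
       rejects = dplyr::bind_rows(rejects))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> trace -> measure -> stats for every condition and
#' replicate in the plan, writes the per-complex measurement table, QC reject
#' log, per-condition summary table (occupancy per DNA +/- SD, specificity S
#' +/- SD, significance stars versus the reference condition) and a
#' machine-readable JSON run report. Re-running with the same configuration
#' and master seed reproduces all outputs byte-identically.
#'
#' @param config An `afm_run_config` or path to a YAML configuration.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @return Object of class `afm_run`: list with `summary` (tibble),
#'   `measurements`, `occupancy` / `position_fits` per condition, `report`.
#' @export
run_all <- function(config, seed = 1, out_dir = tempfile("afm_run_")) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "afm_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  conds <- names(config$conditions)
  all_meas <- list(); all_rej <- list(); n_dna_tbl <- list()
  for (ci in seq_along(conds)) {
    for (rep in seq_len(config$replicates)) {
      res <- tryCatch(
        measure_one_replicate(config, conds[ci], config$conditions[[ci]],
                              rep, derive_seed(seed, ci, rep), out_dir),
        error = function(e) {
          abort(sprintf("pipeline stage failed in condition '%s' replicate %d: %s",
                        conds[ci], rep, conditionMessage(e)),
                class = "afmdna_stage_error")
        })
      all_meas[[length(all_meas) + 1L]] <- res$measurements
      all_rej[[length(all_rej) + 1L]] <- res$rejects
      n_dna_tbl[[length(n_dna_tbl) + 1L]] <- tibble::tibble(
        condition = conds[ci], replicate = paste0("r", rep), n_dna = res$n_dna)
    }
  }
  measurements <- dplyr::bind_rows(all_meas)
  validate_measurements(measurements)
  n_dna_tbl <- dplyr::bind_rows(n_dna_tbl)
  rejects <- dplyr::bind_rows(all_rej)

  st <- config$stats
  cond_stats <- purrr::map(conds, function(cn) {
    sub <- measurements[measurements$condition == cn, ]
    nd <- n_dna_tbl[n_dna_tbl$condition == cn, c("replicate", "n_dna")]
    occ <- occupancy_at_site(sub, nd, bin = st$occupancy_bin)
    s_per_rep <- purrr::map_dbl(nd$replicate, function(r) {
      rsub <- sub[sub$replicate == r, ]
      if (nrow(rsub) < 10) return(NA_real_)
      h <- build_position_histogram(rsub, st$fit_bin_width,
                                    n_dna = nd$n_dna[nd$replicate == r])
      fit <- fit_position_model(h, st$site_pct)
      if (!fit$converged || fit$A_nsp <= 0) return(NA_real_)
      specificity(fit$A_sp, fit$A_nsp, st$n_sites)
    })
    pooled_fit <- if (nrow(sub) >= 10) {
      h <- build_position_histogram(sub, st$fit_bin_width,
                                    n_dna = sum(nd$n_dna))
      fit_position_model(h, st$site_pct)
    } else NULL
    list(condition = cn, occupancy = occ, S_per_rep = s_per_rep,
         pooled_fit = pooled_fit)
  })
  names(cond_stats) <- conds

  ref_occ <- cond_stats[[config$reference]]$occupancy$per_replicate$occupancy
  summary <- purrr::map_dfr(cond_stats, function(cs) {
    stars <- if (cs$condition == config$reference ||
                 length(ref_occ) != 3 ||
                 nrow(cs$occupancy$per_replicate) != 3) {
      NA_character_
    } else {
      compare_replicates(cs$occupancy$per_replicate$occupancy, ref_occ)$stars
    }
    s_vals <- cs$S_per_rep[!is.na(cs$S_per_rep)]
    tibble::tibble(
      condition = cs$condition,
      n_replicates = nrow(cs$occupancy$per_replicate),
      n_dna = sum(cs$occupancy$per_replicate$n_dna),
      n_complexes = sum(cs$occupancy$per_replicate$n_events),
      occupancy_per_dna = cs$occupancy$mean,
      occupancy_sd = cs$occupancy$sd,
      specificity_S = if (length(s_vals) > 0) mean(s_vals) else NA_real_,
      specificity_sd = if (length(s_vals) > 1) sd(s_vals) else NA_real_,
      significance = stars
    )
  })

  readr::write_csv(measurements, file.path(out_dir, "measurements.csv"))
  readr::write_csv(n_dna_tbl, file.path(out_dir, "n_dna.csv"))
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  if (nrow(rejects) > 0) {
    readr::write_csv(rejects, file.path(out_dir, "qc_rejects.csv"))
  }
  cfg_yaml <- yaml::as.yaml(unclass_recursive(config))
  report <- list(
    package_version = as.character(utils::packageVersion("afmdna")),
    master_seed = as.integer(seed),
    config_hash = rlang::hash(cfg_yaml),
    mode = config$mode,
    conditions = conds,
    replicates = config$replicates,
    n_dna = split(setNames(n_dna_tbl$n_dna, n_dna_tbl$replicate),
                  n_dna_tbl$condition),
    summary = summary
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(cfg_yaml, file.path(out_dir, "config_used.yaml"))

  structure(list(summary = summary, measurements = measurements,
                 condition_stats = cond_stats, rejects = rejects,
                 report = report, out_dir = out_dir),
            class = "afm_run")
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.afm_run <- function(x, ...) {
  cat("<afm_run>\n")
  print(as.data.frame(x$summary))
  invisible(x)
}
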