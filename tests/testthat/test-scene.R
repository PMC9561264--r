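test_that("an empty noiseless scene renders as flat background", {
  cfg <- quiet_cfg(noise_sd_nm = 0)
  sc <- render_chains(list(), cfg)
  expect_true(all(unclass(sc$height_map) == 0))
})

test_that("rendered blob volume matches the configured volume before tip convolution", {
  cfg <- quiet_cfg(tip_sigma_nm = 0, noise_sd_nm = 0, dna_height_nm = 1e-6)
  ch <- straight_chain()
  cx <- tibble::tibble(molecule_id = 1L, position_fraction = 0.5,
                       kind = "specific", bend_angle_true = 0,
                       volume_true = 100, height_true = 1.5, is_qd = FALSE)
  sc <- render_scene(list(ch), cx, cfg)
  vol <- sum(unclass(sc$height_map)) * cfg$pixel_size_nm^2
  expect_lt(abs(vol / 100 - 1), 0.02)
})

test_that("rendered maxima sit at the configured complex heights", {
  cfg <- quiet_cfg(tip_sigma_nm = 0, noise_sd_nm = 0)
  ch <- straight_chain()
  mk <- function(h, v, qd) tibble::tibble(
    molecule_id = 1L, position_fraction = 0.5, kind = "specific",
    bend_angle_true = 0, volume_true = v, height_true = h, is_qd = qd)
  protein <- render_scene(list(ch), mk(1.5, 100, FALSE), cfg)
  qd <- render_scene(list(ch), mk(4.5, 700, TRUE), cfg)
  expect_equal(max(unclass(protein$height_map)), 1.5, tolerance = 0.05)
  expect_equal(max(unclass(qd$height_map)), 4.5, tolerance = 0.05)
})

test_that("Gaussian tip broadening conserves integrated volume away from edges", {
  cfg <- quiet_cfg(tip_sigma_nm = 0, noise_sd_nm = 0, dna_height_nm = 1e-6)
  ch <- straight_chain()
  cx <- tibble::tibble(molecule_id = 1L, position_fraction = 0.5,
                       kind = "specific", bend_angle_true = 0,
                       volume_true = 120, height_true = 1.5, is_qd = FALSE)
  sc <- render_scene(list(ch), cx, cfg)
  m <- unclass(sc$height_map)
  blurred <- afmdna:::gaussian_blur(m, 1.5)
  expect_lt(abs(sum(blurred) / sum(m) - 1), 0.005)
})

test_that("scene generation is bit-identical under a fixed seed", {
  cfg <- afm_config(molecules_per_scene = 4, occupancy_specific = 0.5,
                    nonspecific_rate = 0.4, seed = 11)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(unclass(a$height_map), unclass(b$height_map))
  expect_identical(a$truth, b$truth)
})

test_that("complexes resolved off the grid raise a placement error", {
  cfg <- quiet_cfg(noise_sd_nm = 0)
  ch <- straight_chain(x0 = -300, y0 = 250)  # mostly off-grid
  cx <- tibble::tibble(molecule_id = 1L, position_fraction = 0.1,
                       kind = "nonspecific", bend_angle_true = 0,
                       volume_true = 100, height_true = 1.5, is_qd = FALSE)
  expect_error(render_scene(list(ch), cx, cfg),
               class = "afmdna_placement_error")
})

test_that("height maps round-trip through TIFF and plain-text formats", {
  cfg <- afm_config(molecules_per_scene = 2, occupancy_specific = 1,
                    scene_px = 128, seed = 3)
  sc <- simulate_scene(cfg)
  stem <- file.path(withr::local_tempdir(), "scene")
  write_height_map(sc, stem)
  txt <- read_height_map(paste0(stem, ".txt"))
  tif <- read_height_map(paste0(stem, ".tif"))
  orig <- unclass(sc$height_map)
  expect_equal(unclass(txt), orig, tolerance = 1e-6)
  expect_equal(unclass(tif), orig, tolerance = 1e-6)  # float32 round-trip
  expect_equal(attr(txt, "pixel_size_nm"), 2)
  side <- yaml::read_yaml(paste0(stem, ".yaml"))
  expect_equal(side$seed, 3)
})

test_that("ground truth bookkeeping matches the number of placed complexes", {
  cfg <- afm_config(molecules_per_scene = 6, occupancy_specific = 1,
                    nonspecific_rate = 0.5, seed = 21)
  sc <- simulate_scene(cfg)
  expect_true(all(is.finite(unclass(sc$height_map))))
  expect_equal(nrow(sc$molecules), 6)
  expect_true(all(sc$truth$position_fraction >= 0 &
                    sc$truth$position_fraction <= 1))
  expect_true(all(sc$truth$volume_true > 0))
  expect_true(all(sc$truth$position_pct_folded_true >= 0 &
                    sc$truth$position_pct_folded_true <= 50))
})
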