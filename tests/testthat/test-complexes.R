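test_that("bare DNA yields zero detections and a blob at the site is found", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  bare <- render_chains(list(straight_chain(x0 = 280, y0 = 380)), cfg)
  trb <- trace_molecules(bare$height_map)
  expect_equal(nrow(detect_complexes(trb$trace[[1]], bare$height_map,
                                     smooth_sigma_nm = 0)), 0)

  ch <- straight_chain(x0 = 280, y0 = 380)
  cx <- tibble::tibble(molecule_id = 1L, position_fraction = 0.498,
                       kind = "specific", bend_angle_true = 0,
                       volume_true = 100, height_true = 1.5, is_qd = FALSE)
  sc <- render_scene(list(ch), cx, cfg)
  tr <- trace_molecules(sc$height_map)
  mm <- measure_scene(sc$height_map, tr, smooth_sigma_nm = 0)
  expect_equal(nrow(mm), 1)
  expect_lt(abs(mm$position_pct_folded - 49.8), 1.5)
})

test_that("two blobs 30 nm apart are resolved as two detections", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  ch <- straight_chain(x0 = 280, y0 = 380)
  cx <- tibble::tibble(molecule_id = 1L,
                       position_fraction = c(0.4, 0.4 + 30 / 171.7),
                       kind = "nonspecific", bend_angle_true = 0,
                       volume_true = 100, height_true = 1.5, is_qd = FALSE)
  sc <- render_scene(list(ch), cx, cfg)
  tr <- trace_molecules(sc$height_map)
  pk <- detect_complexes(tr$trace[[1]], sc$height_map, smooth_sigma_nm = 2)
  expect_equal(nrow(pk), 2)
})

test_that("fractional position folds symmetric cases and trace orientation away", {
  tr <- polyline_trace(seq(100, 272, by = 0.5), rep(200, 345))
  L <- attr(tr, "contour_length")
  expect_equal(fractional_position(tr, L / 2), 50)
  expect_equal(fractional_position(tr, 0), 0)
  expect_equal(fractional_position(tr, L), 0)
  expect_error(fractional_position(tr, L + 1), class = "afmdna_invalid_input")
  # reversing the trace orientation leaves the folded position unchanged
  s <- 0.3 * L
  rev_tr <- polyline_trace(rev(tr$x), rev(tr$y))
  expect_equal(fractional_position(tr, s), fractional_position(rev_tr, L - s),
               tolerance = 1e-9)
})

test_that("bend angles are read off constructed polylines to line-fit accuracy", {
  straight <- polyline_trace(seq(0, 80, by = 0.5) + 100, rep(100, 161))
  expect_lt(measure_bend_angle(straight, 40), 1e-6)

  for (ang in c(20, 35, 70)) {
    kink <- kinked_polyline(ang)
    mid <- attr(kink, "contour_length") / 2
    expect_lt(abs(measure_bend_angle(kink, mid) - ang), 2)
  }

  # invariant under global rotation of the scene
  kink <- kinked_polyline(55)
  mid <- attr(kink, "contour_length") / 2
  a0 <- measure_bend_angle(kink, mid)
  th <- 0.61
  rot <- polyline_trace(cos(th) * kink$x - sin(th) * kink$y + 40,
                        sin(th) * kink$x + cos(th) * kink$y + 15)
  expect_lt(abs(measure_bend_angle(rot, mid) - a0), 1)

  # peaks within one arm length of an end are not measurable
  expect_true(is.na(measure_bend_angle(kink, 3)))
})

test_that("volume integration recovers isolated blob volumes", {
  cfg <- quiet_cfg(tip_sigma_nm = 0, noise_sd_nm = 0, dna_height_nm = 1e-6,
                   scene_px = 384)
  ch <- straight_chain(x0 = 280, y0 = 380)
  cx <- tibble::tibble(molecule_id = 1L, position_fraction = 0.5,
                       kind = "specific", bend_angle_true = 0,
                       volume_true = 100, height_true = 1.5, is_qd = FALSE)
  sc <- render_scene(list(ch), cx, cfg)
  v <- measure_volume(sc$height_map, c(sc$truth$x, sc$truth$y))
  expect_lt(abs(v$volume_nm3 / 100 - 1), 0.05)

  # and is conserved under tip convolution (integral-preserving blur)
  blurred <- height_map(afmdna:::gaussian_blur(unclass(sc$height_map), 1.5), 2)
  vb <- measure_volume(blurred, c(sc$truth$x, sc$truth$y))
  expect_lt(abs(vb$volume_nm3 / 100 - 1), 0.10)

  # zero-height region measures zero
  flat <- height_map(matrix(0, 128, 128), 2)
  v0 <- measure_volume(flat, c(128, 128))
  expect_equal(v0$volume_nm3, 0)
})

test_that("monomer and dimer scenes give separated, ordered volume modes", {
  run_cond <- function(vol, seeds) {
    cfg <- afm_config(molecules_per_scene = 5, nonspecific_rate = 0.2,
                      occupancy_specific = 0.8, protein_volume_nm3 = vol,
                      volume_sd_nm3 = 0.12 * vol)
    out <- c()
    for (s in seeds) {
      sc <- simulate_scene(cfg, seed = s)
      m <- flatten(sc$height_map, 1)
      tr <- trace_molecules(m, flatten_order = NULL)
      out <- c(out, measure_scene(m, tr)$volume_nm3)
    }
    out
  }
  v_mono <- run_cond(100, 9001:9008)
  v_dim <- run_cond(160, 9101:9108)
  expect_gt(median(v_dim), median(v_mono))
  expect_gt(median(v_dim) - median(v_mono), 25)
})

test_that("the QD height criterion is inclusive at the 3 nm boundary", {
  expect_identical(classify_qd(c(1.5, 2.99, 3.0, 4.5)),
                   c(FALSE, FALSE, TRUE, TRUE))
  # misclassification of the two height populations is negligible
  set.seed(1)
  protein <- rnorm(1e5, 1.5, 0.3)
  qd <- rnorm(1e5, 4.5, 0.3)
  err <- mean(classify_qd(protein)) + mean(!classify_qd(qd))
  expect_lt(err, 1e-4)
})
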