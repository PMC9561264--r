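test_that("flatten removes scanline tilt and is idempotent on flat maps", {
  nr <- 128
  plane <- outer(rep(1, nr), seq_len(nr)) * 0.01  # 0.01 nm/px tilt
  tilted <- height_map(plane + 0.3, pixel_size_nm = 2)
  flat <- flatten(tilted, 1)
  expect_lt(abs(median(unclass(flat))), 0.01)

  again <- flatten(flat, 1)
  expect_equal(unclass(again), unclass(flat), tolerance = 1e-6)

  expect_error(flatten(tilted, 5), class = "afmdna_invalid_input")
})

test_that("tilt does not change traced contour lengths", {
  cfg <- afm_config(molecules_per_scene = 3, occupancy_specific = 0,
                    nonspecific_rate = 0, scene_px = 384, seed = 31)
  sc <- simulate_scene(cfg)
  m0 <- unclass(sc$height_map)
  tilt <- outer(rep(1, nrow(m0)), seq_len(ncol(m0))) * 0.01
  tr_ref <- trace_molecules(sc$height_map)
  tr_tilt <- trace_molecules(height_map(m0 + tilt, 2))
  ok_ref <- sort(tr_ref$contour_length_nm[tr_ref$qc_status == "ok"])
  ok_tilt <- sort(tr_tilt$contour_length_nm[tr_tilt$qc_status == "ok"])
  expect_equal(length(ok_ref), length(ok_tilt))
  expect_true(all(abs(ok_tilt / ok_ref - 1) < 0.01))
})

test_that("segmentation finds separated molecules and flags border contact", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  # empty map: zero regions, not an error
  empty <- render_chains(list(), cfg)
  seg0 <- segment_molecules(empty$height_map)
  expect_equal(nrow(seg0$regions), 0)

  two <- render_chains(list(straight_chain(x0 = 150, y0 = 180),
                            straight_chain(x0 = 350, y0 = 550, angle_deg = 60)),
                       cfg)
  seg2 <- segment_molecules(two$height_map)
  expect_equal(nrow(seg2$regions), 2)
  expect_false(any(seg2$regions$touches_border))

  edge <- render_chains(list(straight_chain(x0 = -60, y0 = 400)), cfg)
  sege <- segment_molecules(edge$height_map)
  expect_true(any(sege$regions$touches_border))
  tre <- trace_molecules(edge$height_map)
  expect_true(all(tre$qc_status == "edge_touching"))
})

test_that("a rendered straight rod traces to its true contour length", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  sc <- render_chains(list(straight_chain(x0 = 280, y0 = 380,
                                          angle_deg = 25)), cfg)
  tr <- trace_molecules(sc$height_map)
  expect_equal(tr$qc_status, "ok")
  expect_lt(abs(tr$contour_length_nm / 171.7 - 1), 0.05)
})

test_that("tracing is rotation-robust", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  lens <- vapply(c(0, 22.5, 45, 67.5, 90), function(a) {
    sc <- render_chains(list(straight_chain(x0 = 280, y0 = 380,
                                            angle_deg = a)), cfg)
    tr <- trace_molecules(sc$height_map)
    expect_equal(tr$qc_status, "ok")
    tr$contour_length_nm
  }, numeric(1))
  expect_lt(diff(range(lens)) / mean(lens), 0.02)
})

test_that("loops and crossings are recognised by skeleton topology", {
  cfg <- quiet_cfg(noise_sd_nm = 0, scene_px = 384)
  loop <- render_chains(list(circle_chain(x0 = 380, y0 = 380)), cfg)
  trl <- trace_molecules(loop$height_map)
  expect_equal(trl$qc_status, "closed_loop")

  crossed <- render_chains(list(straight_chain(x0 = 300, y0 = 380, angle_deg = 15),
                                straight_chain(x0 = 320, y0 = 300, angle_deg = 75)),
                           cfg)
  trc <- trace_molecules(crossed$height_map)
  expect_equal(nrow(trc), 1)  # one merged region
  expect_equal(trc$qc_status, "branched")
})

test_that("the length filter flags incomplete substrates only", {
  traces <- tibble::tibble(
    molecule_id = 1:4,
    contour_length_nm = c(150, 100, 171.7, 210),
    qc_status = c("ok", "ok", "ok", "ok"),
    trace = vector("list", 4)
  )
  out <- filter_traces(traces, expected_length_nm = 171.7,
                       tolerance_fraction = 0.2)
  expect_equal(out$qc_status, c("ok", "off_length", "ok", "off_length"))
  expect_error(filter_traces(traces, tolerance_fraction = 1.5),
               class = "afmdna_invalid_input")
})

test_that("traced paths never exceed their contour length end-to-end", {
  cfg <- afm_config(molecules_per_scene = 4, occupancy_specific = 0,
                    nonspecific_rate = 0, seed = 17)
  sc <- simulate_scene(cfg)
  tr <- trace_molecules(sc$height_map)
  for (k in which(tr$qc_status == "ok")) {
    p <- tr$trace[[k]]
    e2e <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
    expect_lte(e2e, attr(p, "contour_length") + 1e-9)
  }
})

test_that("noiseless scenes trace every isolated interior molecule", {
  cfg <- afm_config(molecules_per_scene = 6, occupancy_specific = 0,
                    nonspecific_rate = 0, noise_sd_nm = 0, seed = 23)
  sc <- simulate_scene(cfg)
  tr <- trace_molecules(sc$height_map)
  clean <- sum(!sc$molecules$touches_border & !sc$molecules$overlaps)
  expect_gte(sum(tr$qc_status == "ok"), clean)
})
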