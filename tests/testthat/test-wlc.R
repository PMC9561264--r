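test_that("stiff chains are straight and contour length is exact by construction", {
  cfg <- afm_config(persistence_length = 1e9)
  ch <- sample_wlc_chain(cfg, seed = 1)
  L <- attr(ch, "contour_length")
  expect_equal(L, 505 * 0.34, tolerance = 1e-12)
  e2e <- sqrt((ch$x[nrow(ch)] - ch$x[1])^2 + (ch$y[nrow(ch)] - ch$y[1])^2)
  expect_equal(e2e, 171.7, tolerance = 1e-6)

  # flexible chain: contour length still exactly n_segments * segment_length
  ch2 <- sample_wlc_chain(afm_config(persistence_length = 10), seed = 2)
  seg <- attr(ch2, "segment_length")
  expect_identical(attr(ch2, "contour_length"), seg * (nrow(ch2) - 1L))
  expect_true(all(diff(ch2$arclength) > 0))
  # end-to-end distance can never exceed the contour length
  e2e2 <- sqrt((ch2$x[nrow(ch2)] - ch2$x[1])^2 + (ch2$y[nrow(ch2)] - ch2$y[1])^2)
  expect_lt(e2e2, attr(ch2, "contour_length"))
})

test_that("mean squared end-to-end distance matches the 2D closed form", {
  cases <- list(c(L = 171.7, P = 10), c(L = 171.7, P = 50), c(L = 343.4, P = 50))
  set.seed(101)
  for (cs in cases) {
    cfg <- afm_config(dna_length_bp = round(cs[["L"]] / 0.34),
                      persistence_length = cs[["P"]])
    msd <- mean(vapply(seq_len(10000), function(i) {
      ch <- sample_wlc_chain(cfg)
      (ch$x[nrow(ch)] - ch$x[1])^2 + (ch$y[nrow(ch)] - ch$y[1])^2
    }, numeric(1)))
    theory <- wlc_msd_theory(cfg$contour_length_nm, cs[["P"]])
    expect_lt(abs(msd / theory - 1), 0.03)
  }
})

test_that("chain sampling is deterministic under a fixed seed", {
  cfg <- afm_config()
  expect_identical(sample_wlc_chain(cfg, seed = 7),
                   sample_wlc_chain(cfg, seed = 7))
})

test_that("invalid chain configurations are rejected", {
  expect_error(afm_config(persistence_length = -1),
               class = "afmdna_invalid_config")
  expect_error(afm_config(dna_length_bp = 0), class = "afmdna_invalid_config")
  expect_error(afm_config(bend_state_weights = c(0.5, 0.5, 0.5)),
               class = "afmdna_invalid_config")
})

test_that("impose_bend sets the local deflection exactly and preserves arclength", {
  ch <- straight_chain()
  # angle 0 on a straight chain leaves coordinates unchanged
  same <- impose_bend(ch, 86, 0)
  expect_equal(same$x, ch$x, tolerance = 1e-12)
  expect_equal(same$y, ch$y, tolerance = 1e-12)

  bent <- impose_bend(ch, 86, 70)
  expect_equal(attr(bent, "contour_length"), attr(ch, "contour_length"),
               tolerance = 1e-12)
  # geometric deflection at the node equals 70 degrees exactly
  i <- 86
  v1 <- c(bent$x[i] - bent$x[i - 1], bent$y[i] - bent$y[i - 1])
  v2 <- c(bent$x[i + 1] - bent$x[i], bent$y[i + 1] - bent$y[i])
  defl <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(defl, 70, tolerance = 1e-9)

  expect_error(impose_bend(ch, 1, 30), class = "afmdna_invalid_site")
  expect_error(impose_bend(ch, nrow(ch), 30), class = "afmdna_invalid_site")
})

test_that("bend-state mixture draws realise the configured state means", {
  set.seed(42)
  means <- c(0, 35, 70)
  weights <- c(0.3, 0.4, 0.3)
  state <- sample.int(3, 1000, replace = TRUE, prob = weights)
  target <- abs(means[state] + rnorm(1000, 0, 8))
  realised <- vapply(seq_len(1000), function(k) {
    ch <- straight_chain()
    b <- impose_bend(ch, 86, target[k])
    i <- 86
    v1 <- c(b$x[i] - b$x[i - 1], b$y[i] - b$y[i - 1])
    v2 <- c(b$x[i + 1] - b$x[i], b$y[i + 1] - b$y[i])
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }, numeric(1))
  # imposed deflections reproduce their targets, so the per-state empirical
  # means track the mixture (folded at 0 for the 0-degree state)
  for (s in 1:3) {
    expect_lt(abs(mean(realised[state == s]) - mean(target[state == s])), 1e-6)
  }
  expect_lt(abs(mean(realised[state == 2]) - 35), 2)
  expect_lt(abs(mean(realised[state == 3]) - 70), 2)
})

test_that("local straightening zeroes curvature in the window only", {
  ch <- sample_wlc_chain(afm_config(persistence_length = 20), seed = 5)
  st <- straighten_chain(ch, 86, half_width_nm = 15)
  expect_equal(attr(st, "contour_length"), attr(ch, "contour_length"),
               tolerance = 1e-9)
  # the window around the node is now collinear
  th <- atan2(diff(st$y), diff(st$x))
  win <- 72:100
  expect_lt(max(abs(diff(th[win]))), 1e-9)
})
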