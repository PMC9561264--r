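test_that("position histograms bin, normalise and conserve counts", {
  m <- tibble::tibble(position_pct_folded = rep(47, 100))
  h <- build_position_histogram(m, bin_width_pct = 5, n_dna = 200)
  expect_equal(h$counts_per_dna[h$bin_lo == 45], 0.5)
  expect_equal(sum(h$counts), 100)

  empty <- build_position_histogram(
    tibble::tibble(position_pct_folded = numeric()), 2, n_dna = 10)
  expect_true(all(empty$counts == 0))

  # conservation: sum(counts_per_dna) * n_dna equals the total count exactly
  set.seed(2)
  m2 <- tibble::tibble(position_pct_folded = runif(357, 0, 50))
  h2 <- build_position_histogram(m2, 2, n_dna = 123)
  expect_equal(sum(h2$counts_per_dna) * 123, 357)
  # boundary values land in the outer bins (last bin right-inclusive)
  h3 <- build_position_histogram(
    tibble::tibble(position_pct_folded = c(0, 50)), 2, n_dna = 1)
  expect_equal(h3$counts[1], 1)
  expect_equal(h3$counts[nrow(h3)], 1)

  expect_error(build_position_histogram(m, 2, n_dna = 0),
               class = "afmdna_invalid_input")
})

test_that("the position model recovers exact histogram parameters", {
  mids <- seq(1, 49, by = 2)
  truth <- list(bg = 4, area = 120, mu = 49.8, sigma = 1.5)
  counts <- truth$bg + truth$area * 2 *
    afmdna:::reflected_dnorm(mids, truth$mu, truth$sigma)
  h <- tibble::tibble(bin_lo = mids - 1, bin_hi = mids + 1, mid = mids,
                      counts = counts, counts_per_dna = counts / 100)
  attr(h, "n_dna") <- 100; attr(h, "bin_width") <- 2
  class(h) <- c("position_histogram", class(h))
  fit <- fit_position_model(h, 49.8)
  expect_true(fit$converged)
  expect_equal(fit$components$center, 49.8, tolerance = 1e-3)
  expect_equal(fit$components$sd, 1.5, tolerance = 1e-3)
  expect_equal(fit$A_sp, 120, tolerance = 1e-3)
  expect_equal(fit$background_level, 4, tolerance = 1e-3)
  expect_equal(fit$A_nsp, 4 * 25, tolerance = 1e-2)

  # broom-style accessors
  expect_equal(glance(fit)$A_sp, fit$A_sp)
  expect_equal(nrow(tidy(fit)), 2)
})

test_that("zero-signal histograms fit a near-zero specific area", {
  set.seed(9)
  m <- tibble::tibble(position_pct_folded = runif(500, 0, 50))
  h <- build_position_histogram(m, 2, n_dna = 1000)
  fit <- fit_position_model(h, 49.8)
  expect_true(fit$converged)
  expect_lt(fit$A_sp, 2 * sqrt(500))
})

test_that("specificity follows S = N (A_sp / A_nsp) + 1", {
  expect_equal(specificity(0, 10, 505), 1)
  expect_equal(specificity(10, 10, 505), 506)
  expect_error(specificity(1, 0, 505),
               class = "afmdna_undefined_specificity")
  # monotone increasing in A_sp, decreasing in A_nsp
  a_sp <- seq(0.5, 5, by = 0.5)
  s1 <- vapply(a_sp, specificity, numeric(1), A_nsp = 2, N = 505)
  expect_true(all(diff(s1) > 0))
  a_nsp <- seq(0.5, 5, by = 0.5)
  s2 <- vapply(a_nsp, function(x) specificity(2, x, 505), numeric(1))
  expect_true(all(diff(s2) < 0))
})

test_that("occupancy per DNA averages over replicates with additive background", {
  m0 <- tibble::tibble(position_pct_folded = c(10, 20, 30),
                       molecule_id = 1:3, replicate = "r1")
  occ0 <- occupancy_at_site(m0, n_dna = 50)
  expect_equal(occ0$mean, 0)
  expect_true(is.na(occ0$sd))  # single replicate: SD not available

  m3 <- tibble::tibble(
    position_pct_folded = rep(47, 27),
    molecule_id = 1:27,
    replicate = rep(c("r1", "r2", "r3"), each = 9))
  occ3 <- occupancy_at_site(m3, n_dna = 50)
  expect_equal(occ3$mean, 0.18)
  expect_equal(occ3$sd, 0)

  # additive background: specific rate + uniform background leakage into bin
  cfg <- afm_config(n_molecules = 4000, occupancy_specific = 0.10,
                    nonspecific_rate = 0.2)
  m <- simulate_measurements(cfg, seed = 13)
  occ <- occupancy_at_site(m, n_dna = 4000)
  expected <- 0.10 + 0.2 * (5 / 50)
  se <- sqrt(expected / 4000)
  expect_lt(abs(occ$per_replicate$occupancy - expected), 3 * se)

  expect_error(occupancy_at_site(m3, n_dna = c(r9 = 10)),
               class = "afmdna_invalid_input")
})

test_that("bend-state decomposition recovers mixtures and refuses tiny samples", {
  set.seed(31)
  expect_error(decompose_bend_states(runif(20, 0, 90)),
               class = "afmdna_small_sample")
  expect_error(decompose_bend_states(c(runif(40, 0, 90), 200)),
               class = "afmdna_invalid_input")

  one_state <- abs(rnorm(200, 0, 8))
  f1 <- decompose_bend_states(one_state, k = 3)
  expect_true(f1$converged)
  dominant <- f1$components[which.max(f1$components$area), ]
  expect_lt(dominant$center, 5)

  mix <- abs(sample(c(0, 35, 70), 300, TRUE, c(0.3, 0.4, 0.3)) +
               rnorm(300, 0, 8))
  f3 <- decompose_bend_states(mix, k = 3)
  expect_equal(f3$components$center, c(0, 35, 70), tolerance = 5 / 35)
  expect_lt(abs(f3$components$center[2] - 35), 5)
  expect_lt(abs(f3$components$center[3] - 70), 5)

  f20 <- decompose_bend_states(abs(rnorm(200, 20, 8)), k = 1,
                               init_means = 20)
  expect_lt(abs(f20$components$center - 20), 3)

  # self-consistency: refitting data simulated from the fitted parameters
  cmp <- f3$components
  set.seed(77)
  st <- sample.int(3, 400, TRUE, prob = cmp$area / sum(cmp$area))
  resim <- abs(cmp$center[st] + rnorm(400, 0, cmp$sd[st]))
  f_rt <- decompose_bend_states(resim, k = 3)
  expect_lt(abs(f_rt$components$center[2] - cmp$center[2]), 5)
  expect_lt(abs(f_rt$components$center[3] - cmp$center[3]), 5)
})

test_that("pooled-variance t comparison matches the textbook formula", {
  same <- compare_replicates(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  a <- c(0.10, 0.10, 0.11); b <- c(0.18, 0.17, 0.19)
  cmp <- compare_replicates(a, b)
  # independent textbook computation: pooled sd, t with 4 df
  sp <- sqrt(((3 - 1) * var(a) + (3 - 1) * var(b)) / 4)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-6)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(cmp$degrees_freedom, 4L)
  expect_equal(cmp$stars, "***")  # p here is ~2e-4 < 0.005
  expect_lt(cmp$p_value, 0.005)

  # star thresholds across the bands
  p_of <- function(a, b) compare_replicates(a, b)
  expect_equal(p_of(c(1, 2, 3), c(2, 3, 4))$stars, "ns")
  infy <- compare_replicates(c(1, 1, 1), c(2, 2, 2))
  expect_true(infy$infinite_t)

  expect_error(compare_replicates(c(1, 2), c(1, 2, 3)),
               class = "afmdna_invalid_input")
})
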