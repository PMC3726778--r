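# Shared small pool with cached curves.
make_cached_pool <- function(n = 30L, seed = 12) {
  pool <- generate_pool(tiny_topology(seed = 6), n, seed = seed)
  precompute_curves(pool, default_q_grid())
}

test_that("ensemble average curve: repeats, pairwise mean, Rg envelope", {
  pool <- make_cached_pool(10L)
  avg1 <- ensemble_average_curve(pool, rep(3L, 7L))
  expect_equal(avg1$intensity, pool$curves[, 3L])
  avg2 <- ensemble_average_curve(pool, c(1L, 2L))
  expect_equal(avg2$intensity, (pool$curves[, 1L] + pool$curves[, 2L]) / 2)
  # I(0) of the average is the mean of member I(0)
  expect_equal(avg2$intensity[1L],
               mean(pool$curves[1L, c(1L, 2L)]))
  # Guinier Rg^2 of the average lies inside the member Rg^2 envelope
  d <- pool_descriptors(pool)
  g2 <- guinier_rg(ensemble_average_curve(pool, c(1L, 5L, 9L)))$rg^2
  expect_gte(g2, min(d$rg[c(1, 5, 9)]^2) * 0.98)
  expect_lte(g2, max(d$rg[c(1, 5, 9)]^2) * 1.02)
  expect_error(ensemble_average_curve(generate_pool(tiny_topology(6), 2L), 1L),
               "precompute_curves")
})

test_that("GA on a degenerate pool of identical conformers is immediate", {
  arm <- make_toy_rigid_arm(30L, 80, seed = 2)
  topo <- build_topology(list(segment("rigid", 1L, 30L, "rod", arm)))
  pool <- precompute_curves(generate_pool(topo, 5L, seed = 1),
                            default_q_grid())
  theo <- debye_intensity(arm, default_q_grid())
  data <- scattering_curve(theo$q, theo$intensity,
                           sigma = 0.01 * theo$intensity)
  ens <- ga_select(pool, data, M = 4L,
                   config = ga_config(population_size = 10L,
                                      generations = 5L, n_repeats = 1L))
  single <- chi_squared(theo, data)$chi2
  expect_equal(ens$fit$chi2, single, tolerance = 1e-12)
  expect_equal(ens$generation_found, 1L)
})

test_that("GA matches the exhaustive multiset optimum on a small pool", {
  pool <- make_cached_pool(12L, seed = 44)
  spec <- tiny_spec(seed = 9, noise_fraction = 0.01)
  # target: noisy mixture of two pool members
  mix <- scattering_curve(pool$q,
                          0.6 * pool$curves[, 2L] + 0.4 * pool$curves[, 7L])
  sig <- 0.01 * mix$intensity
  set.seed(3)
  data <- scattering_curve(pool$q, mix$intensity + rnorm(length(sig), 0, sig),
                           sigma = sig)
  M <- 3L
  all_sets <- multisets(12L, M)
  best_exh <- min(apply(all_sets, 2L, function(idx)
    chi_squared(ensemble_average_curve(pool, idx), data)$chi2))
  ens <- ga_select(pool, data, M = M,
                   config = ga_config(population_size = 60L,
                                      generations = 150L, n_repeats = 3L,
                                      seed = 5))
  expect_lte(ens$fit$chi2, best_exh * 1.05)
})

test_that("GA best chi-square trace is non-increasing (elitism)", {
  pool <- make_cached_pool(20L, seed = 13)
  data <- scattering_curve(pool$q, rowMeans(pool$curves),
                           sigma = 0.01 * rowMeans(pool$curves))
  ens <- ga_select(pool, data, M = 10L,
                   config = ga_config(population_size = 30L,
                                      generations = 60L, n_repeats = 1L,
                                      seed = 2))
  expect_true(all(diff(ens$trace) <= 1e-12))
  expect_length(ens$member_indices, 10L)
  expect_false(is.unsorted(ens$member_indices))
})

test_that("GA selection is deterministic given the config seed", {
  pool <- make_cached_pool(15L, seed = 14)
  data <- scattering_curve(pool$q, rowMeans(pool$curves),
                           sigma = 0.02 * rowMeans(pool$curves))
  cfg <- ga_config(population_size = 20L, generations = 40L, n_repeats = 2L,
                   seed = 31)
  e1 <- ga_select(pool, data, M = 5L, config = cfg)
  e2 <- ga_select(pool, data, M = 5L, config = cfg)
  expect_identical(e1$member_indices, e2$member_indices)
  expect_identical(e1$fit$chi2, e2$fit$chi2)
})

test_that("RMS-averaged Rg: arithmetic, idempotence, Jensen bound", {
  expect_equal(ensemble_rg_rms(c(3, 4)), sqrt(12.5))
  expect_equal(ensemble_rg_rms(rep(7.3, 10L)), 7.3)
  set.seed(15)
  for (k in 1:5) {
    x <- runif(20L, 10, 90)
    expect_gte(ensemble_rg_rms(x), mean(x))
  }
  expect_error(ensemble_rg_rms(c(3, -1)), "non-negative")
  expect_error(ensemble_rg_rms(numeric(0)), "empty")
})

test_that("distribution summary: null ensembles track the pool", {
  pool <- make_cached_pool(400L, seed = 16)
  set.seed(9)
  idx <- sample.int(400L, 50L)
  s <- summarize_distributions(pool, idx)
  expect_equal(sum(s$rg_hist$pool), 1, tolerance = 1e-12)
  expect_equal(sum(s$rg_hist$selected), 1, tolerance = 1e-12)
  d <- pool_descriptors(pool)
  ks <- suppressWarnings(stats::ks.test(d$rg, d$rg[idx]))
  expect_gt(ks$p.value, 0.001)
  # RMS Rg of any sub-ensemble stays inside the pool extremes
  expect_gte(s$rg_rms_selected, min(d$rg))
  expect_lte(s$rg_rms_selected, max(d$rg))
})

test_that("single-conformer ensembles give a degenerate one-bin histogram", {
  pool <- make_cached_pool(10L, seed = 18)
  s <- summarize_distributions(pool, rep(4L, 6L))
  expect_equal(sum(s$rg_hist$selected > 0), 1L)
  expect_equal(s$peak_count_selected, 1L)
  expect_true(is.na(s$peak_ratio))
})

test_that("shape classification: point masses and uniform angular measure", {
  spec90 <- tiny_spec("L_shape", seed = 5)
  spec90$arm_angle_distribution <- list(type = "point", angle = 170)
  ensI <- simulate_true_ensemble(spec90, 25L)
  expect_equal(unname(classify_shapes(ensI)["I"]), 1.0)

  specU <- tiny_spec("uniform_flexible", seed = 6)
  ensU <- simulate_true_ensemble(specU, 400L)
  fr <- classify_shapes(ensU)
  expect_equal(sum(fr), 1)
  # classes partition [0, 180] into three 60-degree bands: ~1/3 each,
  # binomial 3-sigma tolerance at n = 400
  for (cl in c("L", "U", "I"))
    expect_lt(abs(fr[[cl]] - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 400))

  # fractions of a weighted sub-ensemble also sum to one
  pool <- make_cached_pool(10L, seed = 19)
  expect_equal(sum(classify_shapes(pool, c(1L, 1L, 2L))), 1)

  rod <- build_topology(list(segment("rigid", 1L, 10L, "rod",
                                     make_toy_rigid_arm(10L, 30, seed = 2))))
  pr <- generate_pool(rod, 3L, seed = 1)
  expect_error(classify_shapes(pr), "fewer than two rigid arms")
})
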