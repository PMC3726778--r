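cfg <- generator_config()

test_that("sample_linker honors the chain geometry contract", {
  set.seed(1)
  anchor <- c(5, 5, 5)
  one <- sample_linker(1L, anchor, c(0, 0, 1), cfg)
  expect_equal(sqrt(sum((one[1L, ] - anchor)^2)), cfg$bond_length,
               tolerance = 1e-12)
  chain <- sample_linker(30L, anchor, c(1, 0, 0), cfg)
  bonds <- sqrt(rowSums((chain[-1L, ] - chain[-30L, ])^2))
  expect_equal(bonds, rep(cfg$bond_length, 29L), tolerance = 1e-9)
  # pseudo-bond angles inside the configured window
  angs <- sapply(2:29, function(i) {
    u <- chain[i - 1L, ] - chain[i, ]; v <- chain[i + 1L, ] - chain[i, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  })
  expect_true(all(angs >= cfg$pseudo_angle_range[1L] - 1e-6))
  expect_true(all(angs <= cfg$pseudo_angle_range[2L] + 1e-6))
  # no self clashes at >= 2 separations
  d <- as.matrix(dist(chain))
  d[abs(row(d) - col(d)) <= 1L] <- Inf
  expect_gte(min(d), cfg$clash_radius)
})

test_that("sample_linker is deterministic under a fixed RNG state", {
  a <- with(list(), { set.seed(99); sample_linker(20L, c(0, 0, 0), c(1, 0, 0), cfg) })
  b <- with(list(), { set.seed(99); sample_linker(20L, c(0, 0, 0), c(1, 0, 0), cfg) })
  expect_identical(a, b)
})

test_that("mean squared end-to-end distance grows with linker length", {
  # random-chain scaling: brute-force simulation at two lengths
  msq <- function(n, draws = 1000L) {
    set.seed(123)
    mean(replicate(draws, {
      ch <- sample_linker(n, c(0, 0, 0), c(1, 0, 0), cfg)
      sum(ch[n, ]^2)
    }))
  }
  expect_gt(msq(50L), msq(25L))
})

test_that("rigid-only topology reproduces the template assembly exactly", {
  arm <- make_toy_rigid_arm(25L, 70, seed = 4)
  topo <- build_topology(list(segment("rigid", 1L, 25L, "rod", arm)))
  set.seed(2)
  cf <- generate_conformer(topo, cfg)
  expect_equal(cf$model$coordinates, arm$coordinates)
  expect_equal(cf$rg, compute_descriptors(arm, topo)$rg)
})

test_that("rigid segments keep their template internal distances to 1e-6 A", {
  topo <- tiny_topology(seed = 6)
  idx <- saxsens:::segment_bead_indices(topo)
  rig <- saxsens:::rigid_segments(topo)
  set.seed(31)
  for (k in 1:10) {
    cf <- generate_conformer(topo, cfg)
    for (r in rig) {
      tpl_d <- dist(topo$segments[[r]]$template$coordinates)
      got_d <- dist(cf$model$coordinates[idx[[r]], ])
      expect_lt(max(abs(tpl_d - got_d)), 1e-6)
    }
  }
})

test_that("conformers are clash-free at the configured radius", {
  topo <- tiny_topology(seed = 6)
  set.seed(8)
  for (k in 1:10) {
    cf <- generate_conformer(topo, cfg)
    d <- as.matrix(dist(cf$model$coordinates))
    d[abs(row(d) - col(d)) <= 1L] <- Inf
    expect_gte(min(d), cfg$clash_radius)
  }
})

test_that("a free hinge lets the arm angle span most of its range", {
  topo <- tiny_topology(seed = 6)
  set.seed(77)
  angles <- replicate(500L, generate_conformer(topo, cfg)$arm_angle)
  expect_gt(diff(range(angles)), 120)
})

test_that("pools are reproducible and sized as requested", {
  topo <- tiny_topology(seed = 6)
  p1 <- generate_pool(topo, 25L, cfg, seed = 17)
  p2 <- generate_pool(topo, 25L, cfg, seed = 17)
  expect_length(p1$conformers, 25L)
  expect_identical(pool_descriptors(p1), pool_descriptors(p2))
  p3 <- generate_pool(topo, 1L, cfg, seed = 17)
  expect_length(p3$conformers, 1L)
  # same substreams: conformer i identical regardless of pool size
  expect_equal(p3$conformers[[1L]]$model$coordinates,
               p1$conformers[[1L]]$model$coordinates)
})

test_that("descriptors match closed forms and brute-force oracles", {
  topo2 <- build_topology(list(segment("rigid", 1L, 2L, "pair",
    bead_model(matrix(c(0, 0, 0, 10, 0, 0), 2L, 3L, byrow = TRUE),
               validate_bonds = "none"))))
  d <- compute_descriptors(topo2$segments[[1L]]$template, topo2)
  expect_equal(d$rg, 5)
  expect_equal(d$dmax, 10)
  expect_equal(d$end_to_end, 10)

  # collinear arms pointing apart -> 180 deg, I; folded back -> 0, U
  mk <- function(arm2_x) {
    coords <- rbind(cbind(seq(0, 3 * 3.5, by = 3.5), 0, 0),
                    cbind(arm2_x, 3.5, 0))
    topo <- build_topology(list(
      segment("rigid", 1L, 4L, "a1",
              bead_model(coords[1:4, ], validate_bonds = "none")),
      segment("rigid", 5L, 8L, "a2",
              bead_model(coords[5:8, ], validate_bonds = "none"))))
    compute_descriptors(bead_model(coords, validate_bonds = "none"), topo)
  }
  ext <- mk(seq(14, 14 + 3 * 3.5, by = 3.5))       # continues outward
  expect_equal(ext$arm_angle, 180)
  expect_equal(ext$shape_class, "I")
  fold <- mk(seq(10.5, 0, by = -3.5))              # doubles back
  expect_equal(fold$arm_angle, 0)
  expect_equal(fold$shape_class, "U")

  # dmax equals the O(n^2) brute-force maximum on a random cloud
  set.seed(5)
  cloud <- matrix(rnorm(150, sd = 20), 50L, 3L)
  topoc <- build_topology(list(segment("rigid", 1L, 50L, "c",
    bead_model(cloud, validate_bonds = "none"))))
  dm <- compute_descriptors(bead_model(cloud, validate_bonds = "none"), topoc)$dmax
  brute <- 0
  for (i in 1:49) for (j in (i + 1):50)
    brute <- max(brute, sqrt(sum((cloud[i, ] - cloud[j, ])^2)))
  expect_equal(dm, brute)
})

test_that("arm angle and shape class are absent without two rigid arms", {
  arm <- make_toy_rigid_arm(10L, 30, seed = 1)
  topo <- build_topology(list(segment("rigid", 1L, 10L, "rod", arm)))
  d <- compute_descriptors(arm, topo)
  expect_true(is.na(d$arm_angle))
  expect_true(is.na(d$shape_class))
})

test_that("freely hinged pool Rg and Dmax distributions are near-Gaussian", {
  # scaled down from the nominal 5,000 conformers for runtime; the skewness
  # bound is unchanged
  topo <- tiny_topology(seed = 6)
  pool <- generate_pool(topo, 2000L, cfg, seed = 55)
  d <- pool_descriptors(pool)
  expect_lt(abs(skewness(d$rg)), 0.5)
  expect_lt(abs(skewness(d$dmax)), 0.5)
})

test_that("generator errors are informative", {
  expect_error(generator_config(clash_radius = 4), "below bond_length")
  expect_error(sample_linker(0L, c(0, 0, 0), c(1, 0, 0), cfg), ">= 1")
  topo_noarm <- build_topology(list(segment("rigid", 1L, 10L, "naked")))
  expect_error(generate_conformer(topo_noarm, cfg), "no template")
})
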