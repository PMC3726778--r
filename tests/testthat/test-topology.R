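test_that("hinge residue arithmetic matches the stated boundary definitions", {
  # desmoplakin-style: long polar insertion P627-K663 between the arms
  desmo <- build_topology(list(
    segment("flexible", 580L, 626L, "pre"),
    segment("rigid", 627L, 627L, "x")))
  # direct construction of the hinged architecture
  topo <- build_topology(list(
    segment("rigid", 540L, 626L, "SR3-6"),
    segment("flexible", 627L, 663L, "hinge"),
    segment("rigid", 664L, 750L, "SR78")))
  hinge <- topo$segments[[2L]]
  expect_equal(saxsens:::segment_length(hinge), 37L)
  expect_equal(flexible_length(topo), 37L)

  # periplakin-style hinge P496-L503: brute-force enumeration oracle
  peri <- build_topology(list(
    segment("rigid", 400L, 495L, "SR3-6"),
    segment("flexible", 496L, 503L, "hinge"),
    segment("rigid", 504L, 600L, "SR78")))
  expect_equal(flexible_length(peri), length(seq(496L, 503L)))
  expect_equal(flexible_length(peri), 8L)
})

test_that("degenerate rigid-only topology is valid with zero hinge length", {
  topo <- build_topology(list(segment("rigid", 1L, 100L, "rod")))
  expect_s3_class(topo, "segment_topology")
  expect_equal(topology_length(topo), 100L)
  expect_equal(flexible_length(topo), 0L)
})

test_that("invalid segment lists are rejected with the offending segments named", {
  expect_error(build_topology(list(
    segment("rigid", 1L, 50L, "a"), segment("flexible", 52L, 60L, "b"))),
    "'a'.*'b'")
  expect_error(build_topology(list(
    segment("rigid", 1L, 50L, "a"), segment("flexible", 40L, 60L, "b"))),
    "not contiguous|ascending")
  expect_error(build_topology(list(
    segment("flexible", 1L, 10L, "only-flex"))), "rigid")
  expect_error(segment("flexible", 1L, 5L, "f",
                       template = make_toy_rigid_arm(5L, 15)), "template")
  expect_error(segment("rigid", 1L, 10L, "r",
                       template = make_toy_rigid_arm(5L, 15)), "5 beads")
})

test_that("adjacent flexible segments are merged into one linker", {
  expect_message(
    topo <- build_topology(list(
      segment("rigid", 1L, 10L, "arm"),
      segment("flexible", 11L, 15L, "f1"),
      segment("flexible", 16L, 20L, "f2"))),
    "merged")
  expect_length(topo$segments, 2L)
  expect_equal(saxsens:::segment_length(topo$segments[[2L]]), 10L)
})

test_that("segment lengths always sum to the full residue span", {
  set.seed(7)
  for (rep in 1:20) {
    first <- sample.int(500L, 1L)
    cuts <- sort(sample(5:200, sample(2:6, 1L)))
    bounds <- first + c(0L, cuts)
    kinds <- rep(c("rigid", "flexible"), length.out = length(cuts))
    segs <- lapply(seq_along(cuts), function(i)
      segment(kinds[i], bounds[i], bounds[i + 1L] - 1L, paste0("s", i)))
    topo <- suppressMessages(build_topology(segs))
    last <- topo$segments[[length(topo$segments)]]$end
    expect_equal(topology_length(topo), last - topo$first_residue + 1L)
  }
})

test_that("topology config round-trips through serialization", {
  arm <- make_toy_rigid_arm(20L, 60, seed = 3)
  topo <- build_topology(list(
    segment("rigid", 144L, 163L, "SR3", arm),
    segment("flexible", 164L, 171L, "hinge"),
    segment("rigid", 172L, 191L, "SR78", make_toy_rigid_arm(20L, 60, seed = 4))),
    protein_label = "toy")
  cfg <- tempfile(fileext = ".tsv")
  write_topology_config(topo, cfg)
  back <- read_topology_config(cfg)
  expect_equal(back$protein_label, "toy")
  expect_equal(length(back$segments), length(topo$segments))
  for (i in seq_along(topo$segments)) {
    expect_equal(back$segments[[i]]$kind, topo$segments[[i]]$kind)
    expect_equal(back$segments[[i]]$start, topo$segments[[i]]$start)
    expect_equal(back$segments[[i]]$end, topo$segments[[i]]$end)
  }
  expect_equal(back$segments[[1L]]$template$coordinates,
               topo$segments[[1L]]$template$coordinates, tolerance = 1e-3)
})

test_that("toy arm: minimal chain, determinism and impossibility error", {
  two <- make_toy_rigid_arm(2L, 3.8, radius = 0)
  expect_equal(nrow(two$coordinates), 2L)
  expect_equal(sqrt(sum((two$coordinates[2L, ] - two$coordinates[1L, ])^2)),
               3.8, tolerance = 1e-12)
  a <- make_toy_rigid_arm(30L, 40, seed = 42)
  b <- make_toy_rigid_arm(30L, 40, seed = 42)
  expect_identical(a$coordinates, b$coordinates)
  expect_error(make_toy_rigid_arm(10L, 40), "exceeds")
})

test_that("toy arm Rg matches the analytic cylinder within 10%", {
  # uniform cylinder: Rg^2 = L^2/12 + R^2/2
  arm <- make_toy_rigid_arm(106L, 50, radius = 8, seed = 2)
  topo <- build_topology(list(segment("rigid", 1L, 106L, "arm", arm)))
  d <- compute_descriptors(arm, topo)
  rg_cyl <- sqrt(50^2 / 12 + 8^2 / 2)
  expect_lt(abs(d$rg - rg_cyl) / rg_cyl, 0.10)
})

test_that("toy arm Rg and Dmax scale monotonically with length", {
  lens <- c(60, 90, 120, 150)
  topo_of <- function(m) build_topology(list(segment("rigid", 1L, 50L, "a", m)))
  rgs <- sapply(lens, function(L) {
    m <- make_toy_rigid_arm(50L, L, seed = 5)
    compute_descriptors(m, topo_of(m))$rg
  })
  dmaxs <- sapply(lens, function(L) {
    m <- make_toy_rigid_arm(50L, L, seed = 5)
    compute_descriptors(m, topo_of(m))$dmax
  })
  expect_true(all(diff(rgs) > 0))
  expect_true(all(diff(dmaxs) > 0))
})

test_that("PDB C-alpha reader: read-back, altloc and missing-CA rules", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "N", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", 1, 1.5, 2.0, 2.5),
    pdb_atom_line(3, "CA", 2, 4.5, 2.0, 2.5),
    pdb_atom_line(4, "CA", 3, 7.5, 2.0, 2.5)))
  m <- suppressWarnings(load_pdb_as_beads(p))
  expect_equal(nrow(m$coordinates), 3L)
  expect_equal(m$coordinates[1L, ], c(1.5, 2.0, 2.5))
  expect_equal(m$residue_ids, 1:3)

  # two altlocs on one CA: altloc A (first) kept
  p2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", 1, 0, 0, 0, altloc = "A"),
    pdb_atom_line(2, "CA", 1, 9, 9, 9, altloc = "B"),
    pdb_atom_line(3, "CA", 2, 3.5, 0, 0)))
  m2 <- suppressWarnings(load_pdb_as_beads(p2))
  expect_equal(nrow(m2$coordinates), 2L)
  expect_equal(m2$coordinates[1L, ], c(0, 0, 0))

  # residue lacking CA entirely: skipped with a warning
  p3 <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", 1, 0, 0, 0),
    pdb_atom_line(2, "N", 2, 2, 0, 0),
    pdb_atom_line(3, "CA", 3, 3.5, 0, 0)))
  expect_warning(m3 <- load_pdb_as_beads(p3), "without a C-alpha")
  expect_equal(nrow(m3$coordinates), 2L)

  # chain filter and empty selection
  expect_error(suppressWarnings(load_pdb_as_beads(p, chain_id = "Z")),
               "no ATOM records")
})

test_that("bead models written as PDB round-trip through the reader", {
  arm <- make_toy_rigid_arm(12L, 36, seed = 9)
  f <- tempfile(fileext = ".pdb")
  write_pdb_ca(arm, f)
  back <- load_pdb_as_beads(f)
  expect_equal(back$coordinates, arm$coordinates, tolerance = 1e-3)
})

test_that("bead model validation catches bad geometry", {
  expect_error(bead_model(matrix(c(0, 0, 0, 1, 0, 0), 2L, byrow = TRUE)),
               "outside")
  expect_error(bead_model(matrix(c(0, 0, 0, Inf, 0, 0), 2L, byrow = TRUE),
                          validate_bonds = "none"), "finite")
  expect_warning(bead_model(matrix(c(0, 0, 0, 10, 0, 0), 2L, byrow = TRUE),
                            validate_bonds = "warn"), "outside")
})
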