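#' Declare a synthetic ground-truth scenario
#'
#' Named scenarios emulate the three flexibility phenotypes the pipeline is
#' designed to discriminate: a hinge restricted to right angles
#' (`"L_shape"`), a hinge populating two extremes — folded-back U plus
#' extended I at 75/25 (`"bimodal_UI"`), a freely articulating hinge
#' (`"uniform_flexible"`), and a fully rigid extended rod
#' (`"rigid_linear"`). Arms are toy rods at roughly spectrin-arm scale: a
#' long arm of 160 residues and a short arm of 40, giving extended maximum
#' dimensions in the 200--250 Angstrom regime.
#'
#' @param name One of `"L_shape"`, `"bimodal_UI"`, `"uniform_flexible"`,
#'   `"rigid_linear"`.
#' @param arm1_residues,arm2_residues Long/short rigid arm sizes.
#' @param hinge_residues Flexible hinge length; preset per scenario
#'   (9 for `L_shape`, 37 for `bimodal_UI`, 8 for `uniform_flexible`,
#'   0 for `rigid_linear`, mirroring short plakin-family linkers versus the
#'   long desmoplakin-type insertion).
#' @param ct_residues C-terminal tail length (default 20); flexible in all
#'   scenarios except `rigid_linear`, where it is a rigid rod continuation.
#' @param arm_angle_distribution List describing the hinge-angle law:
#'   `list(type = "point", angle = )`,
#'   `list(type = "truncnorm", mean = , sd = , lower = 0, upper = 180)`,
#'   `list(type = "mixture", angles = , weights = )`, or
#'   `list(type = "uniform", lower = 0, upper = 180)`. Preset per scenario.
#' @param noise_fraction Relative uncertainty sigma/I of the synthetic data
#'   (default 0.02).
#' @param q_grid q grid of the synthetic data (default [default_q_grid()]).
#' @param arm_rise Axial rise per arm residue in Angstrom (default 1.05).
#' @param arm_radius Arm helix radius in Angstrom (default 8).
#' @param seed Integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("L_shape", "bimodal_UI",
                                   "uniform_flexible", "rigid_linear"),
                          arm1_residues = 160L, arm2_residues = 40L,
                          hinge_residues = NULL, ct_residues = 20L,
                          arm_angle_distribution = NULL,
                          noise_fraction = 0.02,
                          q_grid = default_q_grid(),
                          arm_rise = 1.05, arm_radius = 8, seed = 1L) {
  name <- match.arg(name)
  if (is.null(hinge_residues))
    hinge_residues <- switch(name, L_shape = 9L, bimodal_UI = 37L,
                             uniform_flexible = 8L, rigid_linear = 0L)
  if (is.null(arm_angle_distribution))
    arm_angle_distribution <- switch(
      name,
      L_shape = list(type = "truncnorm", mean = 90, sd = 10,
                     lower = 0, upper = 180),
      bimodal_UI = list(type = "mixture", angles = c(20, 170),
                        weights = c(0.75, 0.25)),
      uniform_flexible = list(type = "uniform", lower = 0, upper = 180),
      rigid_linear = list(type = "point", angle = 180))
  if (arm_angle_distribution$type == "mixture" &&
      abs(sum(arm_angle_distribution$weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  if (noise_fraction <= 0) stop("noise_fraction must be positive")
  if (arm1_residues < 2L || arm2_residues < 2L) stop("arms need >= 2 residues")
  structure(list(name = name, arm1_residues = as.integer(arm1_residues),
                 arm2_residues = as.integer(arm2_residues),
                 hinge_residues = as.integer(hinge_residues),
                 ct_residues = as.integer(ct_residues),
                 arm_angle_distribution = arm_angle_distribution,
                 noise_fraction = noise_fraction, q_grid = q_grid,
                 arm_rise = arm_rise, arm_radius = arm_radius,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Fuse rod-like bead models collinearly along the first model's axis, each
# next piece starting one bond beyond the previous last bead.
fuse_collinear <- function(models, bond = 3.8) {
  out <- models[[1L]]$coordinates
  for (k in seq_along(models)[-1L]) {
    ax <- unit_vec(out[nrow(out), ] - out[1L, ])
    tpl <- models[[k]]$coordinates
    rot <- if (nrow(tpl) == 1L) tpl else
      tpl %*% t(align_rotation(tpl[nrow(tpl), ] - tpl[1L, ], ax))
    shift <- out[nrow(out), ] + bond * ax - rot[1L, ]
    out <- rbind(out, sweep(rot, 2L, -shift))
  }
  bead_model(out, validate_bonds = "none")
}

# An alpha-helical spacer rod: 1.5 Angstrom rise per residue on a small
# cylinder so consecutive beads keep ~3.8 Angstrom virtual bonds.
helical_spacer <- function(n_residues, seed = 1L) {
  if (n_residues == 1L)
    return(bead_model(matrix(0, 1L, 3L), validate_bonds = "none"))
  make_toy_rigid_arm(n_residues, length = 1.5 * (n_residues - 1),
                     radius = 2.3, seed = seed)
}

# The two toy arm templates of a scenario.
scenario_arms <- function(spec) {
  list(
    arm1 = make_toy_rigid_arm(spec$arm1_residues,
                              spec$arm_rise * (spec$arm1_residues - 1),
                              spec$arm_radius, seed = derive_seed(spec$seed, 1L)),
    arm2 = make_toy_rigid_arm(spec$arm2_residues,
                              spec$arm_rise * (spec$arm2_residues - 1),
                              spec$arm_radius, seed = derive_seed(spec$seed, 2L)))
}

#' Build the hinged two-arm topology of a scenario
#'
#' Long rigid arm, flexible hinge of the scenario's length, short rigid arm,
#' and (when `ct_residues > 0`) a flexible C-terminal tail. With
#' `hinge_residues = 0` the two arms are fused collinearly into a single
#' rigid body.
#'
#' @param spec A [scenario_spec()].
#' @return A `segment_topology`.
#' @export
make_scenario_topology <- function(spec) {
  arms <- scenario_arms(spec)
  a1 <- spec$arm1_residues; h <- spec$hinge_residues
  a2 <- spec$arm2_residues; ct <- spec$ct_residues
  segs <- if (h > 0L) {
    list(segment("rigid", 1L, a1, "arm1", arms$arm1),
         segment("flexible", a1 + 1L, a1 + h, "hinge"),
         segment("rigid", a1 + h + 1L, a1 + h + a2, "arm2", arms$arm2))
  } else {
    fused <- fuse_collinear(arms)
    list(segment("rigid", 1L, a1 + a2, "arm1+arm2", fused))
  }
  last <- segs[[length(segs)]]$end
  if (ct > 0L) {
    if (spec$name == "rigid_linear") {
      # rigid rod continuation: fuse the tail into the (single) rigid body
      rod <- helical_spacer(ct, seed = derive_seed(spec$seed, 3L))
      fused <- fuse_collinear(c(list(segs[[length(segs)]]$template),
                                list(rod)))
      s0 <- segs[[length(segs)]]
      segs[[length(segs)]] <- segment("rigid", s0$start, last + ct,
                                      paste0(s0$label, "+CT"), fused)
    } else {
      segs <- c(segs, list(segment("flexible", last + 1L, last + ct, "CT")))
    }
  }
  build_topology(segs, protein_label = spec$name)
}

# Draw n hinge angles (degrees) from the scenario's law. For mixtures the
# component counts are exact (round(n * w)), so declared weights are realized.
draw_angles <- function(dist, n) {
  switch(dist$type,
    point = rep(dist$angle, n),
    uniform = runif(n, dist$lower, dist$upper),
    truncnorm = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- rnorm(2L * n, dist$mean, dist$sd)
        out <- c(out, x[x >= dist$lower & x <= dist$upper])
      }
      out[seq_len(n)]
    },
    mixture = {
      counts <- round(n * dist$weights)
      counts[1L] <- n - sum(counts[-1L])
      sample(rep(dist$angles, counts))
    },
    stop("unknown angle distribution type: ", dist$type))
}

# Build one conformer whose hinge opening angle equals `angle` (degrees):
# arm1 is placed as template, the hinge linker sampled, and arm2 attached so
# that the angle between the outward arm axes is exactly the target, with a
# uniformly random azimuth about arm1's axis. CT tail sampled freely.
realize_angle_conformer <- function(topology, angle, config) {
  segs <- topology$segments
  rig <- rigid_segments(topology)
  if (length(rig) < 2L) {
    if (abs(angle - 180) > 2)
      stop(sprintf("angle %.0f unrealizable: single fused rigid body", angle))
    return(generate_conformer(topology, config))
  }
  arm1 <- segs[[rig[1L]]]$template
  arm2 <- segs[[rig[2L]]]$template
  hinge_n <- segment_length(segs[[2L]])
  ct_n <- if (length(segs) >= 4L) segment_length(segs[[4L]]) else 0L
  a1c <- arm1$coordinates
  out1 <- unit_vec(a1c[1L, ] - a1c[nrow(a1c), ])   # arm1 outward axis
  for (attempt in seq_len(config$max_retries)) {
    linker <- sample_linker(hinge_n, a1c[nrow(a1c), ],
                            unit_vec(a1c[nrow(a1c), ] - a1c[nrow(a1c) - 1L, ]),
                            config,
                            anchor_prev = a1c[nrow(a1c) - 1L, ])
    # target outward direction for arm2 at `angle` from out1, random azimuth
    fr <- perp_frame(out1)
    phi <- runif(1L, 0, 2 * pi)
    b <- out1 * cos(angle * pi / 180) +
      (fr$n1 * cos(phi) + fr$n2 * sin(phi)) * sin(angle * pi / 180)
    tpl <- arm2$coordinates
    R <- align_rotation(tpl[nrow(tpl), ] - tpl[1L, ], b)
    spin <- rotation_axis_angle(b, runif(1L, 0, 2 * pi))
    rot <- tpl %*% t(spin %*% R)
    anchor <- linker[nrow(linker), ]
    shift <- anchor + config$bond_length * b - rot[1L, ]
    placed2 <- sweep(rot, 2L, -shift)
    coords <- rbind(a1c, linker, placed2)
    if (ct_n > 0L) {
      tail <- sample_linker(ct_n, coords[nrow(coords), ],
                            unit_vec(coords[nrow(coords), ] -
                                       coords[nrow(coords) - 1L, ]),
                            config,
                            anchor_prev = coords[nrow(coords) - 1L, ])
      coords <- rbind(coords, tail)
    }
    if (!chain_self_clashes(coords, config$clash_radius)) {
      model <- bead_model(coords, validate_bonds = "none")
      model$residue_ids <- seq.int(topology$first_residue,
                                   length.out = nrow(coords))
      return(new_conformer(model, topology))
    }
  }
  stop(sprintf("could not realize hinge angle %.0f within %d retries",
               angle, config$max_retries))
}

#' Simulate a ground-truth ensemble with a declared hinge-angle law
#'
#' Conformers are built so the hinge opening angle matches draws from the
#' declared distribution (realized exactly via the arm axes, well within the
#' 2-degree target). Mixture components use exact counts, so the declared
#' weights are the true mixture weights. Returns a `conformer_pool` carrying
#' equal per-conformer weights plus the realized angles and component labels.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of ground-truth conformers (default 200).
#' @param config A [generator_config()].
#' @return A `conformer_pool` with extra fields `weights`, `true_angles`,
#'   `components`.
#' @export
simulate_true_ensemble <- function(spec, n = 200L,
                                   config = generator_config()) {
  topology <- make_scenario_topology(spec)
  dist <- spec$arm_angle_distribution
  if (spec$hinge_residues == 0L &&
      (dist$type != "point" || abs(dist$angle - 180) > 2))
    stop("hinge of length 0 admits only the fused 180-degree geometry")
  angles <- with_seed(derive_seed(spec$seed, 0L, salt = 11L),
                      draw_angles(dist, n))
  conformers <- vector("list", n)
  for (i in seq_len(n)) {
    conformers[[i]] <- with_seed(
      derive_seed(spec$seed, i, salt = 11L),
      realize_angle_conformer(topology, angles[i], config))
  }
  components <- if (dist$type == "mixture")
    match(angles, dist$angles) else rep(1L, n)
  structure(list(conformers = conformers, topology = topology,
                 seed = spec$seed, config = config, curves = NULL, q = NULL,
                 weights = rep(1 / n, n), true_angles = angles,
                 components = components),
            class = "conformer_pool")
}

#' Synthesize an experimental-style SAXS curve from a true ensemble
#'
#' The weighted-average Debye curve of the ensemble is perturbed with
#' independent Gaussian noise of standard deviation
#' sigma(q) = noise_fraction * I(q) + floor, with
#' floor = noise_fraction * I(q_max) / 10, emulating a subtracted beamline
#' profile with a small additive error floor. Rare negative draws are
#' resampled so intensities stay positive.
#'
#' @param true_ensemble A `conformer_pool` (weights default to equal).
#' @param spec A [scenario_spec()] providing grid, noise level and seed.
#' @param seed Optional seed override for the noise stream.
#' @return A `scattering_curve` with `sigma`.
#' @export
synthesize_saxs <- function(true_ensemble, spec, seed = NULL) {
  if (is.null(true_ensemble$curves) ||
      !isTRUE(all.equal(true_ensemble$q, spec$q_grid)))
    true_ensemble <- precompute_curves(true_ensemble, spec$q_grid)
  w <- true_ensemble$weights
  if (is.null(w)) w <- rep(1 / ncol(true_ensemble$curves),
                           ncol(true_ensemble$curves))
  avg <- as.vector(true_ensemble$curves %*% w)
  nf <- spec$noise_fraction
  sigma <- nf * avg + nf * avg[length(avg)] / 10
  noisy <- with_seed(
    if (is.null(seed)) derive_seed(spec$seed, 0L, salt = 13L) else seed, {
      x <- avg + rnorm(length(avg), 0, sigma)
      while (any(x <= 0)) {
        bad <- x <= 0
        x[bad] <- avg[bad] + rnorm(sum(bad), 0, sigma[bad])
      }
      x
    })
  scattering_curve(spec$q_grid, noisy, sigma = sigma,
                   label = sprintf("synthetic %s", spec$name))
}

#' Exact (noise-free) ensemble-average curve of a true ensemble
#'
#' @param true_ensemble A `conformer_pool` with `weights`.
#' @param q_grid q grid.
#' @return A `scattering_curve` without noise or sigma.
#' @export
true_average_curve <- function(true_ensemble, q_grid = default_q_grid()) {
  if (is.null(true_ensemble$curves) ||
      !isTRUE(all.equal(true_ensemble$q, q_grid)))
    true_ensemble <- precompute_curves(true_ensemble, q_grid)
  w <- true_ensemble$weights
  if (is.null(w)) w <- rep(1 / ncol(true_ensemble$curves),
                           ncol(true_ensemble$curves))
  scattering_curve(q_grid, as.vector(true_ensemble$curves %*% w),
                   label = "true ensemble average")
}

#' Fabricate a complete synthetic experiment
#'
#' Ground-truth ensemble plus its noisy experimental-style curve.
#'
#' @param spec A [scenario_spec()].
#' @param n_true Number of ground-truth conformers.
#' @param config A [generator_config()].
#' @return List with `true_ensemble`, `data` and `scenario` (class
#'   `synthetic_experiment`).
#' @export
make_synthetic_experiment <- function(spec, n_true = 200L,
                                      config = generator_config()) {
  ens <- simulate_true_ensemble(spec, n_true, config)
  ens <- precompute_curves(ens, spec$q_grid)
  data <- synthesize_saxs(ens, spec)
  structure(list(true_ensemble = ens, data = data, scenario = spec),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment as a fixture directory
#'
#' Topology config, pool descriptors, the noisy `.dat` curve and a truth
#' manifest (weights, angles, seed) in JSON.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory.
#' @export
save_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_topology_config(experiment$true_ensemble$topology,
                        file.path(dir, "topology.tsv"))
  utils::write.table(pool_descriptors(experiment$true_ensemble),
                     file.path(dir, "truth_descriptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_saxs_dat(experiment$data, file.path(dir, "data.dat"),
                 comment = sprintf("scenario %s, noise %.3f",
                                   experiment$scenario$name,
                                   experiment$scenario$noise_fraction))
  jsonlite::write_json(
    list(scenario = experiment$scenario$name,
         seed = experiment$scenario$seed,
         noise_fraction = experiment$scenario$noise_fraction,
         weights = experiment$true_ensemble$weights,
         angles = experiment$true_ensemble$true_angles,
         components = experiment$true_ensemble$components),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
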