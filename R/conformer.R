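#' Sampling parameters for the conformer generator
#'
#' Flexible linkers are sampled as virtual-bond C-alpha chains: fixed bond
#' length, pseudo-bond angles drawn uniformly from a coil-like window, and
#' uniform torsions. Clashes are hard spheres; sequence-adjacent beads are
#' exempt.
#'
#' @param bond_length Virtual C-alpha bond length in Angstrom (default 3.8).
#' @param pseudo_angle_range Pseudo-bond angle window in degrees
#'   (default `c(80, 150)`).
#' @param clash_radius Minimum distance between non-adjacent beads in
#'   Angstrom (default 3.0; must be below `bond_length`).
#' @param max_retries Whole-conformer (or whole-linker) resampling budget
#'   (default 100).
#' @param inter_arm_clash Also check clashes between different segments, not
#'   only within linkers (default TRUE).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(bond_length = 3.8,
                             pseudo_angle_range = c(80, 150),
                             clash_radius = 3.0,
                             max_retries = 100L,
                             inter_arm_clash = TRUE) {
  if (bond_length <= 0) stop("bond_length must be positive")
  if (clash_radius >= bond_length)
    stop("clash_radius must be below bond_length")
  if (length(pseudo_angle_range) != 2L ||
      pseudo_angle_range[1L] > pseudo_angle_range[2L])
    stop("pseudo_angle_range must be an ascending pair of degrees")
  structure(list(bond_length = bond_length,
                 pseudo_angle_range = pseudo_angle_range,
                 clash_radius = clash_radius,
                 max_retries = as.integer(max_retries),
                 inter_arm_clash = isTRUE(inter_arm_clash)),
            class = "generator_config")
}

# Self-clash test: any pair separated by >= 2 positions closer than radius?
chain_self_clashes <- function(coords, radius) {
  n <- nrow(coords)
  if (n < 3L) return(FALSE)
  d <- as.matrix(stats::dist(coords))
  d[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- Inf
  diag(d) <- Inf
  min(d) < radius
}

#' Sample a flexible linker as a self-avoiding virtual-bond chain
#'
#' Grows `n_residues` beads from an anchor point: consecutive distances equal
#' the configured bond length, pseudo-bond angles are uniform in the
#' configured window and torsions uniform on `[0, 360)`. The whole linker is
#' resampled until self-clash-free (beads >= 2 positions apart at least
#' `clash_radius` from each other).
#'
#' @param n_residues Number of linker beads (>= 1).
#' @param anchor_position XYZ of the bead preceding the linker.
#' @param anchor_direction Unit-ish direction of the bond entering the
#'   anchor; the first linker bead is angle-sampled against it when
#'   `anchor_prev` is `NULL`, otherwise placed along it.
#' @param config A [generator_config()].
#' @param anchor_prev Optional XYZ of the bead before the anchor; when given,
#'   the first linker bead is sampled with the same angle window as interior
#'   beads.
#' @return Matrix `n_residues` x 3 of bead coordinates.
#' @export
sample_linker <- function(n_residues, anchor_position,
                          anchor_direction = c(1, 0, 0),
                          config = generator_config(),
                          anchor_prev = NULL) {
  if (n_residues < 1L) stop("n_residues must be >= 1")
  b <- config$bond_length
  ang <- config$pseudo_angle_range * pi / 180
  place_next <- function(A, B) {
    # next bead C with pseudo-bond angle at B in the window, torsion uniform
    theta <- runif(1L, ang[1L], ang[2L])
    phi <- runif(1L, 0, 2 * pi)
    u <- unit_vec(B - A)
    fr <- perp_frame(u)
    d <- u * cos(pi - theta) +
      (fr$n1 * cos(phi) + fr$n2 * sin(phi)) * sin(pi - theta)
    B + b * d
  }
  for (attempt in seq_len(config$max_retries)) {
    coords <- matrix(0, n_residues, 3L)
    if (is.null(anchor_prev)) {
      coords[1L, ] <- anchor_position + b * unit_vec(anchor_direction)
    } else {
      coords[1L, ] <- place_next(anchor_prev, anchor_position)
    }
    if (n_residues >= 2L)
      coords[2L, ] <- place_next(anchor_position, coords[1L, ])
    if (n_residues >= 3L)
      for (i in 3:n_residues)
        coords[i, ] <- place_next(coords[i - 2L, ], coords[i - 1L, ])
    if (!chain_self_clashes(coords, config$clash_radius)) return(coords)
  }
  stop(sprintf("linker sampling: retry budget (%d) exhausted for %d residues",
               config$max_retries, n_residues))
}

# Assemble one chain realization from a topology. Returns the coordinate
# matrix or NULL on clash rejection.
assemble_chain_once <- function(topology, config) {
  segs <- topology$segments
  pieces <- vector("list", length(segs))
  coords_prev_tail <- NULL   # last two placed beads (matrix rows)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (s$kind == "flexible") {
      if (is.null(coords_prev_tail)) {
        # N-terminal tail: grow from the origin in a random direction
        pieces[[k]] <- sample_linker(segment_length(s), c(0, 0, 0),
                                     random_direction(), config)
      } else {
        anchor <- coords_prev_tail[nrow(coords_prev_tail), ]
        prev <- if (nrow(coords_prev_tail) >= 2L)
          coords_prev_tail[nrow(coords_prev_tail) - 1L, ] else NULL
        pieces[[k]] <- sample_linker(segment_length(s), anchor,
                                     if (is.null(prev)) random_direction()
                                     else unit_vec(anchor - prev),
                                     config, anchor_prev = prev)
      }
    } else {
      if (is.null(s$template))
        stop("rigid segment '", s$label, "' has no template")
      tpl <- s$template$coordinates
      if (is.null(coords_prev_tail)) {
        placed <- tpl                                  # first body: as-is
      } else {
        anchor <- coords_prev_tail[nrow(coords_prev_tail), ]
        prev_seg_kind <- segs[[k - 1L]]$kind
        if (prev_seg_kind == "flexible") {
          # free articulation: uniform random orientation, attached one bond
          # away from the linker end in a uniform random direction
          R <- random_rotation()
          d <- random_direction()
        } else {
          # rigid following rigid with no linker: continue collinearly
          ax <- unit_vec(anchor - coords_prev_tail[1L, ])
          R <- align_rotation(tpl[nrow(tpl), ] - tpl[1L, ], ax)
          d <- ax
        }
        rot <- tpl %*% t(R)
        shift <- anchor + config$bond_length * d - rot[1L, ]
        placed <- sweep(rot, 2L, -shift)
      }
      pieces[[k]] <- placed
    }
    pc <- pieces[[k]]
    coords_prev_tail <- pc[max(1L, nrow(pc) - 1L):nrow(pc), , drop = FALSE]
  }
  coords <- do.call(rbind, pieces)
  if (config$inter_arm_clash && chain_self_clashes(coords, config$clash_radius))
    return(NULL)
  coords
}

#' Generate one random conformer of a rigid/flexible topology
#'
#' Rigid segments move as rigid bodies (internal geometry identical to their
#' templates); flexible segments are freshly sampled; a rigid body following
#' a linker is attached with a uniformly random orientation. The whole chain
#' is rejected and resampled on any hard-sphere clash.
#'
#' @param topology A `segment_topology` with templates on all rigid segments.
#' @param config A [generator_config()].
#' @return An object of class `conformer`: the full-chain `bead_model` plus
#'   descriptors `rg`, `dmax`, `end_to_end`, `arm_angle`, `shape_class`.
#' @export
generate_conformer <- function(topology, config = generator_config()) {
  for (attempt in seq_len(config$max_retries)) {
    coords <- assemble_chain_once(topology, config)
    if (!is.null(coords)) {
      model <- bead_model(coords, validate_bonds = "none")
      model$residue_ids <- seq.int(topology$first_residue,
                                   length.out = n_beads(model))
      return(new_conformer(model, topology))
    }
  }
  stop(sprintf("conformer generation: clash rejection exceeded %d retries",
               config$max_retries))
}

new_conformer <- function(model, topology) {
  d <- compute_descriptors(model, topology)
  structure(c(list(model = model), d), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf(
    "<conformer> %d beads  Rg %.1f A  Dmax %.1f A  end-to-end %.1f A  angle %s  class %s\n",
    n_beads(x$model), x$rg, x$dmax, x$end_to_end,
    if (is.na(x$arm_angle)) "-" else sprintf("%.0f deg", x$arm_angle),
    if (is.na(x$shape_class)) "-" else x$shape_class))
  invisible(x)
}

#' Shape descriptors of a full-chain bead model
#'
#' `rg` is the weight-averaged root-mean-square distance from the centroid;
#' `dmax` the maximum pairwise bead distance; `end_to_end` the distance from
#' the first bead of the first rigid segment to the last bead of the last
#' rigid segment. `arm_angle` is the hinge opening angle: the angle between
#' the two arm axes pointing *away* from the hinge, so collinear extended
#' arms score 180 degrees and fully folded-back arms 0. Shape classes:
#' I (extended) above 120 degrees, L between 60 and 120, U below 60.
#' With fewer than two rigid segments, `arm_angle` and `shape_class` are `NA`.
#'
#' @param model Full-chain `bead_model` matching the topology's bead count.
#' @param topology The `segment_topology` the chain realizes.
#' @return List with `rg`, `dmax`, `end_to_end`, `arm_angle`, `shape_class`.
#' @export
compute_descriptors <- function(model, topology) {
  x <- model$coordinates
  if (nrow(x) != topology_length(topology))
    stop("model bead count does not match topology")
  w <- model$weights
  ctr <- colSums(x * w) / sum(w)
  rg <- sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)) / sum(w))
  dmax <- if (nrow(x) >= 2L) max(stats::dist(x)) else 0
  idx <- segment_bead_indices(topology)
  rig <- rigid_segments(topology)
  first_r <- idx[[rig[1L]]]
  last_r <- idx[[rig[length(rig)]]]
  end_to_end <- sqrt(sum((x[last_r[length(last_r)], ] - x[first_r[1L], ])^2))
  arm_angle <- NA_real_; shape_class <- NA_character_
  if (length(rig) >= 2L) {
    # outward-pointing axes: arm 1 from its hinge-proximal end to its free
    # end, arm 2 likewise
    a <- x[first_r[1L], ] - x[first_r[length(first_r)], ]
    b <- x[last_r[length(last_r)], ] - x[last_r[1L], ]
    arm_angle <- vector_angle_deg(a, b)
    shape_class <- classify_angle(arm_angle)
  }
  list(rg = rg, dmax = dmax, end_to_end = end_to_end,
       arm_angle = arm_angle, shape_class = shape_class)
}

classify_angle <- function(angle) {
  ifelse(is.na(angle), NA_character_,
         ifelse(angle > 120, "I", ifelse(angle >= 60, "L", "U")))
}

#' Generate a random pool of conformers
#'
#' Each conformer is drawn under its own deterministic RNG substream derived
#' from `seed` and the conformer index, so pools are reproducible and
#' order-independent.
#'
#' @param topology A `segment_topology` with templates on rigid segments.
#' @param n Pool size (the headline analysis uses 10,000).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return An object of class `conformer_pool`.
#' @export
generate_pool <- function(topology, n, config = generator_config(),
                          seed = 1L) {
  if (n < 1L) stop("pool size must be >= 1")
  conformers <- vector("list", n)
  for (i in seq_len(n)) {
    conformers[[i]] <- tryCatch(
      with_seed(derive_seed(seed, i), generate_conformer(topology, config)),
      error = function(e)
        stop(sprintf("conformer %d: %s", i, conditionMessage(e)),
             call. = FALSE))
  }
  structure(list(conformers = conformers, topology = topology,
                 seed = as.integer(seed), config = config,
                 curves = NULL, q = NULL),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  d <- pool_descriptors(x)
  cat(sprintf(
    "<conformer_pool> %d conformers of %s (seed %d)%s\n  Rg %.1f-%.1f A (median %.1f), Dmax %.1f-%.1f A\n",
    nrow(d), if (nzchar(x$topology$protein_label)) x$topology$protein_label
    else "(unnamed topology)", x$seed,
    if (is.null(x$curves)) "" else ", curves cached",
    min(d$rg), max(d$rg), stats::median(d$rg), min(d$dmax), max(d$dmax)))
  invisible(x)
}

#' Descriptor table of a conformer pool
#' @param pool A `conformer_pool`.
#' @return data.frame with columns `index`, `rg`, `dmax`, `end_to_end`,
#'   `arm_angle`, `shape_class`.
#' @export
pool_descriptors <- function(pool) {
  data.frame(
    index = seq_along(pool$conformers),
    rg = vapply(pool$conformers, `[[`, 0, "rg"),
    dmax = vapply(pool$conformers, `[[`, 0, "dmax"),
    end_to_end = vapply(pool$conformers, `[[`, 0, "end_to_end"),
    arm_angle = vapply(pool$conformers, `[[`, 0, "arm_angle"),
    shape_class = vapply(pool$conformers, `[[`, "", "shape_class"))
}

#' Cache theoretical scattering curves for every pool member
#'
#' @param pool A `conformer_pool`.
#' @param q_grid Ascending q grid in inverse Angstrom.
#' @param method Debye evaluation mode, see [debye_intensity()].
#' @return The pool with a `curves` matrix (rows = q points, columns =
#'   conformers) and the grid stored.
#' @export
precompute_curves <- function(pool, q_grid = default_q_grid(),
                              method = "hist") {
  curves <- vapply(pool$conformers, function(cf)
    debye_intensity(cf$model, q_grid, method = method)$intensity,
    numeric(length(q_grid)))
  pool$curves <- matrix(curves, nrow = length(q_grid))
  pool$q <- q_grid
  pool
}

#' Persist a pool as a multi-model PDB plus a descriptor table
#'
#' @param pool A `conformer_pool`.
#' @param dir Output directory (created if needed).
#' @export
save_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "pool.pdb")
  if (file.exists(pdb)) file.remove(pdb)
  for (i in seq_along(pool$conformers))
    write_pdb_ca(pool$conformers[[i]]$model, pdb, model_number = i)
  utils::write.table(pool_descriptors(pool),
                     file.path(dir, "descriptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
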