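#' Coarse-grained bead model of a polypeptide
#'
#' One bead per residue at the C-alpha position, with a per-bead scattering
#' weight. This is the only structural representation used by the package:
#' rigid arms, flexible linkers and full-chain conformers are all bead chains.
#'
#' @param coordinates Numeric matrix with one row per bead and columns x, y, z
#'   in Angstrom.
#' @param weights Per-bead dimensionless scattering weights; default 1.
#' @param residue_ids Integer residue identifiers in chain numbering; default
#'   `1:n`.
#' @param validate_bonds One of `"error"`, `"warn"`, `"none"`: how to react
#'   when a consecutive bead distance falls outside the virtual C-alpha bond
#'   window of 2.8--4.2 Angstrom. Chain-derived models should use `"error"`;
#'   PDB-derived models may contain chain breaks and use `"warn"`.
#'
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(coordinates, weights = NULL, residue_ids = NULL,
                       validate_bonds = c("error", "warn", "none")) {
  validate_bonds <- match.arg(validate_bonds)
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be an n x 3 matrix")
  n <- nrow(coordinates)
  if (n < 1L) stop("bead model needs at least one bead")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must match bead count")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (length(residue_ids) != n) stop("residue_ids length must match bead count")
  if (validate_bonds != "none" && n >= 2L) {
    d <- sqrt(rowSums((coordinates[-1L, , drop = FALSE] -
                         coordinates[-n, , drop = FALSE])^2))
    bad <- which(d < 2.8 | d > 4.2)
    if (length(bad)) {
      msg <- sprintf(
        "%d consecutive bead distance(s) outside [2.8, 4.2] Angstrom (first at bead %d: %.2f)",
        length(bad), bad[1L], d[bad[1L]])
      if (validate_bonds == "error") stop(msg) else warning(msg, call. = FALSE)
    }
  }
  structure(
    list(coordinates = unname(coordinates), weights = as.numeric(weights),
         residue_ids = as.integer(residue_ids)),
    class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads, residues %d..%d, total weight %.1f\n",
              nrow(x$coordinates), x$residue_ids[1L],
              x$residue_ids[length(x$residue_ids)], sum(x$weights)))
  invisible(x)
}

n_beads <- function(model) nrow(model$coordinates)

# First -> last bead vector; used as the arm axis of rod-like segments.
model_axis <- function(model) {
  n <- n_beads(model)
  model$coordinates[n, ] - model$coordinates[1L, ]
}

# Apply rotation R (3x3) and translation t to a bead model.
transform_model <- function(model, R = diag(3L), t = c(0, 0, 0)) {
  model$coordinates <- sweep(model$coordinates %*% t(R), 2L, -t)
  model
}

#' Generate a toy rigid arm as a helical trace on a cylinder
#'
#' Stand-in for rod-like multi-spectrin-repeat arm templates: beads are traced
#' along a helix of the given radius so the axial extent (first to last bead
#' along the axis) equals `length` while consecutive beads sit ~3.8 Angstrom
#' apart, the virtual C-alpha bond. With `radius = 0` beads lie on the axis at
#' spacing `length / (n - 1)`.
#'
#' @param n_residues Number of beads (>= 2).
#' @param length Axial extent in Angstrom; must not exceed `3.8 * (n - 1)`.
#' @param radius Cylinder radius in Angstrom (default 8, roughly a
#'   three-helix-bundle cross-section).
#' @param seed Integer seed fixing the helical phase; same seed gives
#'   identical coordinates.
#' @return A `bead_model` whose axis lies along +x starting at the origin.
#' @export
make_toy_rigid_arm <- function(n_residues, length, radius = 8, seed = 1L) {
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (length <= 0) stop("length must be positive")
  bond <- 3.8
  if (length > bond * (n_residues - 1) + 1e-9)
    stop(sprintf("length %.1f exceeds the maximal extent %.1f of %d beads",
                 length, bond * (n_residues - 1), n_residues))
  h <- length / (n_residues - 1)          # axial rise per bead
  i <- seq_len(n_residues) - 1
  if (radius <= 0) {
    coords <- cbind(i * h, 0, 0)
    return(bead_model(coords, validate_bonds = "none"))
  }
  chord2 <- bond^2 - h^2                   # lateral chord needed for 3.8 bonds
  if (chord2 > (2 * radius)^2)
    stop(sprintf(
      "radius %.1f too small to keep %.1f Angstrom bonds at rise %.2f; need >= %.2f",
      radius, bond, h, sqrt(chord2) / 2))
  dphi <- 2 * asin(sqrt(chord2) / (2 * radius))
  phi0 <- with_seed(seed, runif(1L, 0, 2 * pi))
  phi <- phi0 + i * dphi
  coords <- cbind(i * h, radius * cos(phi), radius * sin(phi))
  bead_model(coords)
}

#' Read C-alpha beads from a PDB file
#'
#' ATOM records only; first model of multi-model files; first altloc per
#' residue. One bead per residue at the C-alpha position; residues lacking a
#' C-alpha are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain_id Optional single chain identifier to select.
#' @return A `bead_model` with residue numbering taken from the file.
#' @export
load_pdb_as_beads <- function(path, chain_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM")]
  if (!is.null(chain_id))
    atoms <- atoms[substr(atoms, 22L, 22L) == chain_id]
  if (!length(atoms)) stop("no ATOM records selected from ", path)
  resseq <- substr(atoms, 23L, 26L)
  icode <- substr(atoms, 27L, 27L)
  reskey <- paste0(substr(atoms, 22L, 22L), resseq, icode)
  res_order <- unique(reskey)
  name <- trimws(substr(atoms, 13L, 16L))
  is_ca <- name == "CA"
  coords <- matrix(NA_real_, length(res_order), 3L)
  ids <- integer(length(res_order))
  for (k in seq_along(res_order)) {
    sel <- which(reskey == res_order[k] & is_ca)
    if (!length(sel)) next                       # residue without C-alpha
    j <- sel[1L]                                  # first altloc kept
    coords[k, ] <- c(as.numeric(substr(atoms[j], 31L, 38L)),
                     as.numeric(substr(atoms[j], 39L, 46L)),
                     as.numeric(substr(atoms[j], 47L, 54L)))
    ids[k] <- as.integer(trimws(resseq[match(res_order[k], reskey)]))
  }
  keep <- !is.na(coords[, 1L])
  if (!any(keep)) stop("no C-alpha atoms found in ", path)
  if (any(!keep))
    warning(sprintf("%d residue(s) without a C-alpha record skipped",
                    sum(!keep)), call. = FALSE)
  bead_model(coords[keep, , drop = FALSE], residue_ids = ids[keep],
             validate_bonds = "warn")
}

#' Write a bead model as a C-alpha-only PDB file
#'
#' One `ATOM` record (atom name CA, residue GLY) per bead, for visual
#' inspection in molecular viewers. With `model_number` set, records are
#' wrapped in `MODEL`/`ENDMDL` and appended, which is how conformer pools are
#' persisted as multi-model PDBs.
#'
#' @param model A `bead_model`.
#' @param path Output file path.
#' @param model_number Optional integer; write as that model number and append.
#' @export
write_pdb_ca <- function(model, path, model_number = NULL) {
  n <- n_beads(model)
  recs <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, model$residue_ids %% 10000L,
    model$coordinates[, 1L], model$coordinates[, 2L], model$coordinates[, 3L])
  if (is.null(model_number)) {
    writeLines(c(recs, "END"), path)
  } else {
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(c(sprintf("MODEL     %4d", model_number), recs, "ENDMDL"), con)
  }
  invisible(path)
}
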