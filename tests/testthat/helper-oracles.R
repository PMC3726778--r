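# Independent oracles and small fixtures shared across test files.

# Analytic uniform-sphere form factor, normalized to 1 at q = 0.
sphere_form_factor <- function(q, R) {
  x <- q * R
  out <- rep(1, length(q))
  nz <- x > 1e-8
  out[nz] <- (3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3)^2
  out
}

# N beads uniformly filling a sphere of radius R (exact radial inversion).
sphere_bead_cloud <- function(n, R, seed = 1) {
  set.seed(seed)
  r <- R * runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  bead_model(u * r, validate_bonds = "none")
}

# Golden-section minimizer: independent 1-D oracle for the analytic scale.
golden_minimize <- function(f, lo, hi, tol = 1e-12) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - phi * (b - a); d <- a + phi * (b - a)
  }
  (a + b) / 2
}

# Small two-arm scenario used where full scale is not needed.
tiny_spec <- function(name = "bimodal_UI", seed = 1, ...) {
  scenario_spec(name, arm1_residues = 40L, arm2_residues = 16L,
                hinge_residues = if (name == "rigid_linear") 0L else 8L,
                ct_residues = 4L, seed = seed, ...)
}

tiny_topology <- function(seed = 1) make_scenario_topology(tiny_spec(seed = seed))

# Hand-built PDB fixture text; altloc goes in column 17.
pdb_atom_line <- function(serial, name, resseq, x, y, z, altloc = " ",
                          chain = "A", resname = "GLY") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", name), altloc, resname, chain, resseq, x, y, z)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Sample skewness.
skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# All multisets of size m from 1..n (columns of a matrix), for exhaustive
# GA oracles.
multisets <- function(n, m) {
  grid <- do.call(expand.grid, rep(list(seq_len(n)), m))
  keep <- apply(grid, 1L, function(r) all(diff(r) >= 0))
  t(as.matrix(grid[keep, , drop = FALSE]))
}
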