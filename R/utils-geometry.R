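# Internal geometry and RNG helpers shared by the sampling modules.

#' @keywords internal
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# Rodrigues rotation matrix about `axis` (need not be unit) by `theta` radians.
#' @keywords internal
rotation_axis_angle <- function(axis, theta) {
  u <- unit_vec(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# Rotation carrying direction `a` onto direction `b` (minimal-angle rotation).
#' @keywords internal
align_rotation <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3L))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to a
    perp <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit_vec(perp - sum(perp * a) * a)
    return(rotation_axis_angle(axis, pi))
  }
  rotation_axis_angle(pracma_cross(a, b), acos(max(-1, min(1, d))))
}

#' @keywords internal
pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Uniform random rotation matrix (unit quaternion from 4 standard normals).
#' @keywords internal
random_rotation <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

# Uniform random unit vector.
#' @keywords internal
random_direction <- function() unit_vec(rnorm(3L))

# Two unit vectors completing `u` to an orthonormal frame.
#' @keywords internal
perp_frame <- function(u) {
  u <- unit_vec(u)
  p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- unit_vec(p - sum(p * u) * u)
  n2 <- pracma_cross(u, n1)
  list(n1 = n1, n2 = n2)
}

# Angle in degrees between two vectors.
#' @keywords internal
vector_angle_deg <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed below 2^31, so per-item streams are independent
# of evaluation order.
#' @keywords internal
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(index) * 10007 + as.double(salt) * 65537
  as.integer(s %% 2147483646) + 1L
}
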