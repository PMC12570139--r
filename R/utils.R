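# Internal geometry and RNG helpers shared across modules.

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a^2))

# Wrap angles (degrees) to [-180, 180).
wrap_deg <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out >= 180] <- out[out >= 180] - 360
  out
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four points (or four matched sets of
#' points, one row per observation) using the atan2 normal-vector formula, in
#' degrees wrapped to `[-180, 180)`. Near-collinear defining atoms yield `NA`.
#'
#' @param p1,p2,p3,p4 Numeric vectors of length 3 or `n x 3` matrices.
#' @return Numeric vector of dihedral angles in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  b2u <- b2 / row_norm(b2)
  m1 <- row_cross(n1, b2u)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # degenerate (collinear) configurations: normal vectors vanish
  bad <- row_norm(n1) < 1e-9 | row_norm(n2) < 1e-9
  ang[bad] <- NA_real_
  wrap_deg(ang)
}

# Rotate rows of v (n x 3) about unit axis k by angles theta (radians),
# Rodrigues' formula.
rotate_about_axis <- function(v, k, theta) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3)
  k <- k / sqrt(sum(k^2))
  kv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  kdv <- as.numeric(v %*% k)
  ct <- cos(theta); st <- sin(theta)
  v * ct + kv * st + outer(kdv * (1 - ct), k)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
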