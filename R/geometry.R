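# Closed-form sphere geometry and deterministic low-discrepancy point sets.
# These primitives back both the analytic fast path of compute_restrictions()
# and the fixture truths.

#' Volume of a sphere
#' @param r radius (Angstrom)
#' @return volume in Angstrom^3
#' @export
sphere_volume <- function(r) 4 / 3 * pi * r^3

#' Spherical cap volume and area
#'
#' The cap of a sphere of radius `r` cut by a plane at signed distance `h`
#' from the center, on the far side of the plane (`h = r` gives an empty cap,
#' `h = -r` the full ball/sphere).
#'
#' @param r sphere radius (Angstrom)
#' @param h signed plane-center distance (Angstrom), in `[-r, r]`
#' @return volume (`sphere_cap_volume`) in Angstrom^3 or lateral spherical
#'   area (`sphere_cap_area`) in Angstrom^2
#' @export
sphere_cap_volume <- function(r, h) {
  stopifnot(all(abs(h) <= r + 1e-12))
  a <- pmin(pmax(r - h, 0), 2 * r) # cap height
  pi * a^2 * (3 * r - a) / 3
}

#' @rdname sphere_cap_volume
#' @export
sphere_cap_area <- function(r, h) {
  stopifnot(all(abs(h) <= r + 1e-12))
  a <- pmin(pmax(r - h, 0), 2 * r)
  2 * pi * r * a
}

#' Two-sphere intersection (lens) volume
#'
#' Computed as the sum of the two caps cut by the radical plane, which for
#' overlapping spheres contains the intersection circle.
#'
#' @param r1,r2 radii (Angstrom)
#' @param d center distance (Angstrom)
#' @return intersection volume in Angstrom^3 (0 if disjoint; volume of the
#'   smaller ball if contained)
#' @export
sphere_lens_volume <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d + r1 <= r2) return(sphere_volume(r1))
  if (d + r2 <= r1) return(sphere_volume(r2))
  h1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- d - h1
  sphere_cap_volume(r1, h1) + sphere_cap_volume(r2, h2)
}

# Deterministic Fibonacci lattice on the unit sphere: n x 3 matrix.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Sunflower lattice on the unit disk: n x 2 matrix.
.sunflower_disk <- function(n) {
  i <- seq_len(n)
  r <- sqrt((i - 0.5) / n)
  th <- i * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th))
}

# Rotation-covariant orthonormal frame (rows e1, e2, e3) built from a matrix
# of unit normals: e3 is the first normal, e1 the orthonormalized first
# independent normal. Sampling lattices expressed in this frame rotate with
# the configuration, making numerically integrated quantities invariant
# under rigid motions. Falls back to a fixed global frame when all normals
# are collinear.
.local_frame <- function(U) {
  z <- U[1, ]
  x <- NULL
  if (nrow(U) > 1) {
    for (k in 2:nrow(U)) {
      cand <- U[k, ] - sum(U[k, ] * z) * z
      nc <- sqrt(sum(cand^2))
      if (nc > 1e-8) { x <- cand / nc; break }
    }
  }
  if (is.null(x)) x <- .plane_basis(z)[1, ]
  y <- c(
    z[2] * x[3] - z[3] * x[2],
    z[3] * x[1] - z[1] * x[3],
    z[1] * x[2] - z[2] * x[1]
  )
  rbind(x, y, z, deparse.level = 0)
}

# Orthonormal basis of the plane orthogonal to unit vector u.
.plane_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  rbind(e1, e2)
}
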