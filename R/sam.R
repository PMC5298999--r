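# Solvent-accessible models and power-diagram restriction geometry.
#
# Restriction volumes and exposed areas are exact (closed-form cap algebra)
# whenever a ball's clipping caps are pairwise disjoint -- which covers every
# one- and two-ball configuration -- and fall back to deterministic
# Fibonacci-lattice quadrature otherwise. Facet areas on radical planes are
# estimated by deterministic sunflower sampling. All iteration is ordered by
# atom_id, so results are bitwise reproducible.

#' Build the solvent-accessible model (SAM)
#'
#' Expands every van der Waals ball by the water-probe radius `r_w`,
#' producing the ball set whose union bounds the solvent-accessible surface.
#'
#' @param atoms data frame with columns `atom_id`, `x`, `y`, `z`, `r_vdw`
#'   (or a `ComplexStructure` from [read_structure()])
#' @param r_w water probe radius in Angstrom (default 1.4; 0 gives the plain
#'   van der Waals model)
#' @return data frame of balls: `atom_id`, `x`, `y`, `z`, `radius`
#' @export
build_sam <- function(atoms, r_w = 1.4) {
  if (inherits(atoms, "igvor_structure")) atoms <- atoms$atoms
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0, r_w >= 0)
  stopifnot(all(c("atom_id", "x", "y", "z", "r_vdw") %in% names(atoms)))
  stopifnot(all(atoms$r_vdw > 0))
  data.frame(
    atom_id = as.character(atoms$atom_id),
    x = atoms$x, y = atoms$y, z = atoms$z,
    radius = atoms$r_vdw + r_w,
    stringsAsFactors = FALSE
  )
}

# Shared ball preprocessing: containment and coincident-duplicate handling.
# Returns list(C, R, ids, n, contained, suppressed, D = distance matrix).
.ball_setup <- function(balls) {
  stopifnot(is.data.frame(balls), all(c("atom_id", "x", "y", "z", "radius") %in% names(balls)))
  ord <- order(balls$atom_id)
  balls <- balls[ord, , drop = FALSE]
  ids <- as.character(balls$atom_id)
  if (anyDuplicated(ids)) stop("duplicate atom_id in ball set")
  C <- as.matrix(balls[, c("x", "y", "z")])
  R <- balls$radius
  n <- length(ids)
  D <- as.matrix(stats::dist(C))
  suppressed <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (D[i, j] < 1e-9 && abs(R[i] - R[j]) < 1e-9 && !suppressed[j]) {
          # symbolic perturbation: the lexicographically larger id loses
          suppressed[j] <- TRUE
          warning(sprintf(
            "coincident balls %s / %s: tie broken by atom_id (%s suppressed)",
            ids[i], ids[j], ids[j]
          ), call. = FALSE)
        }
      }
    }
  }
  contained <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (suppressed[i]) next
    js <- setdiff(which(!suppressed), i)
    if (length(js)) {
      contained[i] <- any(D[i, js] + R[i] <= R[js] + 1e-12)
    }
  }
  list(C = C, R = R, ids = ids, n = n, D = D,
       suppressed = suppressed, contained = contained)
}

# Per-atom exposed (solvent-accessible) areas of a ball union, exact when the
# buried caps are pairwise disjoint, Fibonacci surface sampling otherwise.
.ball_exposed_areas <- function(setup, n_surf = 4096) {
  C <- setup$C; R <- setup$R; n <- setup$n; D <- setup$D
  area <- numeric(n)
  method <- character(n)
  S0 <- .fibonacci_sphere(n_surf)
  for (i in seq_len(n)) {
    if (setup$suppressed[i] || setup$contained[i]) {
      area[i] <- 0; method[i] <- "degenerate"; next
    }
    js <- setdiff(which(!setup$suppressed), i)
    js <- js[D[i, js] < R[i] + R[js] - 1e-12]
    if (!length(js)) {
      area[i] <- 4 * pi * R[i]^2; method[i] <- "closed-form"; next
    }
    d <- D[i, js]
    h <- (d^2 + R[i]^2 - R[js]^2) / (2 * d)
    cut <- which(h < R[i] - 1e-12) # these spheres cut sphere i
    if (!length(cut)) {
      area[i] <- 4 * pi * R[i]^2; method[i] <- "closed-form"; next
    }
    jc <- js[cut]; hc <- h[cut]
    U <- sweep(C[jc, , drop = FALSE], 2, C[i, ]) / D[i, jc]
    if (.caps_disjoint(U, acos(pmin(pmax(hc / R[i], -1), 1)))) {
      area[i] <- 4 * pi * R[i]^2 - sum(sphere_cap_area(R[i], hc))
      method[i] <- "closed-form"
    } else {
      P <- sweep((S0 %*% .local_frame(U)) * R[i], 2, C[i, ], "+")
      covered <- rep(FALSE, n_surf)
      for (m in seq_along(jc)) {
        dd <- sqrt(rowSums(sweep(P, 2, C[jc[m], ])^2))
        covered <- covered | (dd < R[jc[m]])
      }
      area[i] <- 4 * pi * R[i]^2 * mean(!covered)
      method[i] <- "sampled"
    }
  }
  list(area = area, method = method)
}

# TRUE iff spherical caps (axes U, angular radii alpha) are pairwise disjoint
# with a safety margin, so cap algebra is exact.
.caps_disjoint <- function(U, alpha) {
  m <- length(alpha)
  if (m <= 1) return(TRUE)
  for (a in seq_len(m - 1)) {
    for (b in seq((a + 1), m)) {
      gam <- acos(pmin(pmax(sum(U[a, ] * U[b, ]), -1), 1))
      if (gam <= alpha[a] + alpha[b] + 1e-9) return(FALSE)
    }
  }
  TRUE
}

#' Power-diagram restrictions of a ball set
#'
#' Computes, for every ball, the volume and exposed (accessible) area of its
#' Voronoi restriction -- the intersection of the ball with its power-diagram
#' cell -- together with the restriction adjacency graph (balls whose shared
#' radical-plane facet has positive area inside both balls).
#'
#' @param balls ball data frame from [build_sam()]
#' @param n_dir number of radial quadrature directions per ball for
#'   non-analytic configurations
#' @param n_surf number of surface sample points per ball for non-analytic
#'   exposed areas
#' @param facet_samples number of sample points per candidate contact facet
#' @param area_eps minimal facet area (Angstrom^2) for two restrictions to
#'   count as neighbors
#' @return object of class `igvor_restrictions`: list with `geometry`
#'   (data frame: `atom_id`, `volume_bound`, `exposed_area_bound`, `method`)
#'   and `edges` (data frame: `a`, `b`, `facet_area`; `a < b` by atom id)
#' @export
compute_restrictions <- function(balls, n_dir = 4096, n_surf = 4096,
                                 facet_samples = 512, area_eps = 1e-6) {
  su <- .ball_setup(balls)
  C <- su$C; R <- su$R; ids <- su$ids; n <- su$n; D <- su$D
  vol <- numeric(n)
  vmethod <- character(n)
  dirs <- .fibonacci_sphere(n_dir)

  for (i in seq_len(n)) {
    if (su$suppressed[i] || su$contained[i]) {
      vol[i] <- 0; vmethod[i] <- "degenerate"; next
    }
    js <- setdiff(which(!su$suppressed), i)
    js <- js[D[i, js] < R[i] + R[js] - 1e-12]
    if (length(js)) {
      d <- D[i, js]
      h <- (d^2 + R[i]^2 - R[js]^2) / (2 * d)
      keep <- which(h < R[i] - 1e-12)
      js <- js[keep]; h <- h[keep]
    }
    if (!length(js)) {
      vol[i] <- sphere_volume(R[i]); vmethod[i] <- "closed-form"; next
    }
    U <- sweep(C[js, , drop = FALSE], 2, C[i, ]) / D[i, js]
    alpha <- acos(pmin(pmax(h / R[i], -1), 1))
    if (.caps_disjoint(U, alpha)) {
      vol[i] <- sphere_volume(R[i]) - sum(sphere_cap_volume(R[i], h))
      vmethod[i] <- "closed-form"
    } else if (all(h > 1e-12)) {
      # cell contains the center: star-shaped radial quadrature in a frame
      # anchored to the plane normals (rigid-motion covariant)
      proj <- (dirs %*% .local_frame(U)) %*% t(U) # n_dir x n_planes
      rho <- matrix(R[i], nrow(dirs), length(h))
      pos <- proj > 1e-12
      rho[pos] <- pmin(rho[pos], rep(h, each = nrow(dirs))[pos] / proj[pos])
      rho <- do.call(pmin, c(split(rho, col(rho)), list(R[i])))
      vol[i] <- 4 * pi / (3 * n_dir) * sum(rho^3)
      vmethod[i] <- "quadrature"
    } else {
      # center outside its own cell: seeded rejection sampling in the ball
      vol[i] <- .with_seed(971, {
        m <- 20000
        P <- matrix(rnorm(3 * m), m, 3)
        P <- (P / sqrt(rowSums(P^2)) * runif(m)^(1 / 3) * R[i]) %*%
          .local_frame(U)
        inside <- rep(TRUE, m)
        for (q in seq_along(js)) {
          inside <- inside & (P %*% U[q, ] <= h[q])
        }
        sphere_volume(R[i]) * mean(inside)
      })
      vmethod[i] <- "monte-carlo"
    }
  }

  ar <- .ball_exposed_areas(su, n_surf = n_surf)

  # restriction adjacency: positive-area facets on radical planes
  edges <- list()
  disk <- .sunflower_disk(facet_samples)
  active <- which(!su$suppressed & !su$contained)
  if (length(active) > 1) {
    for (ii in seq_len(length(active) - 1)) {
      for (jj in seq((ii + 1), length(active))) {
        i <- active[ii]; j <- active[jj]
        d <- D[i, j]
        if (d >= R[i] + R[j] - 1e-12) next
        hij <- (d^2 + R[i]^2 - R[j]^2) / (2 * d)
        rc2 <- R[i]^2 - hij^2
        if (rc2 <= 0) next
        u <- (C[j, ] - C[i, ]) / d
        q <- C[i, ] + hij * u
        # in-plane basis anchored to the nearest third ball so the sample
        # lattice rotates with the configuration
        B <- .plane_basis(u)
        ref <- setdiff(active, c(i, j))
        if (length(ref)) {
          k0 <- ref[which.min(D[i, ref] + D[j, ref])]
          e1 <- C[k0, ] - q
          e1 <- e1 - sum(e1 * u) * u
          ne <- sqrt(sum(e1^2))
          if (ne > 1e-8) {
            e1 <- e1 / ne
            e2 <- c(u[2] * e1[3] - u[3] * e1[2],
                    u[3] * e1[1] - u[1] * e1[3],
                    u[1] * e1[2] - u[2] * e1[1])
            B <- rbind(e1, e2, deparse.level = 0)
          }
        }
        P <- sweep(disk %*% (sqrt(rc2) * B), 2, q, "+")
        others <- setdiff(which(!su$suppressed), c(i, j))
        ok <- rep(TRUE, nrow(P))
        pw_i <- rowSums(sweep(P, 2, C[i, ])^2) - R[i]^2
        for (k in others) {
          if (!any(ok)) break
          pw_k <- rowSums(sweep(P, 2, C[k, ])^2) - R[k]^2
          ok <- ok & (pw_i <= pw_k + 1e-12)
        }
        fa <- pi * rc2 * mean(ok)
        if (fa > area_eps) {
          edges[[length(edges) + 1]] <- data.frame(
            a = ids[i], b = ids[j], facet_area = fa,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), facet_area = numeric(),
               stringsAsFactors = FALSE)

  structure(list(
    geometry = data.frame(
      atom_id = ids,
      volume_bound = vol,
      exposed_area_bound = ar$area,
      method_volume = vmethod,
      method_area = ar$method,
      stringsAsFactors = FALSE
    ),
    edges = edges,
    params = list(n_dir = n_dir, n_surf = n_surf,
                  facet_samples = facet_samples, area_eps = area_eps)
  ), class = "igvor_restrictions")
}

#' Per-atom exposed areas of a ball set
#'
#' Accessible-surface areas of the union of balls, charged per atom. Used for
#' the unbound reference states when computing buried surface areas.
#'
#' @inheritParams compute_restrictions
#' @return named numeric vector of areas (Angstrom^2), names are atom ids
#' @export
exposed_areas <- function(balls, n_surf = 4096) {
  su <- .ball_setup(balls)
  ar <- .ball_exposed_areas(su, n_surf = n_surf)
  setNames(ar$area, su$ids)
}

#' Monte-Carlo union-of-balls volume oracle
#'
#' Independent stochastic estimate of the volume of a union of balls, used to
#' validate the power-diagram volume partition (the restriction volumes must
#' sum to the union volume).
#'
#' @param balls ball data frame from [build_sam()]
#' @param n_samples number of uniform samples over the bounding box (>= 1000)
#' @param seed RNG seed
#' @return list with `volume` (Angstrom^3), `se` (standard error), `n`
#' @export
union_volume_oracle <- function(balls, n_samples = 1e5, seed = 1) {
  if (is.null(balls) || nrow(balls) == 0) {
    return(list(volume = 0, se = 0, n = as.integer(n_samples)))
  }
  stopifnot(n_samples >= 1e3)
  lo <- apply(balls[, c("x", "y", "z")] - balls$radius, 2, min)
  hi <- apply(balls[, c("x", "y", "z")] + balls$radius, 2, max)
  vbox <- prod(hi - lo)
  C <- as.matrix(balls[, c("x", "y", "z")])
  R2 <- balls$radius^2
  .with_seed(seed, {
    P <- cbind(
      runif(n_samples, lo[1], hi[1]),
      runif(n_samples, lo[2], hi[2]),
      runif(n_samples, lo[3], hi[3])
    )
    inside <- rep(FALSE, n_samples)
    for (k in seq_len(nrow(C))) {
      inside <- inside | (rowSums(sweep(P, 2, C[k, ])^2) < R2[k])
    }
    p <- mean(inside)
    list(
      volume = vbox * p,
      se = vbox * sqrt(p * (1 - p) / n_samples),
      n = as.integer(n_samples)
    )
  })
}
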