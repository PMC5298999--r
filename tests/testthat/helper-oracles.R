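# Independent oracles, kept deliberately separate from the package's own
# algorithms: they share no code path with what they check.

# Sphere-sphere intersection volume as a single closed-form expression
# (standard lens formula), independent of the cap-sum route in the package.
lens_volume_direct <- function(r1, r2, d) {
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

# Shrake-Rupley-style numerical accessible-area oracle: random (seeded)
# points on each sphere, count those outside all other balls.
sasa_oracle <- function(balls, n_pts = 4000, seed = 99) {
  set.seed(seed)
  C <- as.matrix(balls[, c("x", "y", "z")])
  R <- balls$radius
  n <- nrow(balls)
  out <- numeric(n)
  for (i in seq_len(n)) {
    P <- matrix(rnorm(3 * n_pts), n_pts, 3)
    P <- P / sqrt(rowSums(P^2)) * R[i]
    P <- sweep(P, 2, C[i, ], "+")
    free <- rep(TRUE, n_pts)
    for (j in seq_len(n)[-i]) {
      free <- free & (rowSums(sweep(P, 2, C[j, ])^2) >= R[j]^2)
    }
    out[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  setNames(out, balls$atom_id)
}

# Brute-force shelling orders: Bellman-Ford-style relaxation until a fixed
# point (no BFS frontier logic shared with the implementation).
so_oracle <- function(patch, edges, boundary) {
  patch <- as.character(patch)
  so <- setNames(rep(Inf, length(patch)), patch)
  so[intersect(as.character(boundary), patch)] <- 1
  keep <- edges$a %in% patch & edges$b %in% patch
  ea <- edges$a[keep]; eb <- edges$b[keep]
  repeat {
    changed <- FALSE
    for (r in seq_along(ea)) {
      if (so[eb[r]] + 1 < so[ea[r]]) { so[ea[r]] <- so[eb[r]] + 1; changed <- TRUE }
      if (so[ea[r]] + 1 < so[eb[r]]) { so[eb[r]] <- so[ea[r]] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  so[!is.finite(so)] <- 1 # boundary-free components
  storage.mode(so) <- "integer"
  so
}

# Exact two-sided signed-rank p-value by exhaustive enumeration of all 2^n
# sign assignments (requires no zero differences and no |diff| ties).
wilcoxon_enum_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Minimal fixed-column PDB ATOM/HETATM record writer for hand-built files.
pdb_line <- function(record = "ATOM", serial, name, alt = " ", resname,
                     chain, resno, icode = " ", x, y, z, occ = 1, bfac = 0,
                     element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, icode,
          x, y, z, occ, bfac, element)
}

# Hand-built flat descriptor table with the per-region columns the cdr_stats
# module consumes. `values` is a named list region -> c(n_atoms, n_residues,
# bsa, ivw_ipl); unlisted regions are zero.
fake_desc_row <- function(complex_id, values) {
  regions <- setdiff(region_labels(), "water")
  row <- data.frame(complex_id = complex_id, stringsAsFactors = FALSE)
  for (rg in regions) {
    v <- if (rg %in% names(values)) values[[rg]] else c(0, 0, 0, 0)
    suf <- gsub("-", "_", rg, fixed = TRUE)
    row[[paste0("n_atoms_", suf)]] <- v[1]
    row[[paste0("n_residues_", suf)]] <- v[2]
    row[[paste0("bsa_", suf)]] <- v[3]
    row[[paste0("ivw_ipl_", suf)]] <- v[4]
    row[[paste0("anso_", suf)]] <- if (v[1] > 0) v[4] / v[1] else NA_real_
  }
  row
}

# Minimal hand-built interface object for descriptor arithmetic tests.
fake_interface <- function(atoms, I_Ig, I_Ag, bsa_Ig = NA, bsa_Ag = NA) {
  if (is.na(bsa_Ig)) bsa_Ig <- sum(atoms$bsa[atoms$atom_id %in% I_Ig])
  if (is.na(bsa_Ag)) bsa_Ag <- sum(atoms$bsa[atoms$atom_id %in% I_Ag])
  structure(list(
    atoms = atoms, I_Ig = I_Ig, I_Ag = I_Ag,
    direct_pairs = data.frame(), water_mediated_pairs = data.frame(),
    edges = data.frame(a = character(), b = character()),
    bsa_Ig = bsa_Ig, bsa_Ag = bsa_Ag,
    params = list()
  ), class = "igvor_interface")
}
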