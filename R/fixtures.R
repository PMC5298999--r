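# Synthetic-data generation: analytic ball fixtures with closed-form
# geometric truths, patch fixtures with hand-computable shelling orders,
# random ball clouds and two-sided complexes, and synthetic descriptor /
# affinity cohorts with known class and response structure.

.fixture_atoms <- function(x, y, z, r, partner, region,
                           chain = ifelse(partner == "Ig", "H", "G"),
                           element = "C", resno = seq_along(x),
                           resname = "GLY") {
  n <- length(x)
  data.frame(
    atom_id = sprintf("%s%03d", ifelse(partner == "Ig", "I", "A"), seq_len(n)),
    element = rep_len(element, n),
    x = x, y = y, z = z,
    r_vdw = rep_len(r, n),
    residue_name = rep_len(resname, n),
    residue_seq = resno,
    insert = "",
    chain_id = rep_len(chain, n),
    partner = partner,
    region = region,
    stringsAsFactors = FALSE
  )
}

#' Wrap a fixture atom table into a ComplexStructure
#'
#' @param atoms fixture atom data frame (columns as in [read_structure()]
#'   output)
#' @param heavy_chain,light_chain,ligand_chains chain roles
#' @param ligand_type ligand class
#' @return an `igvor_structure`
#' @export
fixture_structure <- function(atoms, heavy_chain = "H", light_chain = "L",
                              ligand_chains = "G", ligand_type = "unknown") {
  .new_structure(atoms, heavy_chain, light_chain, ligand_chains,
                 ligand_type = ligand_type, radius_table = "fixture")
}

#' Two-ball fixture with closed-form truths
#'
#' Two balls on the x axis at distance `d`, one per partner, with analytic
#' union volume, lens volume, per-ball restriction volumes (radical-plane
#' construction) and exposed cap areas. Radii are used as-is (probe radius
#' 0), so the stored truths apply to the balls themselves.
#'
#' @param d center distance (Angstrom)
#' @param r1,r2 ball radii (Angstrom)
#' @return a `BallFixture`: list with `name`, `atoms`, and `truths`
#' @export
make_two_ball <- function(d, r1 = 2, r2 = 2) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  atoms <- rbind(
    .fixture_atoms(0, 0, 0, r1, "Ig", "VH-CDR3"),
    .fixture_atoms(d, 0, 0, r2, "Ag", "antigen")
  )
  degenerate <- (d < 1e-9 && abs(r1 - r2) < 1e-9)
  if (degenerate) {
    warning("coincident equal balls: degenerate fixture", call. = FALSE)
    truths <- list(degenerate = TRUE, union_volume = sphere_volume(r1))
  } else if (d >= r1 + r2) {
    truths <- list(
      degenerate = FALSE, overlap = FALSE, contact = FALSE,
      lens_volume = 0,
      union_volume = sphere_volume(r1) + sphere_volume(r2),
      restriction_volumes = setNames(c(sphere_volume(r1), sphere_volume(r2)),
                                     atoms$atom_id),
      exposed_areas = setNames(c(4 * pi * r1^2, 4 * pi * r2^2), atoms$atom_id)
    )
  } else if (d + r1 <= r2 || d + r2 <= r1) {
    small_first <- d + r1 <= r2
    truths <- list(
      degenerate = FALSE, overlap = TRUE, contact = FALSE, contained = TRUE,
      lens_volume = sphere_volume(min(r1, r2)),
      union_volume = sphere_volume(max(r1, r2)),
      restriction_volumes = setNames(
        if (small_first) c(0, sphere_volume(r2)) else c(sphere_volume(r1), 0),
        atoms$atom_id),
      exposed_areas = setNames(
        if (small_first) c(0, 4 * pi * r2^2) else c(4 * pi * r1^2, 0),
        atoms$atom_id)
    )
  } else {
    h1 <- (d^2 + r1^2 - r2^2) / (2 * d)
    h2 <- d - h1
    truths <- list(
      degenerate = FALSE, overlap = TRUE, contact = TRUE,
      lens_volume = sphere_lens_volume(r1, r2, d),
      union_volume = sphere_volume(r1) + sphere_volume(r2) -
        sphere_lens_volume(r1, r2, d),
      restriction_volumes = setNames(
        c(sphere_volume(r1) - sphere_cap_volume(r1, h1),
          sphere_volume(r2) - sphere_cap_volume(r2, h2)),
        atoms$atom_id),
      exposed_areas = setNames(
        c(4 * pi * r1^2 - sphere_cap_area(r1, h1),
          4 * pi * r2^2 - sphere_cap_area(r2, h2)),
        atoms$atom_id)
    )
  }
  list(name = sprintf("two-ball d=%g r1=%g r2=%g", d, r1, r2),
       atoms = atoms, truths = truths)
}

#' Patch fixtures with hand-computed shelling orders
#'
#' Deterministic lattice constructions whose shelling orders are known by
#' hand: a path whose two ends are on the patch boundary, a hexagonal disk
#' (ring SO 1, center SO 2), and two isolated single-atom components
#' (boundary-free, SO 1 throughout).
#'
#' @param shape `"path"`, `"disk"`, or `"two-component"`
#' @param n number of atoms for `"path"`
#' @return list with `name`, `atoms`, `edges`, `boundary`, `expected_so`
#' @export
make_patch_fixture <- function(shape = c("path", "disk", "two-component"),
                               n = 5) {
  shape <- match.arg(shape)
  if (shape == "path") {
    stopifnot(n >= 1)
    atoms <- .fixture_atoms(1.5 * (seq_len(n) - 1), 0, 0, 1.0, "Ig", "VH-CDR3")
    ids <- atoms$atom_id
    edges <- if (n > 1) {
      data.frame(a = ids[-n], b = ids[-1], stringsAsFactors = FALSE)
    } else {
      data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
    }
    boundary <- unique(ids[c(1, n)])
    expected <- pmin(seq_len(n), rev(seq_len(n)))
  } else if (shape == "disk") {
    th <- 2 * pi * (0:5) / 6
    atoms <- .fixture_atoms(c(1.5 * cos(th), 0), c(1.5 * sin(th), 0),
                            0, 1.0, "Ig", "VH-CDR3")
    ids <- atoms$atom_id
    ring <- ids[1:6]; center <- ids[7]
    edges <- rbind(
      data.frame(a = ring, b = ring[c(2:6, 1)], stringsAsFactors = FALSE),
      data.frame(a = ring, b = center, stringsAsFactors = FALSE)
    )
    boundary <- ring
    expected <- c(rep(1L, 6), 2L)
  } else {
    atoms <- .fixture_atoms(c(0, 10), 0, 0, 1.0, "Ig", "VH-CDR3")
    ids <- atoms$atom_id
    edges <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
    boundary <- character(0)
    expected <- c(1L, 1L)
  }
  list(name = paste0("patch-", shape), atoms = atoms, edges = edges,
       boundary = boundary,
       expected_so = setNames(as.integer(expected), atoms$atom_id))
}

#' Random ball cloud
#'
#' Uniform ball centers in a cube with radii in a range, away from exact
#' degeneracies with probability one. Used for volume-conservation and
#' rigid-motion property checks.
#'
#' @param n_atoms number of balls
#' @param seed RNG seed
#' @param box cube edge length (Angstrom)
#' @param radius_range min/max ball radius (Angstrom)
#' @return ball data frame (`atom_id`, `x`, `y`, `z`, `radius`)
#' @export
make_random_ball_fixture <- function(n_atoms = 10, seed = 1, box = 6,
                                     radius_range = c(1.4, 2)) {
  .with_seed(seed, data.frame(
    atom_id = sprintf("B%03d", seq_len(n_atoms)),
    x = runif(n_atoms, 0, box),
    y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    radius = runif(n_atoms, radius_range[1], radius_range[2]),
    stringsAsFactors = FALSE
  ))
}

#' Random two-sided complex fixture
#'
#' Two facing clusters of balls -- an Ig patch (atoms labeled with CDR
#' regions) and an Ag cluster -- built so the clusters touch. Returns a
#' `ComplexStructure` suitable for the full interface pipeline.
#'
#' @param n_ig,n_ag atoms per side
#' @param seed RNG seed
#' @param gap x-offset between the cluster centers (Angstrom)
#' @param spread cluster radius (Angstrom)
#' @return an `igvor_structure`
#' @export
make_random_complex <- function(n_ig = 10, n_ag = 8, seed = 1, gap = 4.5,
                                spread = 2.5) {
  .with_seed(seed, {
    cdr <- sample(c("CDR1", "CDR2", "CDR3"), n_ig, replace = TRUE)
    chain <- sample(c("H", "L"), n_ig, replace = TRUE)
    # representative IMGT positions inside each CDR window
    ig_res <- c(CDR1 = 30, CDR2 = 60, CDR3 = 110)[cdr]
    ig <- .fixture_atoms(
      rnorm(n_ig, 0, spread / 2), rnorm(n_ig, 0, spread),
      rnorm(n_ig, 0, spread), runif(n_ig, 1.5, 1.9), "Ig",
      paste0(ifelse(chain == "H", "VH-", "VL-"), cdr),
      chain = chain,
      resno = unname(ig_res),
      resname = sample(c("GLY", "SER", "TYR", "ASP", "LYS"), n_ig,
                       replace = TRUE)
    )
    ag <- .fixture_atoms(
      gap + rnorm(n_ag, 0, spread / 2), rnorm(n_ag, 0, spread),
      rnorm(n_ag, 0, spread), runif(n_ag, 1.5, 1.9), "Ag", "antigen",
      resno = seq_len(n_ag),
      resname = sample(c("ALA", "GLU", "ARG", "THR"), n_ag, replace = TRUE)
    )
    fixture_structure(rbind(ig, ag), ligand_type = "protein")
  })
}

#' Write a fixture as a PDB file
#'
#' Coordinates are rounded to the PDB's three decimals, so a written fixture
#' round-trips through [read_structure()].
#'
#' @param atoms fixture atom data frame (or an `igvor_structure`)
#' @param path output PDB path
#' @return the path, invisibly
#' @export
write_fixture_pdb <- function(atoms, path) {
  if (inherits(atoms, "igvor_structure")) atoms <- atoms$atoms
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    rec <- if (atoms$partner[i] == "water" ||
               !atoms$residue_name[i] %in% c("GLY", "ALA", "SER", "TYR",
                                             "ASP", "GLU", "LYS", "ARG",
                                             "THR", "HIS")) "HETATM" else "ATOM  "
    lines[i] <- sprintf(
      "%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, i, substr(paste0(atoms$element[i], i %% 100), 1, 4), " ",
      atoms$residue_name[i], atoms$chain_id[i], atoms$residue_seq[i],
      ifelse(is.na(atoms$insert[i]) | atoms$insert[i] == "", " ",
             atoms$insert[i]),
      atoms$x[i], atoms$y[i], atoms$z[i], 1.0, 0.0, atoms$element[i]
    )
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Largest-remainder apportionment of class counts
#'
#' @param n total count
#' @param proportions named proportions summing to 1
#' @return named integer counts summing to `n`
#' @export
largest_remainder <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * proportions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }
  setNames(as.integer(counts), names(proportions))
}

#' Synthetic descriptor and affinity cohort
#'
#' Generates (i) a labeled classifier table in (bsa_avg_Ag, bsa_avg_Ig)
#' space, one Gaussian blob per ligand class with the curvature ordering
#' chemical > peptide > protein on the Ag side (and the inverse on the Ig
#' side), plus an interface-size column, and (ii) an affinity table in
#' (IVW-IPL, NIS_charged) space with `minus_dG` generated by a known
#' response function plus Gaussian noise, and the consistent Kd.
#'
#' @param n cohort size
#' @param proportions class proportions (chemical, peptide, protein);
#'   counts by largest-remainder rounding
#' @param seed RNG seed
#' @param class_means named list of c(bsa_avg_Ag, bsa_avg_Ig) class centers
#' @param class_sds named list of feature SDs per class
#' @param response function(ivw_ipl, nis_charged) -> noiseless minus_dG
#' @param noise_sd affinity noise SD (kcal/mol)
#' @param T temperature (kelvin) for the Kd conversion
#' @return list with `classifier` and `affinity` data frames and `counts`
#' @export
make_cohort <- function(n = 489,
                        proportions = c(chemical = 0.16, peptide = 0.25,
                                        protein = 0.59),
                        seed = 1,
                        class_means = list(chemical = c(35, 6),
                                           peptide = c(18, 9),
                                           protein = c(9, 12)),
                        class_sds = list(chemical = c(4, 1.2),
                                         peptide = c(3, 1.2),
                                         protein = c(2, 1.5)),
                        response = function(ivw, nis)
                          4 + 0.28 * ivw - 6 * (nis - 0.25),
                        noise_sd = 0.8, T = 298) {
  counts <- largest_remainder(n, proportions)
  if (any(counts < 0)) stop("invalid proportions")
  size_means <- c(chemical = 40, peptide = 90, protein = 170)
  .with_seed(seed, {
    lab <- rep(names(counts), counts)
    m <- do.call(rbind, class_means[lab])
    s <- do.call(rbind, class_sds[lab])
    classifier <- data.frame(
      complex_id = sprintf("syn_%04d", seq_len(n)),
      bsa_avg_Ag = pmax(0.5, rnorm(n, m[, 1], s[, 1])),
      bsa_avg_Ig = pmax(0.5, rnorm(n, m[, 2], s[, 2])),
      n_interface = pmax(10, round(rnorm(n, size_means[lab],
                                         0.18 * size_means[lab]))),
      label = lab,
      stringsAsFactors = FALSE
    )
    ivw <- pmax(2, rnorm(n, 25, 8))
    nis <- pmin(0.6, pmax(0.05, rnorm(n, 0.25, 0.05)))
    minus_dG <- response(ivw, nis) + rnorm(n, 0, noise_sd)
    affinity <- data.frame(
      complex_id = classifier$complex_id,
      ivw_ipl = ivw,
      nis_charged = nis,
      minus_dG = minus_dG,
      Kd = exp(-minus_dG / (.R_KCAL * T)),
      T = T,
      stringsAsFactors = FALSE
    )
    list(classifier = classifier, affinity = affinity, counts = counts,
         seed = seed)
  })
}
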