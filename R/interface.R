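# Voronoi interface extraction: direct and water-mediated contacts, per-atom
# buried surface area, binding patches and shelling orders.

#' Shelling orders of a binding patch
#'
#' Assigns each patch atom its hop distance to the patch boundary in the
#' restriction-neighbor graph: boundary atoms get SO = 1, every other atom
#' 1 + the minimum over its patch neighbors (breadth-first search). Connected
#' components without any boundary atom get SO = 1 throughout.
#'
#' @param patch character vector of patch atom ids
#' @param edges data frame with columns `a`, `b`: the restriction-neighbor
#'   graph restricted to one partner's atoms
#' @param boundary character vector of patch atoms on the patch boundary
#' @return named integer vector: SO per patch atom (empty patch gives an
#'   empty vector)
#' @export
shelling_orders <- function(patch, edges, boundary) {
  patch <- as.character(patch)
  if (!length(patch)) return(setNames(integer(0), character(0)))
  boundary <- intersect(as.character(boundary), patch)
  adj <- lapply(setNames(patch, patch), function(p) character(0))
  if (nrow(edges)) {
    keep <- edges$a %in% patch & edges$b %in% patch
    for (r in which(keep)) {
      a <- edges$a[r]; b <- edges$b[r]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  so <- setNames(rep(NA_integer_, length(patch)), patch)
  frontier <- boundary
  so[frontier] <- 1L
  level <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(so[nxt])]
    if (!length(nxt)) break
    level <- level + 1L
    so[nxt] <- level
    frontier <- nxt
  }
  so[is.na(so)] <- 1L # boundary-free components
  so
}

#' Extract the Voronoi interface of a complex
#'
#' From the power-diagram restrictions of the full complex SAM (both partners
#' plus crystallographic waters), identifies direct Ig-Ag contact pairs,
#' first-shell interfacial waters (restriction-adjacent to both partners) and
#' the water-mediated pairs through them, charges buried surface area per
#' atom (unbound reference: each partner alone at bound coordinates, waters
#' excluded), and computes shelling orders per binding patch.
#'
#' @param s a `ComplexStructure` from [read_structure()] (annotated or not)
#' @param restrictions optional precomputed [compute_restrictions()] result
#'   for the full complex SAM; computed if `NULL`
#' @param r_w water probe radius (Angstrom)
#' @param so_seed boundary seeding for shelling orders: `"exposed"` (patch
#'   atoms with positive bound exposed area, or adjacent to an exposed
#'   same-partner atom outside the patch) or `"rim"` (adjacency criterion
#'   only)
#' @param area_eps area threshold (Angstrom^2) below which an exposed area
#'   counts as zero
#' @param n_surf surface sample points per ball for numerically integrated
#'   areas
#' @return object of class `igvor_interface`: list with `atoms` (per-atom
#'   table: partner, region, areas, `bsa`, `vol_bound`, `so`, `interface`),
#'   `I_Ig`, `I_Ag` (interface atom ids), `direct_pairs`,
#'   `water_mediated_pairs`, `edges` (full restriction graph), `bsa_Ig`,
#'   `bsa_Ag`, and the parameters used
#' @export
extract_interface <- function(s, restrictions = NULL, r_w = 1.4,
                              so_seed = c("exposed", "rim"),
                              area_eps = 1e-6, n_surf = 4096) {
  so_seed <- match.arg(so_seed)
  stopifnot(inherits(s, "igvor_structure"))
  atoms <- s$atoms
  balls <- build_sam(atoms, r_w = r_w)
  if (is.null(restrictions)) {
    restrictions <- compute_restrictions(balls, n_surf = n_surf)
  }
  geo <- restrictions$geometry
  edges <- restrictions$edges
  atoms <- atoms[match(geo$atom_id, atoms$atom_id), , drop = FALSE]
  partner <- setNames(atoms$partner, atoms$atom_id)

  # direct Ig-Ag contacts
  pa <- partner[edges$a]; pb <- partner[edges$b]
  dir_ab <- (pa == "Ig" & pb == "Ag")
  dir_ba <- (pa == "Ag" & pb == "Ig")
  direct_pairs <- data.frame(
    ig_atom = c(edges$a[dir_ab], edges$b[dir_ba]),
    ag_atom = c(edges$b[dir_ab], edges$a[dir_ba]),
    stringsAsFactors = FALSE
  )

  # first-shell interfacial waters: adjacent to >=1 Ig and >=1 Ag atom
  waters <- atoms$atom_id[atoms$partner == "water"]
  wm <- data.frame(partner_atom = character(), water_atom = character(),
                   stringsAsFactors = FALSE)
  if (length(waters) && nrow(edges)) {
    for (w in waters) {
      nb <- c(edges$b[edges$a == w], edges$a[edges$b == w])
      nbp <- partner[nb]
      if (any(nbp == "Ig") && any(nbp == "Ag")) {
        keep <- nb[nbp %in% c("Ig", "Ag")]
        wm <- rbind(wm, data.frame(partner_atom = keep, water_atom = w,
                                   stringsAsFactors = FALSE))
      }
    }
  }

  I_Ig <- sort(unique(c(direct_pairs$ig_atom,
                        wm$partner_atom[partner[wm$partner_atom] == "Ig"])))
  I_Ag <- sort(unique(c(direct_pairs$ag_atom,
                        wm$partner_atom[partner[wm$partner_atom] == "Ag"])))
  if (!length(I_Ig) && !length(I_Ag)) {
    warning("no Ig-Ag contacts found: empty interface", call. = FALSE)
  }

  # buried surface area: unbound = each partner alone, waters excluded
  area_unbound <- setNames(rep(NA_real_, nrow(atoms)), atoms$atom_id)
  for (side in c("Ig", "Ag")) {
    sel <- atoms$partner == side
    if (!any(sel)) next
    a <- exposed_areas(balls[balls$atom_id %in% atoms$atom_id[sel], ,
                             drop = FALSE], n_surf = n_surf)
    area_unbound[names(a)] <- a
  }
  area_bound <- setNames(geo$exposed_area_bound, geo$atom_id)
  bsa <- pmax(area_unbound - area_bound, 0) # first arg keeps the names
  bsa[atoms$partner == "water"] <- NA_real_

  # shelling orders per partner patch
  so <- setNames(rep(NA_integer_, nrow(atoms)), atoms$atom_id)
  for (side in c("Ig", "Ag")) {
    patch <- if (side == "Ig") I_Ig else I_Ag
    if (!length(patch)) next
    side_atoms <- atoms$atom_id[atoms$partner == side]
    keep <- edges$a %in% side_atoms & edges$b %in% side_atoms
    side_edges <- edges[keep, , drop = FALSE]
    exposed <- side_atoms[area_bound[side_atoms] > area_eps]
    outside_exposed <- setdiff(exposed, patch)
    adj_to_out <- character(0)
    if (nrow(side_edges)) {
      hit <- (side_edges$a %in% patch & side_edges$b %in% outside_exposed) |
        (side_edges$b %in% patch & side_edges$a %in% outside_exposed)
      adj_to_out <- unique(c(
        side_edges$a[hit & side_edges$a %in% patch],
        side_edges$b[hit & side_edges$b %in% patch]
      ))
    }
    boundary <- if (so_seed == "exposed") {
      union(intersect(patch, exposed), adj_to_out)
    } else {
      adj_to_out
    }
    so[patch] <- shelling_orders(patch, side_edges, boundary)
  }

  atab <- data.frame(
    atom_id = atoms$atom_id,
    partner = atoms$partner,
    chain_id = atoms$chain_id,
    residue_name = atoms$residue_name,
    residue_seq = atoms$residue_seq,
    region = atoms$region,
    vol_bound = geo$volume_bound,
    area_bound = unname(area_bound[atoms$atom_id]),
    area_unbound = unname(area_unbound[atoms$atom_id]),
    bsa = unname(bsa[atoms$atom_id]),
    so = unname(so[atoms$atom_id]),
    interface = atoms$atom_id %in% c(I_Ig, I_Ag),
    stringsAsFactors = FALSE
  )

  structure(list(
    atoms = atab,
    I_Ig = I_Ig,
    I_Ag = I_Ag,
    direct_pairs = direct_pairs,
    water_mediated_pairs = wm,
    edges = edges,
    bsa_Ig = sum(bsa[I_Ig]),
    bsa_Ag = sum(bsa[I_Ag]),
    params = list(r_w = r_w, so_seed = so_seed, area_eps = area_eps,
                  n_surf = n_surf)
  ), class = "igvor_interface")
}

#' @export
print.igvor_interface <- function(x, ...) {
  cat("Voronoi interface model\n")
  cat(sprintf("  interface atoms: |I_Ig| = %d, |I_Ag| = %d\n",
              length(x$I_Ig), length(x$I_Ag)))
  cat(sprintf("  direct pairs: %d; water-mediated pairs: %d\n",
              nrow(x$direct_pairs), nrow(x$water_mediated_pairs)))
  cat(sprintf("  BSA: Ig %.2f + Ag %.2f = %.2f A^2\n",
              x$bsa_Ig, x$bsa_Ag, x$bsa_Ig + x$bsa_Ag))
  invisible(x)
}

#' Write the per-atom interface table to CSV
#'
#' @param im an `igvor_interface`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_interface_csv <- function(im, path) {
  stopifnot(inherits(im, "igvor_interface"))
  write.csv(im$atoms, path, row.names = FALSE)
  invisible(path)
}
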