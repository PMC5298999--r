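# Structure parsing, radius assignment, chain roles, and CDR/FR annotation
# under the IMGT unique numbering.

# Heavy-atom van der Waals radii (Angstrom). "bondi" is the default working
# set; "uniform" assigns 1.7 A to every element (sensitivity analyses).
.RADIUS_TABLES <- list(
  bondi = c(
    C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, D = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
    ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75, CA = 2.31, MN = 1.97,
    FE = 1.94, CU = 1.40, NI = 1.63, CO = 1.94
  ),
  uniform = c(C = 1.7)
)

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3")

# IMGT unique-numbering limits of the V-domain regions.
.IMGT_LIMITS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  start = c(1, 27, 39, 56, 66, 105, 118),
  end = c(26, 38, 55, 65, 104, 117, 128),
  stringsAsFactors = FALSE
)

#' Region labels of the V domains
#'
#' The 14 CDR/FR region labels (IMGT unique numbering) plus the
#' constant/outside-V, antigen and water labels used throughout.
#' @return character vector of region labels
#' @export
region_labels <- function() {
  c(paste0("VH-", .IMGT_LIMITS$region), paste0("VL-", .IMGT_LIMITS$region),
    "constant", "antigen", "water")
}

.lookup_radius <- function(element, table_name, fallback_radius) {
  tab <- .RADIUS_TABLES[[table_name]]
  if (is.null(tab)) {
    stop("unknown radius table: ", table_name,
         " (available: ", paste(names(.RADIUS_TABLES), collapse = ", "), ")")
  }
  element <- toupper(element)
  r <- unname(tab[element])
  if (table_name == "uniform") r[is.na(r)] <- 1.7
  if (anyNA(r)) {
    if (is.na(fallback_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(element[is.na(r)]), collapse = ", "),
           "; set fallback_radius to accept them")
    }
    r[is.na(r)] <- fallback_radius
  }
  r
}

.new_structure <- function(atoms, heavy_chain_id, light_chain_id,
                           ligand_chain_ids, ligand_type = "unknown",
                           species = "unknown", radius_table = "bondi") {
  stopifnot(!anyDuplicated(atoms$atom_id), all(atoms$r_vdw > 0))
  structure(list(
    atoms = atoms,
    heavy_chain_id = heavy_chain_id,
    light_chain_id = light_chain_id,
    ligand_chain_ids = ligand_chain_ids,
    ligand_type = ligand_type,
    species = species,
    radius_table = radius_table
  ), class = "igvor_structure")
}

#' Read a complex structure from PDB or mmCIF
#'
#' Parses heavy atoms (hydrogens dropped), resolves alternate locations to
#' the highest-occupancy conformer (ties broken alphabetically), keeps waters
#' as `partner = "water"`, assigns van der Waals radii from a named table,
#' and tags each atom with its partner (Ig / Ag / water) from the declared
#' chain roles.
#'
#' @param path path to a PDB or mmCIF file
#' @param dialect `"auto"` (by extension), `"pdb"`, or `"cif"`
#' @param heavy_chain,light_chain chain identifiers of the Ig heavy and
#'   light chains
#' @param ligand_chains chain identifiers of the antigen; default: every
#'   other non-water chain
#' @param ligand_type one of `"chemical"`, `"peptide"`, `"protein"`,
#'   `"unknown"`
#' @param species dataset metadata, carried but unused by computations
#' @param radius_table name of the radius table (`"bondi"` or `"uniform"`)
#' @param fallback_radius radius (Angstrom) assigned to elements missing from
#'   the table; `NA` (default) makes unknown elements an error
#' @param keep_hydrogens keep hydrogen/deuterium atoms (default `FALSE`: the
#'   geometry operates on heavy-atom SAMs)
#' @return a `ComplexStructure` (class `igvor_structure`)
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "cif"),
                           heavy_chain = "H", light_chain = "L",
                           ligand_chains = NULL,
                           ligand_type = c("unknown", "chemical", "peptide", "protein"),
                           species = "unknown",
                           radius_table = "bondi", fallback_radius = NA,
                           keep_hydrogens = FALSE) {
  dialect <- match.arg(dialect)
  ligand_type <- match.arg(ligand_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  a <- parsed$atom
  if (nrow(a) == 0) stop("no atoms in ", path)
  a$elesy <- toupper(trimws(a$elesy))
  blank <- is.na(a$elesy) | a$elesy == ""
  if (any(blank)) { # infer element from the atom-name field
    a$elesy[blank] <- toupper(substr(trimws(a$elety[blank]), 1, 1))
  }
  if (!keep_hydrogens) a <- a[!a$elesy %in% c("H", "D"), , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms in ", path)

  # altloc resolution: per (chain, residue, atom name) keep the conformer
  # with the highest occupancy, ties broken alphabetically
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  occ <- if (is.null(a$o)) rep(1, nrow(a)) else ifelse(is.na(a$o), 1, a$o)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    best <- idx[occ[idx] == max(occ[idx])]
    best[order(a$alt[best])][1]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]

  chains <- unique(a$chain)
  if (!heavy_chain %in% chains) {
    heavy_chain <- NA_character_
  }
  if (!light_chain %in% chains) {
    light_chain <- NA_character_
  }
  is_water <- a$resid %in% .WATER_CODES
  if (is.null(ligand_chains)) {
    ligand_chains <- setdiff(unique(a$chain[!is_water]),
                             c(heavy_chain, light_chain))
  }
  partner <- ifelse(is_water, "water",
                    ifelse(a$chain %in% c(heavy_chain, light_chain), "Ig",
                           ifelse(a$chain %in% ligand_chains, "Ag",
                                  NA_character_)))
  if (anyNA(partner)) {
    stop("chains with no declared role: ",
         paste(unique(a$chain[is.na(partner)]), collapse = ", "))
  }

  atoms <- data.frame(
    atom_id = sprintf("%s:%d%s:%s", a$chain, a$resno, a$insert,
                      trimws(a$elety)),
    element = a$elesy,
    x = a$x, y = a$y, z = a$z,
    r_vdw = .lookup_radius(a$elesy, radius_table, fallback_radius),
    residue_name = a$resid,
    residue_seq = a$resno,
    insert = a$insert,
    chain_id = a$chain,
    partner = partner,
    region = ifelse(partner == "water", "water",
                    ifelse(partner == "Ag", "antigen", NA_character_)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(atoms$atom_id)) {
    dup <- duplicated(atoms$atom_id)
    atoms$atom_id[dup] <- paste0(atoms$atom_id[dup], "#", seq_len(sum(dup)))
  }
  .new_structure(atoms, heavy_chain, light_chain, ligand_chains,
                 ligand_type, species, radius_table)
}

#' Attach CDR/FR region labels to the Ig chains
#'
#' With `annotation = "imgt-numbered"` the Ig chains are assumed to carry the
#' IMGT unique numbering and the standard V-domain limits are applied (FR1
#' 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117, FR4
#' 118-128; residues beyond 128 are labeled `"constant"`). Otherwise
#' `annotation` is the path of a sidecar CSV with columns
#' `chain_id,start,end,insertion_codes,region` listing residue ranges.
#' Re-annotation is idempotent.
#'
#' @param s a `ComplexStructure`
#' @param annotation `"imgt-numbered"` or a sidecar CSV path
#' @return the structure with every Ig residue labeled
#' @export
annotate_regions <- function(s, annotation = "imgt-numbered") {
  stopifnot(inherits(s, "igvor_structure"))
  atoms <- s$atoms
  ig <- atoms$partner == "Ig"
  if (!any(ig)) {
    warning("no Ig atoms to annotate", call. = FALSE)
    return(s)
  }
  prefix <- ifelse(atoms$chain_id == s$heavy_chain_id, "VH", "VL")
  if (identical(annotation, "imgt-numbered")) {
    lab <- rep(NA_character_, nrow(atoms))
    for (k in seq_len(nrow(.IMGT_LIMITS))) {
      inr <- ig & atoms$residue_seq >= .IMGT_LIMITS$start[k] &
        atoms$residue_seq <= .IMGT_LIMITS$end[k]
      lab[inr] <- paste0(prefix[inr], "-", .IMGT_LIMITS$region[k])
    }
    lab[ig & atoms$residue_seq > 128] <- "constant"
    if (anyNA(lab[ig])) {
      bad <- unique(paste0(atoms$chain_id, ":", atoms$residue_seq)[ig & is.na(lab)])
      stop("Ig residues outside IMGT numbering range: ",
           paste(bad, collapse = ", "))
    }
    atoms$region[ig] <- lab[ig]
  } else {
    side <- read.csv(annotation, stringsAsFactors = FALSE,
                     colClasses = c(chain_id = "character",
                                    insertion_codes = "character",
                                    region = "character"))
    req <- c("chain_id", "start", "end", "region")
    if (!all(req %in% names(side))) {
      stop("sidecar must have columns chain_id,start,end,insertion_codes,region")
    }
    # overlapping ranges within a chain are an error
    for (ch in unique(side$chain_id)) {
      rows <- side[side$chain_id == ch, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      if (nrow(rows) > 1 &&
          any(rows$start[-1] <= rows$end[-nrow(rows)])) {
        stop("overlapping region ranges in sidecar for chain ", ch)
      }
    }
    lab <- rep(NA_character_, nrow(atoms))
    for (k in seq_len(nrow(side))) {
      inr <- ig & atoms$chain_id == side$chain_id[k] &
        atoms$residue_seq >= side$start[k] &
        atoms$residue_seq <= side$end[k]
      lab[inr] <- side$region[k]
    }
    if (anyNA(lab[ig])) {
      bad <- unique(paste0(atoms$chain_id, ":", atoms$residue_seq)[ig & is.na(lab)])
      stop("Ig residues not covered by sidecar: ", paste(bad, collapse = ", "))
    }
    atoms$region[ig] <- lab[ig]
  }
  s$atoms <- atoms
  s
}

#' Check that a complex has the canonical Ig-Ag shape
#'
#' A canonical complex has one heavy chain, one light chain, at least one
#' ligand chain, and a single ligand type.
#'
#' @param s a `ComplexStructure`
#' @param ligand_types optional named character vector mapping ligand chain
#'   id to its `LigandClass`, used to detect mixed ligand types
#' @return character vector of violations (empty if canonical)
#' @export
validate_canonical <- function(s, ligand_types = NULL) {
  stopifnot(inherits(s, "igvor_structure"))
  v <- character(0)
  if (is.na(s$heavy_chain_id) || length(s$heavy_chain_id) != 1) {
    v <- c(v, "missing or ambiguous heavy chain")
  }
  if (is.na(s$light_chain_id) || length(s$light_chain_id) != 1) {
    v <- c(v, "missing or ambiguous light chain")
  }
  if (length(s$ligand_chain_ids) < 1 ||
      !any(s$atoms$partner == "Ag")) {
    v <- c(v, "no ligand atoms")
  }
  if (!is.null(ligand_types)) {
    tl <- unique(unname(ligand_types[s$ligand_chain_ids]))
    tl <- tl[!is.na(tl)]
    if (length(tl) > 1) v <- c(v, "mixed ligand types")
  }
  v
}

#' @export
print.igvor_structure <- function(x, ...) {
  cat("Ig-Ag complex structure\n")
  cat(sprintf("  atoms: %d (Ig %d, Ag %d, water %d)\n", nrow(x$atoms),
              sum(x$atoms$partner == "Ig"), sum(x$atoms$partner == "Ag"),
              sum(x$atoms$partner == "water")))
  cat(sprintf("  chains: H = %s, L = %s, ligand = %s\n", x$heavy_chain_id,
              x$light_chain_id, paste(x$ligand_chain_ids, collapse = ",")))
  cat(sprintf("  ligand type: %s; species: %s; radii: %s\n",
              x$ligand_type, x$species, x$radius_table))
  invisible(x)
}

#' Serialize the atom table to JSON
#'
#' @param s a `ComplexStructure`
#' @param path output path
#' @return the path, invisibly
#' @export
write_atom_json <- function(s, path) {
  stopifnot(inherits(s, "igvor_structure"))
  jsonlite::write_json(
    list(
      heavy_chain_id = s$heavy_chain_id,
      light_chain_id = s$light_chain_id,
      ligand_chain_ids = s$ligand_chain_ids,
      ligand_type = s$ligand_type,
      species = s$species,
      radius_table = s$radius_table,
      atoms = s$atoms
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
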