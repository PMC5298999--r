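# Per-complex interface descriptors: side-resolved average BSA per interface
# atom, inverse volume-weighted internal path length (IVW-IPL), average
# normalized shelling order (ANSO), charged fraction of the non-interacting
# surface (NIS), and the 14-region CDR/FR decomposition.

.CHARGED_DEFAULT <- c("ASP", "GLU", "LYS", "ARG", "HIS")

#' Average buried surface area per interface atom, per side
#'
#' `bsa_avg_Ig = BSA_Ig / |I_Ig|` and likewise on the antigen side. These
#' ratios act as curvature proxies of the two binding patches.
#'
#' @param im an `igvor_interface`
#' @return list with `bsa_avg_Ig`, `bsa_avg_Ag` (Angstrom^2 per atom),
#'   `bsa_Ig`, `bsa_Ag`, `n_Ig`, `n_Ag`
#' @export
bsa_averages <- function(im) {
  stopifnot(inherits(im, "igvor_interface"))
  if (!length(im$I_Ig) || !length(im$I_Ag)) {
    stop("average BSA per interface atom is undefined for an empty interface side")
  }
  list(
    bsa_avg_Ig = im$bsa_Ig / length(im$I_Ig),
    bsa_avg_Ag = im$bsa_Ag / length(im$I_Ag),
    bsa_Ig = im$bsa_Ig, bsa_Ag = im$bsa_Ag,
    n_Ig = length(im$I_Ig), n_Ag = length(im$I_Ag)
  )
}

# Resolve an interface-atom filter to a set of atom ids.
.filter_interface_atoms <- function(im, atoms = NULL, side = NULL, region = NULL) {
  sel <- im$atoms$interface
  if (!is.null(side)) sel <- sel & im$atoms$partner == side
  if (!is.null(region)) sel <- sel & im$atoms$region %in% region
  ids <- im$atoms$atom_id[sel]
  if (!is.null(atoms)) ids <- intersect(ids, as.character(atoms))
  ids
}

#' Inverse volume-weighted internal path length
#'
#' `IVW-IPL = sum over interface atoms of SO(a) / Vol_bound(a)`: large,
#' isotropic, tightly packed interfaces score high. The filter arguments
#' restrict the sum to one partner, one region, or an explicit atom set;
#' an empty filter result gives 0 (empty sum).
#'
#' @param im an `igvor_interface`
#' @param atoms optional atom-id subset
#' @param side optional partner filter (`"Ig"` or `"Ag"`)
#' @param region optional region filter (one or more region labels)
#' @param form `"inverse"` (SO/Vol, the default) or `"product"` (SO*Vol,
#'   audit variant)
#' @return IVW-IPL in Angstrom^-3 (`"inverse"` form)
#' @export
ivw_ipl <- function(im, atoms = NULL, side = NULL, region = NULL,
                    form = c("inverse", "product")) {
  form <- match.arg(form)
  stopifnot(inherits(im, "igvor_interface"))
  ids <- .filter_interface_atoms(im, atoms, side, region)
  if (!length(ids)) return(0)
  tab <- im$atoms[match(ids, im$atoms$atom_id), , drop = FALSE]
  if (anyNA(tab$so) || any(tab$so < 1)) {
    stop("interface atoms without shelling order in IVW-IPL filter")
  }
  if (any(tab$vol_bound <= 0)) {
    stop("zero restriction volume for interface atom(s): ",
         paste(tab$atom_id[tab$vol_bound <= 0], collapse = ", "))
  }
  if (form == "inverse") sum(tab$so / tab$vol_bound) else sum(tab$so * tab$vol_bound)
}

#' Average normalized shelling order of a region
#'
#' `ANSO(A) = IVW-IPL(A) / |A|` over the interface atoms `A` of a region:
#' the per-atom packing-weighted depth, independent of region size.
#'
#' @inheritParams ivw_ipl
#' @return ANSO in Angstrom^-3
#' @export
anso <- function(im, atoms = NULL, side = NULL, region = NULL) {
  ids <- .filter_interface_atoms(im, atoms, side, region)
  if (!length(ids)) {
    stop("ANSO is undefined for an empty interface-atom set")
  }
  ivw_ipl(im, atoms = ids) / length(ids)
}

#' Charged fraction of the non-interacting surface
#'
#' Over residues of both partners that are solvent-exposed in the complex
#' (summed bound exposed area above `area_threshold`) and contribute no
#' interface atom, returns the fraction belonging to the charged set.
#'
#' @param s the `ComplexStructure` (for residue identities)
#' @param im the matching `igvor_interface`
#' @param area_threshold residue surface-exposure threshold (Angstrom^2)
#' @param charged charged residue names (default ASP, GLU, LYS, ARG, HIS)
#' @return fraction in `[0, 1]`
#' @export
nis_charged <- function(s, im, area_threshold = 1,
                        charged = .CHARGED_DEFAULT) {
  stopifnot(inherits(im, "igvor_interface"))
  tab <- im$atoms[im$atoms$partner %in% c("Ig", "Ag"), , drop = FALSE]
  res_key <- paste(tab$chain_id, tab$residue_seq, tab$residue_name, sep = "\r")
  surf <- tapply(tab$area_bound, res_key, sum) > area_threshold
  has_if <- tapply(tab$interface, res_key, any)
  nis <- names(surf)[surf & !has_if]
  if (!length(nis)) {
    stop("no non-interacting surface residues: NIS fraction undefined")
  }
  resname <- vapply(strsplit(nis, "\r", fixed = TRUE), `[`, "", 3)
  mean(resname %in% charged)
}

#' Per-region interface decomposition
#'
#' Splits the Ig-side interface into the 14 CDR/FR regions (plus
#' constant/outside-V) and the Ag side, reporting per region the interface
#' atom count, BSA, IVW-IPL, ANSO, mean shelling order, mean restriction
#' volume, and the residue count of the region in the structure.
#'
#' @param s the `ComplexStructure` (annotated)
#' @param im the matching `igvor_interface`
#' @return data frame, one row per region
#' @export
region_breakdown <- function(s, im) {
  stopifnot(inherits(im, "igvor_interface"))
  regions <- setdiff(region_labels(), "water")
  tab <- im$atoms
  res_key <- paste(s$atoms$chain_id, s$atoms$residue_seq, sep = "\r")
  out <- lapply(regions, function(rg) {
    ids <- .filter_interface_atoms(im, region = rg)
    sub <- tab[match(ids, tab$atom_id), , drop = FALSE]
    n_res <- length(unique(res_key[s$atoms$region %in% rg]))
    data.frame(
      region = rg,
      n_atoms = length(ids),
      n_residues = n_res,
      bsa = if (length(ids)) sum(sub$bsa) else 0,
      ivw_ipl = if (length(ids)) ivw_ipl(im, atoms = ids) else 0,
      anso = if (length(ids)) anso(im, atoms = ids) else NA_real_,
      mean_so = if (length(ids)) mean(sub$so) else NA_real_,
      mean_vol = if (length(ids)) mean(sub$vol_bound) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Compute the full descriptor set of one complex
#'
#' @param s annotated `ComplexStructure`
#' @param im matching `igvor_interface`
#' @param complex_id identifier carried into tables
#' @param ... passed to [nis_charged()]
#' @return object of class `igvor_descriptor`: per-complex scalars plus the
#'   `per_region` data frame
#' @export
compute_descriptors <- function(s, im, complex_id = "complex", ...) {
  av <- bsa_averages(im)
  structure(list(
    complex_id = complex_id,
    ligand_type = s$ligand_type,
    n_interface_Ig = av$n_Ig,
    n_interface_Ag = av$n_Ag,
    bsa_Ig = av$bsa_Ig,
    bsa_Ag = av$bsa_Ag,
    bsa_avg_Ig = av$bsa_avg_Ig,
    bsa_avg_Ag = av$bsa_avg_Ag,
    ivw_ipl = ivw_ipl(im),
    nis_charged = nis_charged(s, im, ...),
    per_region = region_breakdown(s, im)
  ), class = "igvor_descriptor")
}

# Flatten one descriptor into a single row (per-region columns suffixed by
# the region name with "-" replaced by "_").
.descriptor_row <- function(d) {
  row <- data.frame(
    complex_id = d$complex_id,
    ligand_type = d$ligand_type,
    n_interface_Ig = d$n_interface_Ig,
    n_interface_Ag = d$n_interface_Ag,
    n_interface = d$n_interface_Ig + d$n_interface_Ag,
    bsa_Ig = d$bsa_Ig, bsa_Ag = d$bsa_Ag,
    bsa_avg_Ig = d$bsa_avg_Ig, bsa_avg_Ag = d$bsa_avg_Ag,
    ivw_ipl = d$ivw_ipl, nis_charged = d$nis_charged,
    stringsAsFactors = FALSE
  )
  pr <- d$per_region
  for (k in seq_len(nrow(pr))) {
    suf <- gsub("-", "_", pr$region[k], fixed = TRUE)
    row[[paste0("n_atoms_", suf)]] <- pr$n_atoms[k]
    row[[paste0("n_residues_", suf)]] <- pr$n_residues[k]
    row[[paste0("bsa_", suf)]] <- pr$bsa[k]
    row[[paste0("ivw_ipl_", suf)]] <- pr$ivw_ipl[k]
    row[[paste0("anso_", suf)]] <- pr$anso[k]
  }
  row
}

#' Batch descriptor table
#'
#' Computes descriptors for a list of complexes, logging per-complex
#' failures without aborting the batch.
#'
#' @param complexes named list; each element either an `igvor_descriptor` or
#'   a list with components `structure` and `interface`
#' @param ... passed to [compute_descriptors()]
#' @return data frame, one row per successful complex; failures are recorded
#'   in the `"failures"` attribute and reported as a warning
#' @export
descriptor_table <- function(complexes, ...) {
  if (is.null(names(complexes))) {
    names(complexes) <- sprintf("complex_%03d", seq_along(complexes))
  }
  rows <- list()
  failures <- character(0)
  for (nm in names(complexes)) {
    cx <- complexes[[nm]]
    row <- tryCatch({
      d <- if (inherits(cx, "igvor_descriptor")) cx else
        compute_descriptors(cx$structure, cx$interface, complex_id = nm, ...)
      .descriptor_row(d)
    }, error = function(e) {
      failures[[nm]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) rows[[nm]] <- row
  }
  if (length(failures)) {
    warning(sprintf("descriptor_table: %d complex(es) failed: %s",
                    length(failures),
                    paste(names(failures), collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "failures") <- failures
  out
}
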