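# Structure parsing, radius assignment, altloc policy, IMGT region limits,
# canonical-complex validation.

write_mini_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB parsing keeps heavy atoms, waters, and assigns radii", {
  path <- write_mini_pdb(c(
    pdb_line(serial = 1, name = "CA", resname = "GLY", chain = "H",
             resno = 110, x = 0, y = 0, z = 0, element = "C"),
    pdb_line(serial = 2, name = "N", resname = "GLY", chain = "G",
             resno = 1, x = 3, y = 0, z = 0, element = "N"),
    pdb_line(record = "HETATM", serial = 3, name = "O", resname = "HOH",
             chain = "W", resno = 201, x = 1.5, y = 2, z = 0, element = "O")
  ))
  s <- read_structure(path, heavy_chain = "H", light_chain = "L")
  expect_s3_class(s, "igvor_structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(sum(s$atoms$partner == "water"), 1)
  expect_equal(sum(s$atoms$partner %in% c("Ig", "Ag")), 2)
  # bondi radii: C 1.70, N 1.55, O 1.52
  expect_equal(sort(s$atoms$r_vdw), c(1.52, 1.55, 1.70))
  expect_true(all(s$atoms$region[s$atoms$partner == "water"] == "water"))
  expect_identical(s$ligand_chain_ids, "G")
})

test_that("hydrogens are dropped and unknown elements are errors unless a fallback is set", {
  path <- write_mini_pdb(c(
    pdb_line(serial = 1, name = "CA", resname = "GLY", chain = "H",
             resno = 5, x = 0, y = 0, z = 0, element = "C"),
    pdb_line(serial = 2, name = "HA", resname = "GLY", chain = "H",
             resno = 5, x = 0.5, y = 0, z = 0, element = "H"),
    pdb_line(serial = 3, name = "X1", resname = "LIG", chain = "G",
             resno = 1, x = 3, y = 0, z = 0, element = "XX")
  ))
  expect_error(read_structure(path), "XX")
  s <- read_structure(path, fallback_radius = 1.7)
  expect_equal(nrow(s$atoms), 2) # hydrogen dropped
  expect_equal(s$atoms$r_vdw[s$atoms$element == "XX"], 1.7)
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties alphabetical", {
  path <- write_mini_pdb(c(
    pdb_line(serial = 1, name = "CA", alt = "A", resname = "GLY", chain = "H",
             resno = 5, x = 0, y = 0, z = 0, occ = 0.6, element = "C"),
    pdb_line(serial = 2, name = "CA", alt = "B", resname = "GLY", chain = "H",
             resno = 5, x = 1, y = 0, z = 0, occ = 0.4, element = "C"),
    pdb_line(serial = 3, name = "CB", alt = "B", resname = "SER", chain = "G",
             resno = 1, x = 3, y = 0, z = 0, occ = 0.5, element = "C"),
    pdb_line(serial = 4, name = "CB", alt = "A", resname = "SER", chain = "G",
             resno = 1, x = 4, y = 0, z = 0, occ = 0.5, element = "C")
  ))
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$chain_id == "H"], 0) # occupancy 0.6 wins
  expect_equal(s$atoms$x[s$atoms$chain_id == "G"], 4) # tie -> conformer A
})

test_that("fixture files round-trip through write and read", {
  s <- make_random_complex(n_ig = 6, n_ag = 4, seed = 11)
  # PDB stores three decimals; quantize so the round trip is exact
  s$atoms$x <- round(s$atoms$x, 3)
  s$atoms$y <- round(s$atoms$y, 3)
  s$atoms$z <- round(s$atoms$z, 3)
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(s, path)
  s2 <- read_structure(path, heavy_chain = "H", light_chain = "L",
                       fallback_radius = 1.7)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  ord1 <- order(s$atoms$chain_id, s$atoms$residue_seq, s$atoms$x)
  ord2 <- order(s2$atoms$chain_id, s2$atoms$residue_seq, s2$atoms$x)
  for (col in c("x", "y", "z", "residue_seq", "chain_id", "partner",
                "element", "residue_name")) {
    expect_equal(s2$atoms[[col]][ord2], s$atoms[[col]][ord1], info = col)
  }
})

test_that("mmCIF files parse with the same atom semantics as PDB", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id", "label_comp_id",
                            "label_asym_id", "label_entity_id",
                            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                            "Cartn_y", "Cartn_z", "occupancy",
                            "B_iso_or_equiv", "pdbx_formal_charge",
                            "auth_seq_id", "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 C CA . GLY H 1 110 ? 0.000 0.000 0.000 1.00 0.00 ? 110 GLY H CA 1",
    "ATOM 2 N N . ALA G 2 1 ? 3.000 0.000 0.000 1.00 0.00 ? 1 ALA G N 1",
    "HETATM 3 O O . HOH W 3 . ? 1.500 2.000 0.000 1.00 0.00 ? 201 HOH W O 1"
  ), path)
  s <- suppressWarnings(read_structure(path, heavy_chain = "H",
                                       light_chain = "L"))
  expect_equal(nrow(s$atoms), 3)
  expect_identical(sort(s$atoms$partner), c("Ag", "Ig", "water"))
  expect_equal(sort(s$atoms$r_vdw), c(1.52, 1.55, 1.70))
  s <- annotate_regions(s, "imgt-numbered")
  expect_equal(s$atoms$region[s$atoms$chain_id == "H"], "VH-CDR3")
})

test_that("unreadable files raise a parse error naming the file", {
  bad <- tempfile(fileext = ".pdb")
  expect_error(read_structure(bad), "not found")
  writeLines("this is not a structure", bad)
  expect_error(suppressWarnings(read_structure(bad)), "")
})

test_that("IMGT unique-numbering limits label every V-domain residue", {
  atoms <- rbind(
    igvor:::.fixture_atoms(0:6, 0, 0, 1.7, "Ig", NA_character_, chain = "H",
                           resno = c(1, 27, 39, 56, 66, 110, 130)),
    igvor:::.fixture_atoms(10, 0, 0, 1.7, "Ig", NA_character_, chain = "L",
                           resno = 1),
    igvor:::.fixture_atoms(20, 0, 0, 1.7, "Ag", "antigen", chain = "G")
  )
  atoms$atom_id <- sprintf("T%03d", seq_len(nrow(atoms)))
  s <- fixture_structure(atoms)
  s <- annotate_regions(s, "imgt-numbered")
  lab <- setNames(s$atoms$region, paste0(s$atoms$chain_id, s$atoms$residue_seq))
  expect_equal(unname(lab["H110"]), "VH-CDR3")
  expect_equal(unname(lab["H1"]), "VH-FR1")
  expect_equal(unname(lab["H27"]), "VH-CDR1")
  expect_equal(unname(lab["H39"]), "VH-FR2")
  expect_equal(unname(lab["H56"]), "VH-CDR2")
  expect_equal(unname(lab["H66"]), "VH-FR3")
  expect_equal(unname(lab["H130"]), "constant")
  expect_equal(unname(lab["L1"]), "VL-FR1")
  # every Ig residue carries exactly one label
  expect_false(anyNA(s$atoms$region[s$atoms$partner == "Ig"]))
  # idempotent
  s2 <- annotate_regions(s, "imgt-numbered")
  expect_identical(s2$atoms$region, s$atoms$region)
})

test_that("sidecar annotation validates coverage and rejects overlaps", {
  atoms <- rbind(
    igvor:::.fixture_atoms(0:2, 0, 0, 1.7, "Ig", NA_character_, chain = "H",
                           resno = c(50, 51, 52)),
    igvor:::.fixture_atoms(10, 0, 0, 1.7, "Ag", "antigen", chain = "G")
  )
  atoms$atom_id <- sprintf("T%03d", seq_len(nrow(atoms)))
  s <- fixture_structure(atoms)
  side <- tempfile(fileext = ".csv")

  writeLines(c("chain_id,start,end,insertion_codes,region",
               "H,50,52,,VH-CDR2"), side)
  s1 <- annotate_regions(s, side)
  expect_true(all(s1$atoms$region[s1$atoms$partner == "Ig"] == "VH-CDR2"))

  writeLines(c("chain_id,start,end,insertion_codes,region",
               "H,50,52,,VH-CDR2", "H,52,60,,VH-FR3"), side)
  expect_error(annotate_regions(s, side), "overlap")

  writeLines(c("chain_id,start,end,insertion_codes,region",
               "H,50,51,,VH-CDR2"), side)
  expect_error(annotate_regions(s, side), "H:52")
})

test_that("canonical-complex validation reports violations without throwing", {
  s <- make_random_complex(n_ig = 4, n_ag = 3, seed = 2)
  expect_identical(validate_canonical(s), character(0))

  s_nolight <- s
  s_nolight$light_chain_id <- NA_character_
  expect_match(validate_canonical(s_nolight), "light chain", all = FALSE)

  s_mixed <- s
  s_mixed$ligand_chain_ids <- c("G", "X")
  v <- validate_canonical(s_mixed,
                          ligand_types = c(G = "peptide", X = "chemical"))
  expect_match(v, "mixed ligand types", all = FALSE)

  s_nolig <- s
  s_nolig$atoms <- s_nolig$atoms[s_nolig$atoms$partner != "Ag", ]
  expect_match(validate_canonical(s_nolig), "no ligand atoms", all = FALSE)
})
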