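# Descriptor arithmetic (Eq.-level identities), NIS, per-region
# decomposition, and the batch descriptor table.

# hand-built interface: 3 Ig interface atoms with (SO, Vol) = (1,10), (1,20),
# (2,5) and 2 Ag interface atoms, plus non-interface surface residues
hand_interface <- function() {
  atoms <- data.frame(
    atom_id = c("i1", "i2", "i3", "a1", "a2", "s1", "s2", "s3", "s4"),
    partner = c(rep("Ig", 3), rep("Ag", 2), rep("Ig", 2), rep("Ag", 2)),
    chain_id = c(rep("H", 3), rep("G", 2), "H", "H", "G", "G"),
    residue_name = c("TYR", "TYR", "SER", "ALA", "ALA",
                     "LYS", "GLY", "ASP", "THR"),
    residue_seq = c(110, 110, 111, 1, 2, 40, 41, 5, 6),
    region = c("VH-CDR3", "VH-CDR3", "VH-CDR1", "antigen", "antigen",
               "VH-FR2", "VH-FR2", "antigen", "antigen"),
    vol_bound = c(10, 20, 5, 8, 12, 15, 15, 15, 15),
    area_bound = c(2, 0, 1, 3, 0, 10, 5, 8, 0.5),
    area_unbound = c(52, 40, 21, 53, 30, 10, 5, 8, 0.5),
    bsa = c(50, 40, 20, 50, 30, 0, 0, 0, 0),
    so = c(1L, 1L, 2L, 1L, 1L, NA, NA, NA, NA),
    interface = c(rep(TRUE, 5), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
  fake_interface(atoms, I_Ig = c("i1", "i2", "i3"), I_Ag = c("a1", "a2"))
}

test_that("average BSA per interface atom is the plain ratio, per side", {
  im <- hand_interface()
  av <- bsa_averages(im)
  expect_equal(av$bsa_avg_Ig, 110 / 3)
  expect_equal(av$bsa_avg_Ag, 40)
  expect_equal(av$n_Ig, 3)

  im_empty <- im
  im_empty$I_Ag <- character(0)
  expect_error(bsa_averages(im_empty), "undefined")
})

test_that("IVW-IPL and ANSO match hand arithmetic and their identity", {
  im <- hand_interface()
  # (1/10) + (1/20) + (2/5) = 0.55 on the Ig side
  expect_equal(ivw_ipl(im, side = "Ig"), 0.55)
  expect_equal(anso(im, side = "Ig"), 0.55 / 3)
  expect_equal(anso(im, side = "Ig") * 3, ivw_ipl(im, side = "Ig"))
  # empty filter: empty sum for IVW-IPL, undefined for ANSO
  expect_equal(ivw_ipl(im, region = "VL-CDR1"), 0)
  expect_error(anso(im, region = "VL-CDR1"), "undefined")
  # product form differs (audit flag)
  expect_equal(ivw_ipl(im, side = "Ig", form = "product"), 10 + 20 + 10)
  # zero restriction volume is a hard error
  im_bad <- im
  im_bad$atoms$vol_bound[1] <- 0
  expect_error(ivw_ipl(im_bad, side = "Ig"), "zero restriction volume")
})

test_that("NIS charged fraction counts exposed non-interface residues", {
  im <- hand_interface()
  # NIS residues: H40 LYS (charged), H41 GLY, G5 ASP (charged); G6 THR is
  # below the 1 A^2 exposure threshold
  expect_equal(nis_charged(NULL, im), 2 / 3)
  # threshold is configurable: lowering it admits G6 THR
  expect_equal(nis_charged(NULL, im, area_threshold = 0.1), 2 / 4)
  # charged set is configurable
  expect_equal(nis_charged(NULL, im, charged = c("LYS")), 1 / 3)
  # removing a non-interface LYS changes the value by the expected recount
  im2 <- im
  im2$atoms <- im2$atoms[im2$atoms$atom_id != "s1", ]
  expect_equal(nis_charged(NULL, im2), 1 / 2)
  # every residue at the interface -> undefined
  im3 <- im
  im3$atoms <- im3$atoms[im3$atoms$interface, ]
  expect_error(nis_charged(NULL, im3), "undefined")
})

test_that("region decomposition is an exact partition of the Ig side", {
  for (seed in c(4, 8)) {
    s <- make_random_complex(n_ig = 12, n_ag = 8, seed = seed)
    im <- extract_interface(s, n_surf = 2048)
    d <- compute_descriptors(s, im, complex_id = paste0("c", seed))
    pr <- d$per_region
    ig_rows <- !pr$region %in% "antigen"
    expect_equal(sum(pr$bsa[ig_rows]), d$bsa_Ig, tolerance = 1e-6)
    expect_equal(sum(pr$ivw_ipl[ig_rows]), ivw_ipl(im, side = "Ig"),
                 tolerance = 1e-6)
    expect_equal(sum(pr$ivw_ipl), d$ivw_ipl, tolerance = 1e-6)
    expect_equal(sum(pr$n_atoms[ig_rows]), d$n_interface_Ig)
    # anso * |A| = region IVW-IPL; anso = mean of SO/Vol (not mean_so/mean_vol)
    nz <- pr$n_atoms > 0
    expect_equal(pr$anso[nz] * pr$n_atoms[nz], pr$ivw_ipl[nz],
                 tolerance = 1e-12)
    for (rg in pr$region[nz]) {
      sub <- im$atoms[im$atoms$interface & im$atoms$region == rg, ]
      expect_equal(pr$anso[pr$region == rg], mean(sub$so / sub$vol_bound),
                   tolerance = 1e-12)
    }
  }
})

test_that("small convex ligands bury more area per atom than flat ones", {
  # Ig wall: 3x3 grid of balls; Ag either one small ball (convex tip) or a
  # matching flat 3x3 wall at the same gap
  grid <- expand.grid(y = c(-2.2, 0, 2.2), z = c(-2.2, 0, 2.2))
  wall <- igvor:::.fixture_atoms(rep(0, 9), grid$y, grid$z, 1.8, "Ig", "VH-CDR3")
  tip <- igvor:::.fixture_atoms(2.6, 0, 0, 1.5, "Ag", "antigen")
  flat <- igvor:::.fixture_atoms(rep(3.0, 9), grid$y, grid$z, 1.8, "Ag", "antigen")
  flat$atom_id <- sprintf("F%03d", 1:9)
  s_tip <- fixture_structure(rbind(wall, tip))
  s_flat <- fixture_structure(rbind(wall, flat))
  av_tip <- bsa_averages(extract_interface(s_tip, r_w = 1.4, n_surf = 2048))
  av_flat <- bsa_averages(extract_interface(s_flat, r_w = 1.4, n_surf = 2048))
  expect_gt(av_tip$bsa_avg_Ag, av_flat$bsa_avg_Ag)
  # curvature complementarity: the wall facing the tip buries less per atom
  expect_lt(av_tip$bsa_avg_Ig, av_tip$bsa_avg_Ag)
})

test_that("BSA and interface size are strongly positively correlated", {
  rows <- lapply(1:10, function(seed) {
    n <- 6 + 2 * (seed %% 5)
    s <- make_random_complex(n_ig = n, n_ag = n - 2, seed = seed)
    im <- extract_interface(s, n_surf = 1024)
    data.frame(bsa = im$bsa_Ig + im$bsa_Ag,
               n_int = length(im$I_Ig) + length(im$I_Ag))
  })
  tab <- do.call(rbind, rows)
  expect_gt(cor(tab$bsa, tab$n_int), 0.5)
})

test_that("descriptor_table batches complexes and logs failures", {
  mk <- function(seed) {
    s <- make_random_complex(n_ig = 8, n_ag = 6, seed = seed)
    list(structure = s, interface = extract_interface(s, n_surf = 1024))
  }
  cx <- list(a = mk(1), b = mk(2), c = mk(3))
  tab <- descriptor_table(cx)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$complex_id, c("a", "b", "c"))
  # schema includes every headline descriptor and the per-region columns
  expect_true(all(c("bsa_avg_Ig", "bsa_avg_Ag", "ivw_ipl", "nis_charged",
                    "n_interface", "bsa_VH_CDR3", "ivw_ipl_VH_CDR3",
                    "anso_VH_CDR3", "n_residues_VL_CDR1") %in% names(tab)))

  # a failing complex is logged, the rest of the batch survives
  broken <- mk(4)
  broken$interface$I_Ag <- character(0)
  cx$bad <- broken
  expect_warning(tab2 <- descriptor_table(cx), "failed")
  expect_equal(nrow(tab2), 3)
  expect_match(names(attr(tab2, "failures")), "bad")
  # column order is stable across runs
  expect_identical(names(tab2), names(tab))
})
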