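test_that("a toy PDB plus SDF loads into a complex", {
  arc <- simulate_complex("hbond", seed = 1, rotate = FALSE)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  # receptor-only file
  write_complex_pdb(complex3d(arc$complex$receptor,
                              ligand_pose(data.frame(element = "C", x = 99,
                                                     y = 99, z = 99, charge = 0L),
                                          NULL)), pdb)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  la <- arc$complex$ligand$atoms
  write_sdf_fixture(la, arc$complex$ligand$bonds, sdf)
  cx <- load_complex(pdb, sdf)
  expect_s3_class(cx, "complex3d")
  expect_equal(nrow(residue_tbl <- pocket_panel(cx, 1e6)), 5L)
  expect_equal(nrow(cx$ligand$atoms), nrow(la))
})

test_that("HETATM extraction equals the split-file route", {
  arc <- simulate_complex("hbond", seed = 2, rotate = FALSE)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(arc$complex, pdb)
  cx_het <- load_complex(pdb, ligand_resname = "LIG")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_fixture(arc$complex$ligand$atoms, arc$complex$ligand$bonds, sdf)
  cx_split <- load_complex(pdb, sdf)
  expect_equal(cx_het$ligand$atoms$element, cx_split$ligand$atoms$element)
  expect_equal(as.matrix(cx_het$ligand$atoms[, c("x", "y", "z")]),
               as.matrix(cx_split$ligand$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3)
  e1 <- detect_interactions(cx_het)
  e2 <- detect_interactions(cx_split)
  expect_equal(e1$itype, e2$itype)
  expect_error(load_complex(pdb, ligand_resname = "XXX"), "no HETATM")
})

test_that("SDF formal charges are read from the charge property block", {
  atoms <- data.frame(element = c("N", "C"), x = c(0, 1.49), y = 0, z = 0,
                      charge = c(1L, 0L))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_fixture(atoms, data.frame(from = 1, to = 2, order = 1), sdf)
  lig <- read_ligand_sdf(sdf)
  expect_equal(lig$atoms$charge, c(1L, 0L))
})

test_that("generic-number mapping annotates matching residues only", {
  arc <- simulate_complex("ionic", seed = 1, rotate = FALSE)
  rec <- arc$complex$receptor
  rec$atoms$resno[rec$atoms$resno == 2] <- 121
  mapped <- map_generic_numbers(rec, data.frame(chain = "A", resnum = 121,
                                                generic = "3x32"))
  rt <- residue_table_of(mapped)
  expect_equal(rt$generic[rt$resno == 121], "3x32")
  expect_true(all(is.na(rt$generic[rt$resno != 121])))
  # empty mapping: no annotations, empty unmatched report
  m0 <- map_generic_numbers(rec, data.frame(chain = character(0),
                                            resnum = integer(0),
                                            generic = character(0)))
  expect_true(all(is.na(m0$atoms$generic)))
  expect_equal(nrow(attr(m0, "unmatched")), 0L)
  expect_error(map_generic_numbers(rec, data.frame(chain = "A", resnum = 1:2,
                                                   generic = c("3x32", "3x32"))),
               "duplicate")
  expect_error(map_generic_numbers(rec, data.frame(chain = "A", resnum = 1,
                                                   generic = "helix3-32")),
               "invalid generic")
})

test_that("the shipped mapping covers all generic positions under study", {
  mapping <- read.csv(system.file("extdata",
                                  "gpcrdb_mapping_5ht5a_synthetic.csv",
                                  package = "gpcrsift"))
  named_positions <- c("2x64", "3x28", "3x29", "3x32", "3x33", "3x36",
                       "45x50", "45x51", "45x52", "45x53",
                       "5x36", "5x39", "5x40", "5x43", "5x44",
                       "4x56", "4x57", "4x60", "4x61",
                       "6x48", "6x51", "6x52", "6x55", "7x38", "7x42")
  expect_length(named_positions, 25L)
  expect_true(all(named_positions %in% mapping$generic))
  # build a receptor spanning the mapped residues and annotate it
  atoms <- data.frame(chain = "A", resno = mapping$resnum, insert = "",
                      resid = "GLY", elety = "CA", elesy = "C",
                      x = seq_along(mapping$resnum), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  rec <- map_generic_numbers(receptor_structure(atoms), mapping)
  annotated <- residue_table_of(rec)$generic
  expect_equal(sum(named_positions %in% annotated), 25L)
  expect_equal(nrow(attr(rec, "unmatched")), 0L)
})

test_that("pocket panel selects residues by heavy-atom distance", {
  arc <- simulate_complex("hbond", seed = 3, rotate = FALSE)
  panel <- pocket_panel(arc$complex, 6.0)
  expect_equal(panel$resno, 1L)  # only the serine is near the methanol
  expect_equal(nrow(pocket_panel(arc$complex, 0)), 0L)
  # monotone in cutoff
  sizes <- vapply(c(2, 4, 6, 12, 20, 40), function(ct)
    nrow(pocket_panel(arc$complex, ct)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  big <- pocket_panel(arc$complex, 40)
  small <- pocket_panel(arc$complex, 6)
  expect_true(all(small$key %in% big$key))
})

test_that("pose RMSD obeys its contracts", {
  arc <- simulate_complex("aromatic", seed = 1, rotate = FALSE)
  b <- arc$complex$ligand
  expect_equal(pose_rmsd(b, b), 0)
  b_shift <- b
  b_shift$atoms$x <- b_shift$atoms$x + 1
  expect_equal(pose_rmsd(b, b_shift), 1.0)
  other <- ligand_pose(data.frame(element = c("C", "C"), x = 0:1, y = 0, z = 0,
                                  charge = 0L),
                       data.frame(from = 1, to = 2, order = 1))
  expect_error(pose_rmsd(b, other), "heavy-atom count")
})

test_that("symmetry-aware RMSD collapses benzene ring rotations to zero", {
  arc <- simulate_complex("aromatic", seed = 1, rotate = FALSE)
  b <- arc$complex$ligand
  cen <- colMeans(b$atoms[, c("x", "y", "z")])
  th <- pi / 3
  br <- b
  xy <- cbind(br$atoms$x - cen[1], br$atoms$y - cen[2])
  br$atoms$x <- cen[1] + xy[, 1] * cos(th) - xy[, 2] * sin(th)
  br$atoms$y <- cen[2] + xy[, 1] * sin(th) + xy[, 2] * cos(th)
  expect_gt(pose_rmsd(b, br), 1)
  expect_equal(pose_rmsd(b, br, symmetry_aware = TRUE), 0, tolerance = 1e-8)
  # brute-force automorphism count of the benzene ring graph is 12
  g <- igraph::make_ring(6)
  expect_length(igraph::isomorphisms(g, g), 12L)
  # exceeding the cap falls back to naive matching with a warning
  expect_warning(r <- pose_rmsd(b, br, symmetry_aware = TRUE,
                                automorphism_cap = 2L), "cap")
  expect_gt(r, 1)
})

test_that("pose RMSD behaves as a pseudometric on same-molecule poses", {
  set.seed(11)
  arc <- simulate_complex("aromatic", seed = 1, rotate = FALSE)
  base <- arc$complex$ligand
  jitter_pose <- function(p) {
    p$atoms$x <- p$atoms$x + rnorm(nrow(p$atoms), 0, 0.5)
    p$atoms$y <- p$atoms$y + rnorm(nrow(p$atoms), 0, 0.5)
    p$atoms$z <- p$atoms$z + rnorm(nrow(p$atoms), 0, 0.5)
    p
  }
  for (rep in 1:10) {
    a <- jitter_pose(base); b <- jitter_pose(base); c_ <- jitter_pose(base)
    dab <- pose_rmsd(a, b, symmetry_aware = TRUE)
    dba <- pose_rmsd(b, a, symmetry_aware = TRUE)
    dac <- pose_rmsd(a, c_, symmetry_aware = TRUE)
    dcb <- pose_rmsd(c_, b, symmetry_aware = TRUE)
    expect_equal(dab, dba, tolerance = 1e-10)
    expect_lte(dab, dac + dcb + 1e-10)
  }
})

test_that("frame superposition recovers rigid motions exactly", {
  arc <- simulate_complex("hbond", seed = 4, rotate = FALSE)
  base <- arc$complex
  ident <- superpose_frames(list(base, base, base))
  for (tr in ident$transforms) {
    expect_equal(tr$rotation, diag(3), tolerance = 1e-8)
    expect_equal(tr$translation, rep(0, 3), tolerance = 1e-8)
  }
  moved <- rigid_transform_complex(base, angle = 1.1, axis = c(1, 2, 0.5))
  al <- superpose_frames(list(base, moved))
  sel <- al$frames[[2]]$receptor$atoms$elety == "CA"
  dev <- as.matrix(al$frames[[2]]$receptor$atoms[sel, c("x", "y", "z")]) -
    as.matrix(base$receptor$atoms[sel, c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums(dev^2))), 1e-8)
  # transforms are proper rotations
  for (tr in al$transforms) expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
})

test_that("superposition reaches the noise floor under coordinate noise", {
  set.seed(13)
  arc <- simulate_complex("hbond", seed = 5, rotate = FALSE)
  base <- arc$complex
  sigma <- 0.1
  frames <- lapply(1:5, function(k) {
    cx <- rigid_transform_complex(base, angle = runif(1, 0, pi),
                                  axis = rnorm(3), shift = rnorm(3, 0, 20))
    n <- nrow(cx$receptor$atoms)
    cx$receptor$atoms$x <- cx$receptor$atoms$x + rnorm(n, 0, sigma)
    cx$receptor$atoms$y <- cx$receptor$atoms$y + rnorm(n, 0, sigma)
    cx$receptor$atoms$z <- cx$receptor$atoms$z + rnorm(n, 0, sigma)
    cx
  })
  al <- superpose_frames(c(list(base), frames), selection = "all")
  for (k in 2:6) {
    dev <- as.matrix(al$frames[[k]]$receptor$atoms[, c("x", "y", "z")]) -
      as.matrix(base$receptor$atoms[, c("x", "y", "z")])
    rmsd <- sqrt(mean(rowSums(dev^2)))
    expect_lt(rmsd, 3 * sigma * sqrt(3))
    expect_gt(rmsd, 0)
  }
  # cross-check one frame against the bio3d least-squares fit
  mov <- as.matrix(frames[[1]]$receptor$atoms[, c("x", "y", "z")])
  fix <- as.matrix(base$receptor$atoms[, c("x", "y", "z")])
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(fix)),
                                            mobile = as.numeric(t(mov))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - fix)^2)))
  dev <- as.matrix(al$frames[[2]]$receptor$atoms[, c("x", "y", "z")]) - fix
  expect_equal(sqrt(mean(rowSums(dev^2))), rmsd_bio3d, tolerance = 1e-6)
})

test_that("multi-model PDB round-trips trajectory frames", {
  arc <- simulate_complex("hbond", seed = 6, rotate = FALSE)
  spec <- synthetic_spec(seed = 7, persistence = 0.7, jitter_sigma_A = 0.05)
  tr <- simulate_trajectory(arc$complex, spec, n_frames = 8)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(tr$frames, pdb)
  fr <- read_frames(pdb)
  expect_length(fr, 8L)
  for (k in seq_along(fr)) {
    expect_equal(as.matrix(fr[[k]]$ligand$atoms[, c("x", "y", "z")]),
                 as.matrix(tr$frames[[k]]$ligand$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})
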