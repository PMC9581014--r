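# Feature extraction: dihedral inversion, contact counting against a
# brute-force oracle, H-bond chemistry, rigid-motion invariance.

test_that("dihedral extraction inverts the peptide builder", {
  for (ang in list(c(-57, -47), c(-120, 120), c(60, 60))) {
    s <- build_peptide(rep(ang[1], 8), rep(ang[2], 8), "ADKLGSTW")
    di <- compute_dihedrals(s)
    expect_lt(max(abs(di$phi[2:8] - ang[1])), 1e-4)
    expect_lt(max(abs(di$psi[1:7] - ang[2])), 1e-4)
    expect_true(is.na(di$phi[1]))  # chain N-terminus
    expect_true(is.na(di$psi[8]))  # chain C-terminus
  }
})

test_that("dihedral extraction agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(3)
  n <- 12
  phis <- runif(n, -179, 179)
  psis <- runif(n, -179, 179)
  s <- build_peptide(phis, psis, paste(sample(AA <- c("A", "D", "K", "S"),
                                              n, TRUE), collapse = ""))
  tf <- tempfile(fileext = ".pdb")
  writeLines(write_structure(s), tf)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(tf, verbose = FALSE))
  di <- compute_dihedrals(s)
  expect_lt(max(abs(di$phi[-1] - tor$phi[-1])), 0.1)  # 3-decimal coords
  expect_lt(max(abs(di$psi[-n] - tor$psi[-n])), 0.1)
})

test_that("VdW threshold is a hard 5 A cutoff excluding adjacent residues", {
  # residues 1..4 on a line; pairs (1,3) at 4.9 A and (1,4) at 5.1+ A
  coords <- rbind(c(0, 0, 0), c(0, 40, 0), c(4.9, 0, 0), c(5.1, 0, 0))
  s <- parse_structure(ca_only_pdb(coords))
  ct <- count_vdw_contacts(s, "A", 1, 4)
  expect_equal(ct$vdw_intra[1], 1L)  # only residue 3 within 4.9
  expect_equal(ct$vdw_intra[3], 1L)
  expect_equal(ct$vdw_intra[4], 0L)  # 5.1 A > cutoff, and 3 is adjacent
  expect_equal(sum(ct$vdw_external), 0L)
})

test_that("contact and H-bond counts match the brute-force oracle", {
  for (seed in 1:5) {
    s <- random_ca_structure(40, seed = seed)
    start <- 5 + seed
    len <- 12
    ct <- count_vdw_contacts(s, "A", start, len)
    or <- oracle_vdw(s, "A", start, len)
    expect_equal(ct$vdw_intra, or$intra)
    expect_equal(ct$vdw_external, or$external)
  }
  # H-bonds on a realistic backbone (N/O donors/acceptors present)
  fam <- helix_family(n = 2)
  s <- fam$structures[[1]]
  hb <- detect_hbonds(s, "A", fam$offsets[1], 10)
  or <- oracle_hbonds(s, "A", fam$offsets[1], 10)
  expect_equal(hb$hd_intra, or$hd_intra)
  expect_equal(hb$hd_external, or$hd_external)
  expect_equal(hb$ha_intra, or$ha_intra)
  expect_equal(hb$ha_external, or$ha_external)
})

test_that("intra contact counting is symmetric in total", {
  s <- random_ca_structure(30, seed = 9)
  ct <- count_vdw_contacts(s, "A", 1, 30)
  # every intra pair is counted once from each endpoint
  expect_equal(sum(ct$vdw_intra) %% 2, 0)
})

test_that("alpha-helix geometry yields i,i+4 backbone H-bonds", {
  s <- build_peptide(rep(-57, 12), rep(-47, 12),
                     paste(rep("A", 12), collapse = ""))
  hb <- detect_hbonds(s, "A", 1, 12)
  # O(i) of early residues accepts from N(i+4)
  expect_gte(hb$ha_intra[2], 1)
  expect_gte(hb$hd_intra[6], 1)
})

test_that("donor-acceptor pairs beyond 3.5 A are not counted", {
  # two CA-only 'residues' cannot H-bond at all; use N/O atoms directly
  mk <- function(d) paste(c(
    pdb_line(serial = 1, name = "N", resid = "ALA", resno = 1, elem = "N"),
    pdb_line(serial = 2, name = "CA", resid = "ALA", resno = 1, x = 1.4),
    pdb_line(serial = 3, name = "O", resid = "ALA", resno = 3, x = d,
             elem = "O"),
    pdb_line(serial = 4, name = "CA", resid = "ALA", resno = 3, x = d + 1),
    "END"), collapse = "\n")
  near <- parse_structure(mk(3.4))
  far <- parse_structure(mk(3.6))
  expect_equal(detect_hbonds(near, "A", 1, 2)$hd_intra[1], 1L)
  expect_equal(detect_hbonds(far, "A", 1, 2)$hd_intra[1], 0L)
})

test_that("glycine contributes no side-chain donors or acceptors", {
  a <- data.frame(aa1 = "G", elety = c("N", "O", "CA"))
  expect_equal(efloop:::.is_donor(a), c(TRUE, FALSE, FALSE))
  expect_equal(efloop:::.is_acceptor(a), c(FALSE, TRUE, FALSE))
})

test_that("counts and dihedrals are invariant under rigid motion", {
  fam <- helix_family(n = 1)
  s <- fam$structures[[1]]
  base_ct <- count_vdw_contacts(s, "A", fam$offsets[1], 10)
  base_di <- compute_dihedrals(s)
  set.seed(4)
  for (k in 1:3) {
    ang <- runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
                c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    t <- runif(3, -30, 30)
    s2 <- s
    xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(R)
    s2$atom$x <- xyz[, 1] + t[1]
    s2$atom$y <- xyz[, 2] + t[2]
    s2$atom$z <- xyz[, 3] + t[3]
    ct <- count_vdw_contacts(s2, "A", fam$offsets[1], 10)
    expect_equal(ct, base_ct)
    di <- compute_dihedrals(s2)
    expect_lt(max(abs(di$phi - base_di$phi), na.rm = TRUE), 1e-8)
  }
})

test_that("window handling: out of range errors, gaps are flagged", {
  fam <- helix_family(n = 1)
  s <- fam$structures[[1]]
  nres <- nrow(chain_residues(s, "A"))
  expect_error(count_vdw_contacts(s, "A", nres - 3, 10), "out of range")
  expect_error(extract_loop_features(s, "A", 0, 10), "out of range")
  # strip the backbone of two residues inside a window -> flagged positions
  drop <- s
  victims <- (fam$offsets[1] + 3):(fam$offsets[1] + 4)
  drop$atom <- drop$atom[!(drop$atom$res_rank %in% victims &
                             drop$atom$chain == "A"), ]
  drop <- efloop:::.finalize_structure(
    s$id, drop$atom[, setdiff(colnames(drop$atom), c("res_key", "res_rank"))],
    drop$ligand)
  # ranks shift after removal: re-extract over the same span
  loop <- extract_loop_features(drop, "A", fam$offsets[1], 10)
  expect_s3_class(loop, "efl_loop")
  expect_true(any(is.na(loop$features$phi[-1])))  # break breaks torsions
  # isolated loop: no residues outside the window
  iso <- build_peptide(rep(-57, 10), rep(-47, 10),
                       paste(rep("A", 10), collapse = ""))
  expect_true(all(count_vdw_contacts(iso, "A", 1, 10)$vdw_external == 0))
  # partial-backbone positions are flagged, zero-counted
  part <- s
  part$atom <- part$atom[!(part$atom$res_rank == fam$offsets[1] + 2 &
                             part$atom$elety %in% c("CA", "C")), ]
  loop2 <- extract_loop_features(part, "A", fam$offsets[1], 10)
  expect_false(loop2$features$defined[3])
  expect_equal(loop2$features$vdw_intra[3], 0L)
  expect_true(is.na(loop2$features$phi[3]))
})
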