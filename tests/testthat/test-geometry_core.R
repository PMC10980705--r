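test_that("H-bond detector matches the brute-force all-pairs oracle", {
  rm_ <- tau_regions()
  frames <- list(build_ideal_hairpin(tau295_sequence(), rm_, "even"),
                 build_ideal_hairpin(tau295_sequence(), rm_, "odd"),
                 build_extended(tau295_sequence(), 294L),
                 build_coil(tau295_sequence(), 7, 294L))
  # plus noisy copies
  set.seed(42)
  for (f in frames) {
    g <- f
    g$xyz <- g$xyz + matrix(rnorm(length(g$xyz), 0, 0.15), ncol = 3)
    frames <- c(frames, list(g))
  }
  for (f in frames) {
    got <- detect_backbone_hbonds(f)
    ora <- brute_force_hbonds(f)
    expect_equal(got$donor_residue, ora$donor_residue)
    expect_equal(got$acceptor_residue, ora$acceptor_residue)
    expect_equal(got$distance, ora$distance, tolerance = 1e-9)
  }
})

test_that("H-bond cutoff is inclusive at exactly 3.50 A", {
  expect_equal(nrow(detect_backbone_hbonds(pair_distance_frame(3.50))), 1)
  expect_equal(nrow(detect_backbone_hbonds(pair_distance_frame(3.51))), 0)
  expect_equal(nrow(detect_backbone_hbonds(pair_distance_frame(2.90))), 1)
})

test_that("H-bond list is invariant under global rigid motion", {
  rm_ <- tau_regions()
  hp <- build_ideal_hairpin(tau295_sequence(), rm_, "even")
  moved <- hp
  moved$xyz <- apply_rigid(hp$xyz)
  a <- detect_backbone_hbonds(hp)
  b <- detect_backbone_hbonds(moved)
  expect_equal(a$donor_residue, b$donor_residue)
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
})

test_that("secondary structure: strands E, helix H, coils and extended C", {
  rm_ <- tau_regions()
  hp <- build_ideal_hairpin(tau295_sequence(), rm_, "even")
  ss <- assign_secondary_structure(hp)
  # both strands of the hairpin are extended sheet
  expect_true(all(ss[as.character(296:300)] == "E"))
  expect_true(all(ss[as.character(306:310)] == "E"))

  hel <- hairpinreg:::.chain_from_dihedrals(strrep("A", 15),
                                            rep(-57, 15), rep(-47, 15))
  cfh <- hairpinreg:::.conformer_from_assembled(hel, rep("A", 15))
  ssh <- assign_secondary_structure(cfh)
  expect_true(all(ssh[4:12] == "H"))

  ext <- build_extended(tau295_sequence(), 294L)
  expect_true(all(assign_secondary_structure(ext) == "C"))

  co <- build_coil(tau295_sequence(), 3, 294L)
  ssc <- assign_secondary_structure(co)
  expect_true(mean(ssc == "C") > 0.8)
  expect_true(all(assign_secondary_structure(
    hairpinreg:::.conformer_from_assembled(
      hairpinreg:::.chain_from_dihedrals("AA", c(-139, -139), c(135, 135)),
      c("A", "A"))) == "C"))  # chains shorter than 3 residues are all coil
})

test_that("secondary structure agrees with an independent DSSP reference", {
  # mdtraj's DSSP (simplified H/E/C) on the same frames, via the system
  # python; exercises hairpin strands, a helix, and an extended chain
  rm_ <- tau_regions()
  frames <- list(hairpin = build_ideal_hairpin(tau295_sequence(), rm_, "even"),
                 helix = hairpinreg:::.conformer_from_assembled(
                   hairpinreg:::.chain_from_dihedrals(strrep("A", 15),
                                                      rep(-57, 15),
                                                      rep(-47, 15)),
                   rep("A", 15)),
                 extended = build_extended(tau295_sequence(), 294L))
  simplify <- function(ss) {
    out <- rep("C", length(ss))
    out[ss %in% c("H", "G", "I")] <- "H"
    out[ss %in% c("E", "B")] <- "E"
    out
  }
  td <- tempfile(); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  pdbs <- character(0)
  for (nm in names(frames)) {
    p <- file.path(td, paste0(nm, ".pdb"))
    write_ensemble(frames[[nm]], p)
    pdbs <- c(pdbs, p)
  }
  script <- file.path(td, "ref.py")
  writeLines(c("import sys, mdtraj",
               "for f in sys.argv[1:]:",
               "    t = mdtraj.load(f)",
               "    print(''.join(mdtraj.compute_dssp(t, simplified=True)[0]))"),
             script)
  ref <- suppressWarnings(
    system2("python", c(script, pdbs), stdout = TRUE, stderr = FALSE))
  expect_length(ref, length(frames))
  for (i in seq_along(frames)) {
    ours <- paste(simplify(assign_secondary_structure(frames[[i]])),
                  collapse = "")
    expect_identical(ours, ref[i], label = names(frames)[i])
  }
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  # carbon r = 1.7, probe 1.4 -> 4*pi*3.1^2
  got <- atom_sasa(matrix(0, 1, 3), "C")
  expect_equal(got, 4 * pi * 3.1^2, tolerance = 1e-3)
  # nitrogen
  expect_equal(atom_sasa(matrix(0, 1, 3), "N"), 4 * pi * 2.95^2,
               tolerance = 1e-3)
})

test_that("SASA limits: coincident spheres count once, enclosed atoms get 0", {
  tot <- sum(atom_sasa(matrix(0, 2, 3), c("C", "C")))
  expect_equal(tot, 4 * pi * 3.1^2, tolerance = 1e-6)

  shell <- hairpinreg:::.golden_spiral(40) * 2.0
  a <- atom_sasa(rbind(c(0, 0, 0), shell), rep("C", 41))
  expect_equal(a[1], 0)
})

test_that("SASA is non-increasing as atoms are added (monotone burial)", {
  set.seed(11)
  pts <- matrix(rnorm(36, sd = 2.5), 12, 3)
  prev <- Inf
  for (k in c(3, 6, 9, 12)) {
    a <- atom_sasa(pts[1:k, , drop = FALSE], rep("C", k))
    expect_lte(a[1], prev + 1e-9)
    prev <- a[1]
  }
  expect_error(atom_sasa(matrix(0, 1, 3), "X"), "unknown element")
})

test_that("per-residue SASA integrates atoms by residue", {
  cf <- build_extended("AAAA")
  prof <- compute_sasa(cf, n_points = 240)
  expect_equal(nrow(prof), 4)
  expect_true(all(prof$sasa > 0))
  expect_equal(attr(prof, "probe_radius"), 1.4)
})

test_that("Kabsch RMSD: zero under rigid motion, symmetric, matches oracles", {
  set.seed(3)
  A <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)
  B <- apply_rigid(A)
  expect_lt(kabsch_rmsd(A, B), 1e-9)

  C <- A + matrix(rnorm(24, sd = 0.4), 8, 3)
  expect_equal(kabsch_rmsd(A, C), kabsch_rmsd(C, A), tolerance = 1e-12)
  # independent established implementation
  expect_equal(kabsch_rmsd(A, C),
               bio3d::rmsd(as.vector(t(A)), as.vector(t(C)), fit = TRUE),
               tolerance = 1e-3)
  # brute-force rotation-grid oracle on a small set
  A3 <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 1, 1, 1), 4, 3, byrow = TRUE)
  B3 <- matrix(c(0, 0, 0, 1.4, 0.3, 0, -0.2, 1.9, 0.1, 1.1, 0.8, 1.2),
               4, 3, byrow = TRUE)
  best <- Inf
  Ac <- sweep(A3, 2, colMeans(A3)); Bc <- sweep(B3, 2, colMeans(B3))
  grid <- seq(0, 2 * pi, length.out = 49)[-49]
  half <- seq(0, pi, length.out = 25)
  for (a1 in grid) for (a2 in half) for (a3 in grid) {
    Rz1 <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)), 3, 3)
    Rz2 <- matrix(c(cos(a3), -sin(a3), 0, sin(a3), cos(a3), 0, 0, 0, 1), 3, 3)
    R <- Rz1 %*% Ry %*% Rz2
    best <- min(best, sqrt(mean(rowSums((Ac %*% R - Bc)^2))))
  }
  # the closed-form optimum can only undercut the grid search, and the
  # 7.5-degree grid brackets it tightly
  expect_lte(kabsch_rmsd(A3, B3), best + 1e-9)
  expect_lt(best - kabsch_rmsd(A3, B3), 0.08)

  # triangle-like bound on test triples
  D <- A + matrix(rnorm(24, sd = 0.6), 8, 3)
  expect_lte(kabsch_rmsd(A, D),
             kabsch_rmsd(A, C) + kabsch_rmsd(C, D) + 1e-9)
  expect_error(kabsch_rmsd(A, A[1:5, ]), "equal dimensions")
})
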