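test_that("ideal constructions classify as their designated registry", {
  rm_ <- tau_regions()
  hp_e <- build_ideal_hairpin(tau295_sequence(), rm_, "even")
  a_e <- classify_hairpin(hp_e, rm_)
  expect_identical(a_e$registry, "even")
  expect_true(all(as.integer(names(a_e$pairing)) %in% rm_$even_set))
  expect_true(a_e$span_ok)
  # partners all in the N-arm, strictly decreasing (antiparallel)
  expect_true(all(a_e$pairing %in% rm_$n_arm))
  expect_true(all(diff(a_e$pairing) < 0))

  hp_o <- build_ideal_hairpin(tau295_sequence(), rm_, "odd")
  a_o <- classify_hairpin(hp_o, rm_)
  expect_identical(a_o$registry, "odd")
  expect_true(all(as.integer(names(a_o$pairing)) %in% rm_$odd_set))
})

test_that("registry shift by one residue flips even and odd", {
  rm_ <- tau_regions()
  for (tc in c(303L, 304L)) {
    even <- classify_hairpin(build_ideal_hairpin(tau295_sequence(), rm_,
                                                 "even", tc), rm_)
    odd <- classify_hairpin(build_ideal_hairpin(tau295_sequence(), rm_,
                                                "odd", tc), rm_)
    expect_identical(even$registry, "even")
    expect_identical(odd$registry, "odd")
    # the bonded rungs are shifted by exactly one residue between the classes
    expect_identical(as.integer(names(odd$pairing)),
                     as.integer(names(even$pairing)) - 1L)
  }
})

test_that("extended and mixed-parity frames classify as none with reasons", {
  rm_ <- tau_regions()
  ext <- build_extended(tau295_sequence(), 294L)
  a <- classify_hairpin(ext, rm_)
  expect_identical(a$registry, "none")
  expect_match(a$reason, "no cross-arm bonds")

  # synthetic bond table with mixed parity (306 even + 307 odd)
  hb_mixed <- data.frame(donor_residue = c(306L, 307L),
                         acceptor_residue = c(300L, 299L),
                         distance = c(2.9, 2.9))
  am <- classify_hairpin(ext, rm_, hbonds = hb_mixed)
  expect_identical(am$registry, "none")
  expect_match(am$reason, "mixed registry")
  # ... but accepted under allow_mixed with enough majority bonds
  hb_mostly <- rbind(hb_mixed,
                     data.frame(donor_residue = c(308L, 310L),
                                acceptor_residue = c(298L, 296L),
                                distance = c(2.9, 2.9)))
  expect_identical(classify_hairpin(ext, rm_, hbonds = hb_mostly,
                                    allow_mixed = TRUE)$registry, "even")

  # a single bonded residue is not a hairpin
  hb_one <- hb_mixed[1, ]
  a1 <- classify_hairpin(ext, rm_, hbonds = hb_one)
  expect_match(a1$reason, "fewer than 2")

  # parallel-like (increasing partner) geometry is rejected
  hb_par <- data.frame(donor_residue = c(306L, 308L, 310L),
                       acceptor_residue = c(296L, 298L, 300L),
                       distance = c(2.9, 2.9, 2.9))
  ap <- classify_hairpin(ext, rm_, hbonds = hb_par)
  expect_identical(ap$registry, "none")
  expect_match(ap$reason, "antiparallel")

  # full odd ladder: span [304, 310] covers the scored residues 306-310
  hb_odd <- data.frame(donor_residue = c(305L, 307L, 309L),
                       acceptor_residue = c(301L, 299L, 297L),
                       distance = c(2.9, 2.9, 2.9))
  expect_identical(classify_hairpin(ext, rm_, hbonds = hb_odd)$registry, "odd")
  # bonds confined to 306/308 leave 310 outside the span
  hb_short <- data.frame(donor_residue = c(306L, 308L),
                         acceptor_residue = c(300L, 298L),
                         distance = c(2.9, 2.9))
  a_sh <- classify_hairpin(ext, rm_, hbonds = hb_short)
  expect_identical(a_sh$registry, "none")
  expect_match(a_sh$reason, "span")
})

test_that("classification is deterministic and rigid-motion invariant", {
  rm_ <- tau_regions()
  hp <- build_ideal_hairpin(tau295_sequence(), rm_, "odd")
  a1 <- classify_hairpin(hp, rm_)
  a2 <- classify_hairpin(hp, rm_)
  expect_identical(a1, a2)
  moved <- hp
  moved$xyz <- apply_rigid(hp$xyz)
  a3 <- classify_hairpin(moved, rm_)
  expect_identical(a1$registry, a3$registry)
  expect_equal(a1$pairing, a3$pairing)
})

test_that("classifier recovers generator truth: 100% clean, >=99% at 0.2 A", {
  rm_ <- tau_regions()
  seqs <- tau295_sequence()
  n_per <- 60
  clean_ok <- 0; noisy_ok <- 0; total <- 0
  set.seed(202)
  for (par in c("even", "odd")) {
    for (tc in hairpinreg:::.feasible_turn_centres(rm_, par)) {
      hp <- build_ideal_hairpin(seqs, rm_, par, tc)
      expect_identical(classify_hairpin(hp, rm_)$registry, par)
      for (k in seq_len(n_per)) {
        cf <- hp
        cf$xyz <- cf$xyz + matrix(rnorm(length(cf$xyz), 0, 0.2), ncol = 3)
        total <- total + 1
        if (classify_hairpin(cf, rm_)$registry == par)
          noisy_ok <- noisy_ok + 1
      }
    }
  }
  expect_gte(noisy_ok / total, 0.99)
})

test_that("frame flags implement hairpin/coil orthogonality", {
  rm_ <- tau_regions()
  co <- build_coil(tau295_sequence(), 9, 294L, regions = rm_)
  ss_co <- assign_secondary_structure(co)
  a_co <- classify_hairpin(co, rm_)
  fl <- frame_flags(co, rm_, a_co, ss_co)
  expect_false(fl$is_even || fl$is_odd)
  expect_equal(fl$coil_count_hex, sum(ss_co[as.character(306:311)] == "C"))

  # a hairpin frame contributes zero coil regardless of its SS string
  hp <- build_ideal_hairpin(tau295_sequence(), rm_, "even")
  a_hp <- classify_hairpin(hp, rm_)
  fl_hp <- frame_flags(hp, rm_, a_hp, strrep("C", 17))
  expect_true(fl_hp$is_even)
  expect_equal(fl_hp$coil_count_hex, 0L)
  expect_equal(fl_hp$coil_count_raw, 6L)

  # all-E hexapeptide sets the beta flag (string input accepted)
  ss_e <- paste0(strrep("C", 11), strrep("E", 6))
  fl_e <- frame_flags(hp, rm_, a_co, ss_e)
  expect_true(fl_e$all_E_hex)
  expect_false(frame_flags(hp, rm_, a_co, strrep("C", 17))$all_E_hex)
})
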