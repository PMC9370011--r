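test_that("the contact free energy reproduces the worked segment pairs", {
  # AMAIY (4.61) with ILTII (7.36) across a 92-residue loop
  expect_equal(round(as.numeric(contact_free_energy(4.61, 7.36, 92)), 1), -8.9)
  # VQLWV (6.17) with VVVPY (5.34) across 73 residues
  expect_equal(round(as.numeric(contact_free_energy(6.17, 5.34, 73)), 1), -8.2)
  # zero hydrophobicity leaves only the entropic penalties
  expect_equal(contact_free_energy(0, 0, 65),
               1.5 * log(65) + 10.9, ignore_attr = TRUE)
  expect_equal(round(as.numeric(contact_free_energy(0, 0, 65)), 1), 17.2)
  expect_error(contact_free_energy(1, 1, 0), "n_ij")
})

test_that("energy components decompose exactly and scale with width", {
  dg <- contact_free_energy(4.61, 7.36, 92)
  comp <- attr(dg, "components")
  expect_equal(comp$dG_hyd + comp$dG_loop + comp$dG_sidechain, comp$dG_total)
  expect_equal(comp$dG_hyd, -(4.61 + 7.36) / 0.45)
  expect_equal(comp$dG_loop, 1.5 * log(92))
  # the 10.9 kT constant emerges from 1.09 kT/residue over 2w residues
  expect_equal(comp$dG_sidechain, 10.9)
  comp7 <- attr(contact_free_energy(0, 0, 65, scan_config(width = 7)),
                "components")
  expect_equal(comp7$dG_sidechain, 1.09 * 14)
})

test_that("the free energy is monotone in hydrophobicity and separation", {
  h <- seq(0, 8, by = 0.5)
  expect_true(all(diff(contact_free_energy(h, 3, 80)) < 0))
  expect_true(all(diff(contact_free_energy(3, h, 80)) < 0))
  n <- 65:100
  expect_true(all(diff(contact_free_energy(3, 3, n)) > 0))
})

test_that("candidate enumeration matches brute-force pair counting", {
  cfg <- scan_config()
  # too short for any admissible pair: empty grid with a warning
  short <- random_protein(60, seed = 1)
  expect_warning(g0 <- enumerate_candidates(short, fp_scale, cfg),
                 "no admissible")
  expect_identical(nrow(g0), 0L)
  # 70 residues admit exactly the pairs the brute-force oracle finds
  rec <- random_protein(70, seed = 2)
  grid <- enumerate_candidates(rec, fp_scale, cfg)
  oracle <- oracle_scan(rec, fp_scale, cfg)
  expect_identical(nrow(grid), nrow(oracle))
  expect_identical(canon_grid(grid)$center_a, canon_grid(oracle)$center_a)
  expect_identical(canon_grid(grid)$center_b, canon_grid(oracle)$center_b)
  # every retained separation is inside the inclusive bounds
  expect_true(all(grid$n_ij >= 65 & grid$n_ij <= 100))
  expect_true(all(grid$n_ij == grid$center_b - grid$center_a))
})

test_that("the core-domain grid contains the dominant pair at n_ij = 92", {
  grid <- enumerate_candidates(p53_core_fixture(), fp_scale, scan_config())
  row <- grid[grid$center_a == 161 & grid$center_b == 253, ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$n_ij, 92L)
  expect_identical(row$seg_a_seq, "AMAIY")
  expect_identical(row$seg_b_seq, "ILTII")
  expect_equal(row$stability_kT, -row$dG_total)
})

test_that("selection keeps each local optimum and honours the cutoff", {
  fit <- scm_scan(p53_core_fixture())
  ct <- as.data.frame(fit)
  # most stable contact first, stability within cutoff of the best
  expect_true(all(diff(ct$dG_total) >= 0))
  expect_true(all(ct$stability_kT >= max(ct$stability_kT) - 3))
  # suppression soundness: each kept contact beats every grid candidate
  # overlapping it on both segments
  grid <- fit$grid
  for (i in seq_len(nrow(ct))) {
    ov <- grid$seg_a_start <= ct$seg_a_end[i] &
          ct$seg_a_start[i] <= grid$seg_a_end &
          grid$seg_b_start <= ct$seg_b_end[i] &
          ct$seg_b_start[i] <= grid$seg_b_end
    expect_true(all(grid$dG_total[ov] >= ct$dG_total[i]))
  }
  # contacts sharing a single segment stay distinct (VVVPY here)
  expect_identical(ct$seg_b_seq[2], ct$seg_b_seq[3])
  expect_false(ct$seg_a_seq[2] == ct$seg_a_seq[3])
})

test_that("a single planted hydrophobic pair yields a single contact", {
  spec <- generator_spec(200, composition = polar_composition(), seed = 11,
                         plants = list(list(sequence = "IIIII", start = 50),
                                       list(sequence = "WWWWW", start = 120)))
  rec <- generate_sequence(spec)
  fit <- scm_scan(rec)
  ct <- as.data.frame(fit)
  expect_identical(nrow(ct), 1L)
  expect_identical(c(ct$center_a, ct$center_b), c(52L, 122L))
  expect_identical(ct$n_ij, 70L)
})

test_that("ranking ties break deterministically by separation then position", {
  # two identical planted pairs at different separations: equal dG_hyd,
  # the loop term orders them; a re-run gives byte-identical ordering
  spec <- generator_spec(300, composition = stats::setNames(1, "G"), seed = 1,
                         plants = list(list(sequence = "IIIII", start = 10),
                                       list(sequence = "IIIII", start = 100),
                                       list(sequence = "IIIII", start = 110),
                                       list(sequence = "IIIII", start = 200)))
  rec <- generate_sequence(spec)
  g1 <- enumerate_candidates(rec, fp_scale, scan_config())
  g2 <- enumerate_candidates(rec, fp_scale, scan_config())
  expect_identical(g1, g2)
  # the 12<->102 and 112<->202 pairs tie exactly; smaller a-center first
  ties <- g1[g1$n_ij == 90 & g1$h_a == 9 & g1$h_b == 9, ]
  expect_identical(nrow(ties), 2L)
  expect_lt(ties$center_a[1], ties$center_a[2])
  expect_equal(ties$dG_total[1], ties$dG_total[2])
})
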