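p53_fit <- scm_scan(p53_core_fixture())

test_that("each contact yields its two interdiction designations", {
  designs <- fitr_pairs(p53_fit, "C1")
  expect_length(designs, 2L)
  seqs <- vapply(designs, function(d) d$fip_template$sequence, character(1))
  targets <- vapply(designs, function(d) d$fitr$sequence, character(1))
  expect_setequal(seqs, c("AMAIY", "ILTII"))
  # each designation pairs one segment as template with the other as target
  expect_identical(sort(paste(seqs, targets)),
                   sort(c("AMAIY ILTII", "ILTII AMAIY")))
  c2 <- fitr_pairs(p53_fit, "C2")
  expect_setequal(vapply(c2, function(d) d$fip_template$sequence, character(1)),
                  c("VQLWV", "VVVPY"))
  expect_error(fitr_pairs(p53_fit, "C99"), "no contact")
})

test_that("the octapeptide spanning ILTII is assigned to the top contact", {
  asn <- map_peptide_to_contacts("PILTIITL", p53_fit)
  expect_gt(nrow(asn), 0L)
  # every assignment is to a contact whose segment the peptide covers
  expect_true(all(asn$segment_seq == "ILTII"))
  expect_true("C1" %in% asn$contact_label)
  # both interdiction modes are reported for each match
  c1 <- asn[asn$contact_label == "C1", ]
  expect_setequal(c1$mode, c("partner", "mask"))
  expect_true(all(asn$overlap_length == 5L))
  # no assignment to a contact lacking an overlapping segment
  no_iltii <- setdiff(unique(p53_fit$contacts$contacts$label),
                      unique(asn$contact_label))
  ct <- p53_fit$contacts$contacts
  for (lab in no_iltii) {
    row <- ct[ct$label == lab, ]
    expect_false("ILTII" %in% c(row$seg_a_seq, row$seg_b_seq))
  }
})

test_that("non-matching and shared-segment peptides map correctly", {
  expect_identical(nrow(map_peptide_to_contacts("GGGGGGGG", p53_fit)), 0L)
  # VVVPY is shared by two selected contacts: both are assigned
  asn <- map_peptide_to_contacts("VVVPY", p53_fit)
  ct <- p53_fit$contacts$contacts
  sharing <- ct$label[ct$seg_a_seq == "VVVPY" | ct$seg_b_seq == "VVVPY"]
  expect_setequal(unique(asn$contact_label), sharing)
  expect_gte(length(sharing), 2L)
  # a short peptide below min_overlap is rejected
  expect_identical(nrow(map_peptide_to_contacts("ILT", p53_fit)), 0L)
  expect_error(map_peptide_to_contacts("", p53_fit), "non-empty")
})

test_that("attachment scores drop the loop term and nothing else", {
  p53 <- p53_core_fixture()
  w_pep <- window_hydrophobicity(p53, 253, 5, fp_scale)   # ILTII
  w_tgt <- window_hydrophobicity(p53, 161, 5, fp_scale)   # AMAIY
  att <- attachment_score(w_pep, w_tgt)
  expect_equal(att, -(7.36 + 4.61) / 0.45 + 10.9)
  expect_equal(round(att, 1), -15.7)
  # zero-hydrophobicity attachment costs exactly the side-chain term
  g <- protein_record("GGGGG")
  wg <- window_hydrophobicity(g, 3, 5, fp_scale)
  expect_equal(attachment_score(wg, wg), 10.9)
  # never less favorable than the intramolecular contact (dG_loop >= 0)
  intra <- contact_free_energy(7.36, 4.61, 92)
  expect_lte(att, as.numeric(intra))
  w4 <- window_hydrophobicity(g, 2, 4, fp_scale)
  expect_error(attachment_score(w4, wg), "equal width")
})

test_that("blocked population redistributes proportionally and conserves mass", {
  base <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
  # full block of the top channel renormalizes the remaining weights
  r1 <- redistribute_populations(base, "C1", efficiency = 1)
  expect_equal(r1$result$fractions[1], 0)
  expect_equal(r1$result$fractions[-1],
               boltzmann_populations(c(8.2, 7.8, 7.8))$fractions,
               tolerance = 1e-12)
  expect_equal(round(r1$result$fractions[-1], 3), c(0.427, 0.286, 0.286))
  # identity at zero efficiency
  r0 <- redistribute_populations(base, "C1", efficiency = 0)
  expect_equal(r0$result$fractions, base$fractions, tolerance = 1e-12)
  expect_error(redistribute_populations(base, "C9", 0.5), "unknown")
  expect_error(redistribute_populations(base, "C1", 1.5), "\\[0, 1\\]")
})

test_that("redistribution conserves mass and is monotone in efficiency", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- boltzmann_populations(stats::runif(5, 2, 10))
    prev <- base$fractions
    for (eps in seq(0, 1, by = 0.25)) {
      r <- redistribute_populations(base, "C2", eps)
      expect_equal(sum(r$result$fractions), 1, tolerance = 1e-12)
      # every surviving channel is non-decreasing in efficiency
      expect_true(all(r$result$fractions[-2] >= prev[-2] - 1e-12))
      prev <- r$result$fractions
    }
  }
})

test_that("sequential full blocks equal the closed-form renormalization", {
  base <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
  r1 <- redistribute_populations(base, "C1", 1)
  r2 <- redistribute_populations(r1$result, "C2", 1)
  expect_equal(r2$result$fractions, c(0, 0, 0.5, 0.5), tolerance = 1e-12)
})

test_that("the interdiction report bundles assignments and redistributions", {
  rep <- interdiction_report(p53_fit, "PILTIITL", efficiencies = c(0.5, 1))
  expect_s3_class(rep, "interdiction_report")
  expect_true("C1" %in% rep$assignments$contact_label)
  expect_length(rep$redistributions,
                2L * length(unique(rep$assignments$contact_label)))
  full_block <- rep$redistributions[["C1@1"]]
  expect_equal(full_block$result$fractions[1], 0)
  # the model extensions are labelled as assumptions in the report itself
  expect_true(any(grepl("model extension", rep$assumptions)))
})
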