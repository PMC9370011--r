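# Shared fixtures for the test suite.

fp_scale <- load_scale("fauchere-pliska")

# Random protein over the 20 standard residues, deterministic in `seed`.
random_protein <- function(length, seed, composition = NULL) {
  generate_sequence(generator_spec(length, composition = composition,
                                   seed = seed))
}

# Polar/neutral background used for planted-pair constructions: every
# window sum is at most 5 * 0.26 = 1.3 scale units.
polar_composition <- function() {
  letters <- c("G", "S", "N", "Q", "T")
  stats::setNames(rep(1 / 5, 5), letters)
}

# Canonical view of a scored grid for oracle-equivalence comparisons:
# pair order by centers, so score ties cannot reorder rows.
canon_grid <- function(g) {
  g <- g[order(g$center_a, g$center_b),
         c("center_a", "center_b", "n_ij", "dG_total"), drop = FALSE]
  rownames(g) <- NULL
  g
}

# Write records to a temporary FASTA, returning its path.
tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(records, path)
  path
}
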