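# Hand-built toy alignments for the suitability filters: six alignments each
# violating exactly one filter condition, plus one clean alignment. Expected
# verdicts were derived by hand from the filter definitions.

qc_fixture_set <- function() {
  list(
    clean = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",   # col 10 varies
      s3 = "ACDEFGHIRL",   # col 9 varies
      s4 = "ACDEFGHWKL",   # col 8 varies
      family_id = "clean"),
    # min pairwise identity: s2 is s1 reversed, ~0 matches to every row
    low_identity = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "LKIHGFEDCA",
      s3 = "ACDEFGHIKV",
      s4 = "ACDEFGHIRL",
      family_id = "low_identity"),
    # row coverage: s4 has 4 residues of 10 columns (0.4 < 0.5)
    short_row = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",
      s3 = "ACDEFGHIRL",
      s4 = "ACDE------",
      family_id = "short_row"),
    # ambiguous character X
    has_x = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",
      s3 = "ACDEFGHIRL",
      s4 = "ACDXFGHWKL",
      family_id = "has_x"),
    # non-standard residue B
    has_b = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",
      s3 = "ACDEFGHIRL",
      s4 = "BCDEFGHWKL",
      family_id = "has_b"),
    # conserved fraction: 9 invariant columns of 10 (0.9, not < 0.9)
    too_conserved = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",
      s3 = "ACDEFGHIKW",
      s4 = "ACDEFGHIKY",
      family_id = "too_conserved"),
    # unique sequences: s4 duplicates s1 (3 unique < 4)
    few_unique = toy_msa(
      s1 = "ACDEFGHIKL",
      s2 = "ACDEFGHIKV",
      s3 = "ACDEFGHIRL",
      s4 = "ACDEFGHIKL",
      family_id = "few_unique")
  )
}

# small synthetic family with quiet defaults for fast tests
quick_family <- function(seed = 11L, n_taxa = 10L, n_sites = 120L,
                         noise = 0, indel_rate = 0.3) {
  simulate_family(simulation_config(
    n_taxa = n_taxa, n_sites = n_sites, annotation_noise = noise,
    indel_rate = indel_rate, seed = seed))
}
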