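# Shared fixtures, built once per test run. Small sizes keep individual
# tests fast; acceptance-scale runs build their own inputs.

fixture_element <- make_element_model(seed = 101)

fixture_genome <- make_genome(n_chromosomes = 2, chrom_length = 150000,
                              n_clusters = 6, seed = 102)

# deterministic qPCR table encoding planted relative abundances via Ct
# offsets: abundance a relative to the reference strain means
# Ct_target = Ct_ref_target - log2(a) at equal reference-gene Ct
make_qpcr_fixture <- function(abundances, target = "P", ref_gene = "RP49",
                              base_ct = 20) {
  strains <- names(abundances)
  do.call(rbind, lapply(strains, function(s) {
    rbind(
      data.frame(strain = s, target = target, replicate = 1:2,
                 ct = base_ct - log2(abundances[[s]]), stringsAsFactors = FALSE),
      data.frame(strain = s, target = ref_gene, replicate = 1:2,
                 ct = 15, stringsAsFactors = FALSE)
    )
  }))
}

# insertion spec helper
ins_spec <- function(classes, variants = "FP", occupancies = 1, strands = NULL) {
  n <- length(classes)
  df <- data.frame(target_class = classes,
                   variant = rep_len(variants, n),
                   occupancy = rep_len(occupancies, n),
                   stringsAsFactors = FALSE)
  if (!is.null(strands)) df$strand <- rep_len(strands, n)
  df
}
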