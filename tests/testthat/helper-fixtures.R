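# Shared fixtures, built once per test run. The micro-groove complexes are
# deterministic, so caching them is purely a speed matter.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

micro_groove <- function() cached("mg", function() make_micro_groove(1))

micro_groove_occluded <- function() {
  cached("mg_occ", function() make_micro_groove(1, occlude_pocket_b = TRUE))
}

groove_complex <- function() {
  cached("tc", function() trim_to_groove(micro_groove(), "A", "C"))
}

groove_complex_occluded <- function() {
  cached("tc_occ",
         function() trim_to_groove(micro_groove_occluded(), "A", "C"))
}

groove_set <- function() cached("groove", function() {
  groove_residues(groove_complex())
})

# Tiny two-chain complex with exactly three repackable (chi-bearing)
# residues, small enough for exhaustive rotamer enumeration.
tiny_complex <- function() cached("tiny", function() {
  pepA <- epithread:::assemble_chain(build_backbone(rep(-120, 4), rep(120, 4)),
                                     "AAAA", "A", 1L)
  pepC <- epithread:::assemble_chain(build_backbone(rep(-120, 3), rep(120, 3)),
                                     "SCS", "C", 1L)
  pepA <- epithread:::orient_along_x(pepA)
  pepC <- epithread:::orient_along_x(pepC)
  pepA <- epithread:::shift_until_clear(pepA, pepC, c(0, 1, 0), 3.3)
  atoms <- rbind(pepA, pepC)
  atoms$serial <- seq_len(nrow(atoms))
  trim_to_groove(structure_model(atoms, "tiny"), "A", "C")
})

# A one-variant VCF in the package dialect, written to a temp file.
write_demo_vcf <- function(path, af = 0.45, r1 = 6L, r2 = 7L,
                           rna_alt = 15L, gexp = 12.5) {
  rec <- make_protein_with_mutation(11)$variant
  rec$allele_fraction <- af
  rec$alt_read1_count <- r1
  rec$alt_read2_count <- r2
  rec$rna_alt_count <- rna_alt
  rec$gene_expression <- gexp
  write_variants(rec, path)
  rec
}
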