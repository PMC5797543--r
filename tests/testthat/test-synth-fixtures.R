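# Generators: reproducibility, planted-truth bookkeeping, micro-groove
# geometry.

test_that("variant sets honour their planted fractions exactly", {
  vs <- make_variant_set(1, 100, oxog_fraction = 0.2,
                         low_af_fraction = 0.1, unexpressed_fraction = 0.1)
  expect_equal(nrow(vs$variants), 100)
  expect_equal(sum(vs$truth$label == "oxog-artifact"), 20)
  expect_equal(sum(vs$truth$label == "low-af-no-rna"), 10)
  expect_equal(sum(vs$truth$label == "unexpressed-gene"), 10)
  # artifact rows carry the OxoG substitution signature and one-mate support
  art <- vs$variants[vs$truth$label == "oxog-artifact", ]
  expect_true(all(paste0(art$ref_base, ">", art$alt_base) %in%
                    c("C>A", "G>T")))
  expect_true(all(xor(art$alt_read1_count == 0, art$alt_read2_count == 0)))
  expect_error(make_variant_set(1, 10, 0.5, 0.4, 0.3), "sum")
})

test_that("all-clean variant sets pass the filter chain untouched", {
  vs <- make_variant_set(2, 50, 0, 0, 0)
  out <- run_filter_chain(vs$variants)
  expect_equal(nrow(out$kept), 50)
  expect_true(all(out$audit$stage == "passed"))
})

test_that("generators are pure functions of their seeds", {
  expect_identical(make_variant_set(3, 30), make_variant_set(3, 30))
  expect_false(identical(make_variant_set(3, 30)$variants,
                         make_variant_set(4, 30)$variants))
  expect_identical(make_protein_with_mutation(5), make_protein_with_mutation(5))
  expect_identical(make_allele_family(6, "KQYAMTWL"),
                   make_allele_family(6, "KQYAMTWL"))
  expect_identical(make_micro_groove(1)$atoms, make_micro_groove(1)$atoms)
  # file outputs are byte-identical too
  p1 <- tempfile(); p2 <- tempfile()
  make_variant_set(3, 30, path = p1)
  make_variant_set(3, 30, path = p2)
  expect_identical(readLines(paste0(p1, ".vcf")),
                   readLines(paste0(p2, ".vcf")))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_variant_set(9, 10))
  invisible(make_micro_groove(1))
  expect_identical(.Random.seed, before)
})

test_that("the planted protein mutation is consistent with its annotation", {
  pr <- make_protein_with_mutation(7, 80, 33)
  expect_equal(nchar(pr$ref_seq), 80)
  expect_equal(substr(pr$ref_seq, 33, 33), pr$ref_aa)
  expect_equal(substr(pr$mut_seq, 33, 33), pr$alt_aa)
  expect_false(pr$ref_aa == pr$alt_aa)
  expect_equal(pr$variant$protein_pos, 33L)
  # windows: n calls for an interior mutation
  w <- windows_from_variants(pr$variant, pr$proteome, 9L)
  expect_equal(nrow(w), 9)
})

test_that("allele families hold conserved positions fixed", {
  fam <- make_allele_family(8, "ATLQKCWY", n_alleles = 30,
                            mutation_rate = 0.8,
                            conserved_positions = c(1, 4))
  mat <- do.call(rbind, strsplit(fam$seq, ""))
  expect_equal(unique(mat[, 1]), "A")
  expect_equal(unique(mat[, 4]), "Q")
  expect_gt(length(unique(mat[, 2])), 1)
  expect_error(make_allele_family(8, "ATL", conserved_positions = 9),
               "outside")
})

test_that("the micro-groove is a valid two-chain complex with a 3.5-A groove", {
  mg <- micro_groove()
  expect_equal(sort(model_chains(mg)), c("A", "C"))
  expect_equal(model_sequence(mg, "C"), "AQDIYRASY")
  tc <- groove_complex()
  expect_gt(length(groove_residues(tc, 3.5)), 0)
  # round-trips through the PDB layer
  out <- tempfile(fileext = ".pdb")
  write_pdb(mg, out)
  expect_equal(nrow(read_pdb(out)$atoms), nrow(mg$atoms))
  # no hard steric clash anywhere in the assembled fixture
  expect_false(total_energy(mg$atoms)$clashed)
})

test_that("the occluded pocket blocks every arginine rotamer but not glutamine", {
  tco <- groove_complex_occluded()
  scan <- rotamer_clash_scan(tco, "C", 2, "ARG")
  expect_equal(sort(unique(scan$clashes$rotamer)),
               seq_len(nrow(rotamer_library()$ARG$chis)))
  scan_q <- rotamer_clash_scan(tco, "C", 2, "GLN")
  expect_lt(length(unique(scan_q$clashes$rotamer)),
            nrow(rotamer_library()$GLN$chis))
  expect_false(total_energy(micro_groove_occluded()$atoms)$clashed)
})

test_that("melt-curve files delegate to the Boltzmann simulator", {
  prefix <- tempfile()
  curves <- make_melt_curves(11, params = list(
    list(f_min = 0, f_max = 100, tm = 53.4, k = 2),
    list(f_min = 10, f_max = 90, tm = 59.3, k = 1.5)),
    noise_sd = 1, path = prefix)
  expect_equal(length(curves), 2)
  back <- utils::read.delim(paste0(prefix, ".curve1.tsv"))
  expect_equal(back$fluorescence, curves[[1]]$fluorescence)
  fit <- fit_boltzmann(curves[[2]])
  expect_equal(fit$tm, 59.3, tolerance = 0.3)
})
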