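# Filter chain: consensus, OxoG/read-provenance, expression, and the staged
# driver with planted ground truth.

base_variant <- function(...) {
  v <- list(id = "chr1:100:C>A", ref_base = "C", alt_base = "A",
            mutect = "accepted", muse = "accepted", radia = "accepted",
            sniper = "accepted", strelka = "accepted",
            allele_fraction = 0.4, alt_read1_count = 5L,
            alt_read2_count = 6L, rna_depth = 30L, rna_alt_count = 9L,
            rna_spanning_reads = 2L, gene_expression = 8)
  mods <- list(...)
  v[names(mods)] <- mods
  v
}

test_that("consensus filter tolerates up to two rejections", {
  kept2 <- consensus_filter(base_variant(sniper = "rejected",
                                         strelka = "rejected"))
  expect_true(kept2$kept)
  dropped3 <- consensus_filter(base_variant(radia = "rejected",
                                            sniper = "rejected",
                                            strelka = "rejected"))
  expect_false(dropped3$kept)
  expect_equal(dropped3$stage, "consensus")
  expect_true(consensus_filter(base_variant())$kept)
  # absent callers never count as rejections
  absent <- consensus_filter(base_variant(sniper = "absent",
                                          strelka = "absent",
                                          radia = "rejected",
                                          muse = "rejected"))
  expect_true(absent$kept)
  expect_error(consensus_filter(base_variant(mutect = "absent",
                                             muse = "absent",
                                             radia = "absent",
                                             sniper = "absent",
                                             strelka = "absent")),
               "no caller evidence")
})

test_that("read-provenance clause drops single-mate support, annotated", {
  v <- oxog_filter(base_variant(alt_read2_count = 0L))
  expect_false(v$kept)
  expect_match(v$reason, "read1-only")
  expect_match(v$reason, "OxoG-consistent")  # C>A
  v2 <- oxog_filter(base_variant(alt_read1_count = 0L, ref_base = "A",
                                 alt_base = "G"))
  expect_match(v2$reason, "read2-only")
  expect_false(grepl("OxoG", v2$reason))  # A>G is not the OxoG signature
  expect_error(oxog_filter(base_variant(alt_read1_count = 0L,
                                        alt_read2_count = 0L)),
               "no ALT-supporting reads")
})

test_that("low allele fraction without RNA evidence is dropped, strictly", {
  low <- oxog_filter(base_variant(allele_fraction = 0.05,
                                  rna_alt_count = 0L))
  expect_false(low$kept)
  expect_equal(low$reason, "low-AF-no-RNA")
  # RNA ALT evidence rescues a low-fraction call
  expect_true(oxog_filter(base_variant(allele_fraction = 0.05,
                                       rna_alt_count = 7L))$kept)
  # the comparison is strict: exactly 0.1 passes
  expect_true(oxog_filter(base_variant(allele_fraction = 0.1,
                                       rna_alt_count = 0L))$kept)
  expect_true(oxog_filter(base_variant())$kept)
})

test_that("expression filter applies its three reasons in order", {
  g <- expression_filter(base_variant(gene_expression = 0))
  expect_equal(g$reason, "unexpressed-gene")
  s <- expression_filter(base_variant(rna_spanning_reads = 12L,
                                      rna_depth = 0L, rna_alt_count = 0L))
  expect_equal(s$reason, "splice-variant")
  a <- expression_filter(base_variant(rna_alt_count = 0L))
  expect_equal(a$reason, "unexpressed-ALT")
  expect_true(expression_filter(base_variant())$kept)
})

test_that("the chain reports the first failing stage only", {
  # fails consensus AND oxog; verdict must name consensus
  rec <- make_variant_set(5, 1, 0, 0, 0)$variants
  rec$muse <- "rejected"; rec$radia <- "rejected"; rec$sniper <- "rejected"
  rec$alt_read2_count <- 0L
  out <- run_filter_chain(rec)
  expect_equal(out$audit$stage, "consensus")
  expect_equal(nrow(out$kept), 0)
})

test_that("filter chain matches planted truth exactly on synthetic sets", {
  vs <- make_variant_set(42, 100, oxog_fraction = 0.2,
                         low_af_fraction = 0.1, unexpressed_fraction = 0.1)
  out <- run_filter_chain(vs$variants)
  expect_equal(nrow(out$audit), 100)
  expect_equal(out$audit$stage, vs$truth$expected_stage)
  expect_equal(sum(out$audit$stage == "oxog"), 30)  # 20 artifacts + 10 low-AF
  expect_equal(sum(!out$audit$kept),
               sum(vs$truth$expected_stage != "passed"))
  # all planted-clean records kept
  expect_true(all(out$audit$kept[vs$truth$label == "pass"]))
})

test_that("filters are pure and order-invariant; empty input passes through", {
  vs <- make_variant_set(7, 40)
  a <- run_filter_chain(vs$variants)$audit
  perm <- sample.int(nrow(vs$variants))
  b <- run_filter_chain(vs$variants[perm, ])$audit
  expect_equal(b$kept, a$kept[perm])
  empty <- run_filter_chain(vs$variants[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$audit), 0)
})

test_that("raising the allele-fraction cutoff never enlarges the kept set", {
  vs <- make_variant_set(13, 60)
  kept_ids <- function(cut) {
    cfg <- tool_config(allele_fraction_cutoff = cut)
    run_filter_chain(vs$variants, cfg)$kept$id
  }
  prev <- kept_ids(0.05)
  for (cut in c(0.1, 0.2, 0.4)) {
    cur <- kept_ids(cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})
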