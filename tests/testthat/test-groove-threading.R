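# Template trimming, groove definition, threading, repacking, binding
# energies and the clash scan, exercised on the synthetic micro-groove.

test_that("trimming keeps the groove domain and the peptide, verbatim", {
  tc <- groove_complex()
  expect_equal(sort(model_chains(tc$model)), c("A", "C"))
  expect_true(all(select_atoms(tc$model, chain = "A")$resseq <= 180))
  expect_equal(tc$peptide_seq, "AQDIYRASY")
  # already-trimmed input passes through unchanged
  tc2 <- trim_to_groove(tc$model, "A", "C")
  expect_equal(tc2$model$atoms, tc$model$atoms)
  expect_error(trim_to_groove(micro_groove(), "A", "Z"), "peptide chain")
  # a beta2m/alpha3-like stretch numbered past 180 is removed
  extra <- micro_groove()$atoms
  tail_atoms <- extra[extra$chain == "A" & extra$resseq <= 12, ]
  tail_atoms$resseq <- tail_atoms$resseq + 200L
  tail_atoms$z <- tail_atoms$z - 40
  aug <- structure_model(rbind(extra, tail_atoms), "aug")
  tc3 <- trim_to_groove(aug, "A", "C")
  expect_true(all(select_atoms(tc3$model, chain = "A")$resseq <= 180))
})

test_that("groove residues are the heavy residues within the cutoff", {
  tc <- groove_complex()
  g <- groove_residues(tc, 3.5)
  expect_true(length(g) >= 1)
  # brute-force recomputation
  heavy <- select_atoms(tc$model, chain = "A")
  pep <- select_atoms(tc$model, chain = "C")
  brute <- sort(unique(heavy$resseq[vapply(seq_len(nrow(heavy)), function(i) {
    any(sqrt((pep$x - heavy$x[i])^2 + (pep$y - heavy$y[i])^2 +
               (pep$z - heavy$z[i])^2) <= 3.5)
  }, logical(1))]))
  expect_equal(g, brute)
  expect_equal(length(groove_residues(tc, 0.0)), 0)
  # monotone in the cutoff
  prev <- integer(0)
  for (cut in c(2.5, 3.5, 4.5, 6)) {
    cur <- groove_residues(tc, cut)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("threading the template sequence is the identity", {
  tc <- groove_complex()
  tm <- thread_allele(tc, tc$heavy_seq, groove_set(), allele_name = "self")
  expect_equal(length(tm$mutated), 0)
  expect_equal(tm$model$atoms$x, tc$model$atoms$x)
})

test_that("a single substitution changes exactly one side chain", {
  tc <- groove_complex()
  heavy_res <- model_residues(tc$model, "A")
  g <- groove_set()
  idx <- which(heavy_res$resseq == g[1])
  aseq <- strsplit(tc$heavy_seq, "")[[1]]
  aseq[idx] <- if (aseq[idx] == "F") "W" else "F"
  tm <- thread_allele(tc, paste(aseq, collapse = ""), g)
  expect_equal(tm$mutated, g[1])
  old <- tc$model$atoms
  new <- tm$model$atoms
  same <- new[!(new$chain == "A" & new$resseq == g[1]), ]
  ref <- old[!(old$chain == "A" & old$resseq == g[1]), ]
  expect_equal(same$x, ref$x)
  expect_equal(unique(new$resname[new$chain == "A" & new$resseq == g[1]]),
               aa1to3(aseq[idx]))
})

test_that("polyAla threading replaces every groove residue with alanine", {
  tc <- groove_complex()
  g <- groove_set()
  pa <- polyala_sequence(tc, g)
  tm <- thread_allele(tc, pa, g, allele_name = "polyAla")
  res <- model_residues(tm$model, "A")
  expect_true(all(res$aa[res$resseq %in% g] == "A"))
  expect_equal(tm$groove_seq, paste(rep("A", length(g)), collapse = ""))
})

test_that("alleles with a groove-region gap are rejected with a reason", {
  tc <- groove_complex()
  g <- groove_set()
  heavy_res <- model_residues(tc$model, "A")
  aseq <- strsplit(tc$heavy_seq, "")[[1]]
  dropped <- paste(aseq[-which(heavy_res$resseq == g[1])], collapse = "")
  expect_error(thread_allele(tc, dropped, g), class = "thread_rejection")
  sr <- screen_allele(tc, dropped, n_models = 2, top_k = 1, seed = 1,
                      allele_name = "gapped", groove = g)
  expect_equal(sr$status, "rejected")
  expect_true(is.na(sr$mean_dE))
})

test_that("repack is seed-deterministic and never worsens the objective", {
  tc <- groove_complex()
  tm <- thread_allele(tc, tc$heavy_seq, groove_set())
  r1 <- repack(tm, seed = 42)
  r2 <- repack(tm, seed = 42)
  expect_identical(r1$model$atoms, r2$model$atoms)
  expect_lte(r1$pack_final, r1$pack_initial)
  # different seeds may converge to the same optimum, but the final
  # objective can never differ upward from the exhaustive quench floor
  r3 <- repack(tm, seed = 43)
  expect_equal(r3$pack_final, r1$pack_final, tolerance = 1e-6)
  # repacking an already optimal state leaves the energy unchanged
  r4 <- repack(r1, seed = 99)
  expect_equal(r4$pack_final, r1$pack_final, tolerance = 1e-6)
})

test_that("annealing finds the exhaustive rotamer optimum on a tiny system", {
  tc <- tiny_complex()
  g <- groove_residues(tc)
  tm <- thread_allele(tc, tc$heavy_seq, g)
  r <- repack(tm, seed = 3)
  # independent oracle: enumerate every rotamer combination of the three
  # chi-bearing peptide residues through the slow data.frame path
  lib <- rotamer_library()
  combos <- expand.grid(s1 = seq_len(nrow(lib$SER$chis)),
                        c2 = seq_len(nrow(lib$CYS$chis)),
                        s3 = seq_len(nrow(lib$SER$chis)))
  energies <- vapply(seq_len(nrow(combos)), function(i) {
    at <- tm$model$atoms
    at <- epithread:::set_sidechain(at, "C", 1L, "SER",
                                    lib$SER$chis[combos$s1[i], ])
    at <- epithread:::set_sidechain(at, "C", 2L, "CYS",
                                    lib$CYS$chis[combos$c2[i], ])
    at <- epithread:::set_sidechain(at, "C", 3L, "SER",
                                    lib$SER$chis[combos$s3[i], ])
    total_energy(at)$pair
  }, numeric(1))
  expect_equal(r$pack_final, min(energies), tolerance = 1e-6)
})

test_that("a planted resolvable clash is repacked away", {
  tc <- tiny_complex()
  g <- groove_residues(tc)
  tm <- thread_allele(tc, tc$heavy_seq, g)
  # plant the worst rotamer combination, then repack
  lib <- rotamer_library()
  at <- tm$model$atoms
  worst <- NULL; worst_e <- -Inf
  for (k in seq_len(nrow(lib$CYS$chis))) {
    cand <- epithread:::set_sidechain(at, "C", 2L, "CYS", lib$CYS$chis[k, ])
    e <- total_energy(cand)$pair
    if (e > worst_e) { worst_e <- e; worst <- cand }
  }
  tm_bad <- tm
  tm_bad$model <- structure_model(worst, "planted")
  r <- repack(tm_bad, seed = 8)
  expect_lt(r$pack_final, worst_e)
})

test_that("binding energy obeys its decomposition identity and limits", {
  tc <- groove_complex()
  tm <- repack(thread_allele(tc, tc$heavy_seq, groove_set()), seed = 5)
  be <- binding_energy(tm)
  expect_equal(be$dE, be$e_complex - be$e_mhc - be$e_pep)
  expect_equal(sum(be$per_residue), be$dE, tolerance = 1e-8)
  # peptide displaced far from the groove: no interaction
  far <- tm
  at <- far$model$atoms
  at$x[at$chain == "C"] <- at$x[at$chain == "C"] + 100
  far$model <- structure_model(at, "far")
  be_far <- binding_energy(far)
  expect_equal(be_far$dE, 0, tolerance = 1e-10)
})

test_that("a pair at the Lennard-Jones minimum scores the closed form", {
  efn <- energy_function(w_hb = 0, w_coul = 0, w_solv = 0)
  mk <- function(x, chain, resseq) {
    data.frame(serial = 1L, name = "CB", altloc = "", resname = "ALA",
               chain = chain, resseq = resseq, icode = "", x = x, y = 0,
               z = 0, occupancy = 1, bfactor = 0, element = "C",
               stringsAsFactors = FALSE)
  }
  pair <- rbind(mk(0, "A", 1L), mk(3.4, "C", 1L))  # r0 = 1.7 + 1.7
  e <- total_energy(pair, efn)
  expect_equal(e$total, -0.1, tolerance = 1e-12)  # -eps at the minimum
  # general closed-form check off the minimum
  pair2 <- rbind(mk(0, "A", 1L), mk(3.0, "C", 1L))
  x6 <- (3.4 / 3.0)^6
  expect_equal(total_energy(pair2, efn)$total, 0.1 * (x6^2 - 2 * x6),
               tolerance = 1e-12)
})

test_that("screening is reproducible and averages the top-k models", {
  tc <- groove_complex()
  g <- groove_set()
  s1 <- screen_allele(tc, tc$heavy_seq, n_models = 4, top_k = 2, seed = 9,
                      allele_name = "native", groove = g)
  s2 <- screen_allele(tc, tc$heavy_seq, n_models = 4, top_k = 2, seed = 9,
                      allele_name = "native", groove = g)
  expect_identical(s1$per_model, s2$per_model)
  expect_equal(s1$mean_dE, mean(sort(s1$per_model)[1:2]))
  expect_lte(s1$mean_dE, max(sort(s1$per_model)[1:2]))
  # top_k == n_models averages everything
  s3 <- screen_allele(tc, tc$heavy_seq, n_models = 3, top_k = 3, seed = 9,
                      allele_name = "native", groove = g)
  expect_equal(s3$mean_dE, mean(s3$per_model))
})

test_that("per-residue decomposition localizes planted interactions", {
  # synthetic result: interactions only at peptide positions 2 and 9
  tc <- groove_complex()
  tm <- repack(thread_allele(tc, tc$heavy_seq, groove_set()), seed = 5)
  be <- binding_energy(tm)
  fake <- list(decomp = rbind(be$per_residue * 0 + c(0, -2, 0, 0, 0, 0, 0, 0, -1)),
               allele = "x", status = "scored")
  d <- residue_decomposition(fake)
  expect_equal(unname(d[c(2, 9)]), c(-2, -1))
  expect_true(all(d[-c(2, 9)] == 0))
  expect_error(residue_decomposition(list(decomp = NULL)), "unscored")
})

test_that("the clash scan finds occlusion and open sites correctly", {
  tco <- groove_complex_occluded()
  scan_arg <- rotamer_clash_scan(tco, "C", 2, "ARG")
  n_arg <- nrow(rotamer_library()$ARG$chis)
  clashing <- unique(scan_arg$clashes$rotamer)
  expect_equal(sort(clashing), seq_len(n_arg))  # every rotamer clashes
  expect_true(all(scan_arg$strain > 0))
  # the native glutamine still fits
  scan_gln <- rotamer_clash_scan(tco, "C", 2, "GLN")
  n_gln <- nrow(rotamer_library()$GLN$chis)
  expect_lt(length(unique(scan_gln$clashes$rotamer)), n_gln)
  expect_equal(scan_gln$strain[scan_gln$best_rotamer], min(scan_gln$strain))
  # alanine in an open site has no clash at all
  scan_ala <- rotamer_clash_scan(groove_complex(), "C", 5, "ALA")
  expect_equal(nrow(scan_ala$clashes), 0)
})
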