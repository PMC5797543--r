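# Percentile calibration, binder filtering, self ranks, IAR grouping/ranking.

test_that("percentile rank agrees with a brute-force counting oracle", {
  set.seed(1)
  bg <- rnorm(1000)
  oracle <- function(s) 100 * sum(bg > s) / length(bg)
  for (s in c(-3, -0.5, 0, 0.7, 4)) {
    expect_equal(percentile_rank(s, bg), oracle(s))
  }
  scores <- rnorm(50)
  expect_equal(percentile_rank(scores, bg),
               vapply(scores, oracle, numeric(1)))
  # definition checks
  expect_equal(percentile_rank(max(bg) + 1, bg), 0)
  expect_equal(percentile_rank(median(bg), bg), 50)
  bg2 <- seq_len(1000)  # score worse than 95 of 1000
  expect_equal(percentile_rank(905, bg2), 9.5)
  expect_error(percentile_rank(1, numeric(0)), "empty")
})

test_that("the 5% cutoff keeps exactly the printed binders", {
  calls <- data.frame(percentile_rank = c(0.55, 0.85, 2.1, 10.75, 35))
  kept <- filter_binders(calls, 5)
  expect_equal(kept$percentile_rank, c(0.55, 0.85, 2.1))
  # boundary is kept; filtering is idempotent; empty passes through
  expect_equal(filter_binders(data.frame(percentile_rank = 5))$percentile_rank, 5)
  expect_equal(filter_binders(kept, 5), kept)
  expect_equal(nrow(filter_binders(calls[0, , drop = FALSE], 5)), 0)
})

test_that("the PSSM predictor is seeded, calibrated and length-aware", {
  p1 <- pssm_predictor("HLA-X", lengths = 9L, seed = 5,
                       background_n = 20000L)
  p2 <- pssm_predictor("HLA-X", lengths = 9L, seed = 5,
                       background_n = 20000L)
  peps <- vapply(1:20, function(i) {
    paste(sample(epithread:::AA_ONE, 9, replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(predict_rank(p1, peps, "HLA-X"), predict_rank(p2, peps, "HLA-X"))
  r <- predict_rank(p1, peps, "HLA-X")
  expect_true(all(r >= 0 & r <= 100))
  # ranks of random peptides should spread over the scale
  expect_gt(diff(range(r)), 10)
  expect_error(predict_rank(p1, "AQDIYRASYY", "HLA-X"), "length")
  expect_error(predict_rank(p1, "AQDIYRASY", "HLA-Y"), "allele")
})

test_that("external precomputed ranks drive the pipeline via tsv_predictor", {
  tab <- data.frame(peptide = c("AQDIYRASY", "ARDIYRASY"),
                    allele = "HLA-B*15:01", percentile = c(2.1, 35))
  p <- tsv_predictor(tab)
  expect_equal(predict_rank(p, "AQDIYRASY", "HLA-B*15:01"), 2.1)
  call <- list(peptide = "AQDIYRASY", allele = "HLA-B*15:01",
               percentile_rank = 2.1)
  out <- attach_self_rank(call, "ARDIYRASY", p)
  expect_equal(out$self_rank, 35)
  expect_true(out$better_than_self)
  expect_error(attach_self_rank(call, "AQDIYRASY", p), "identical")
  # not-better-than-self is retained with a warning
  tab2 <- data.frame(peptide = c("AAAAAAAAA", "AAAAAAAAC"),
                     allele = "X", percentile = c(3, 4))
  call2 <- list(peptide = "AAAAAAAAA", allele = "X", percentile_rank = 3)
  expect_warning(out2 <- attach_self_rank(call2, "AAAAAAAAC",
                                          tsv_predictor(tab2)),
                 NA)  # 3 < 4: mutant better, no warning
  call3 <- list(peptide = "AAAAAAAAC", allele = "X", percentile_rank = 4)
  expect_warning(out3 <- attach_self_rank(call3, "AAAAAAAAA",
                                          tsv_predictor(tab2)),
                 "does not outrank")
  expect_false(out3$better_than_self)
})

iar_calls <- function() {
  data.frame(
    peptide = c("AQDIYRASY", "AQDIYRASYY", "QDIYRASYY"),
    allele = c("HLA-B*15:01", "HLA-B*15:01", "HLA-A*01:01"),
    n = c(9L, 10L, 9L), start = c(3L, 3L, 4L),
    percentile_rank = c(2.1, 0.85, 4.0),
    mutation_id = "chr2:29436859:G>A", transcripts = "TX1",
    expression = 12, stringsAsFactors = FALSE)
}

test_that("IAR grouping counts 9/10-mer overlaps on the same allele", {
  iars <- group_iars(iar_calls(), overlap_rank_window = 2)
  expect_equal(nrow(iars), 1)
  expect_equal(iars$best_rank, 0.85)
  expect_equal(iars$promiscuity, 2L)
  expect_equal(iars$overlap_count, 1L)  # the 9/10-mer pair at 2.1 vs 0.85
  # 10-mer on allele X with the 9-mer only on allele Y: no overlap
  calls2 <- iar_calls()
  calls2$allele <- c("HLA-A*01:01", "HLA-B*15:01", "HLA-A*01:01")
  expect_equal(group_iars(calls2, 2)$overlap_count, 0L)
  # similar-affinity window is respected
  calls3 <- iar_calls()
  calls3$percentile_rank <- c(0.1, 4.9, 4.0)
  expect_equal(group_iars(calls3, 2)$overlap_count, 0L)
  # two mutations give two IARs
  calls4 <- rbind(iar_calls(), transform(iar_calls(),
                                         mutation_id = "chrX:1:A>T"))
  expect_equal(nrow(group_iars(calls4, 2)), 2)
})

demo_iars <- function() {
  data.frame(mutation_id = c("m1", "m2"), transcripts = "TX",
             n_calls = 3L, best_rank = c(0.5, 3.0), expression = 10,
             promiscuity = 2L, overlap_count = 1L, stringsAsFactors = FALSE)
}

test_that("IAR ranking favours affinity, breaks ties deterministically", {
  r <- rank_iars(demo_iars())
  expect_equal(r$mutation_id, c("m1", "m2"))  # better best_rank first
  single <- rank_iars(demo_iars()[1, ])
  expect_equal(single$rank, 1L)
  tie <- demo_iars(); tie$best_rank <- c(1, 1)
  expect_equal(rank_iars(tie)$mutation_id, c("m1", "m2"))
  expect_error(rank_iars(demo_iars(), weights = c(-1, 0, 0, 0)), "negative")
})

test_that("IAR ranking is invariant to input order and weight rescaling", {
  set.seed(2)
  iars <- data.frame(mutation_id = paste0("m", 1:8), transcripts = "TX",
                     n_calls = 2L, best_rank = runif(8, 0, 5),
                     expression = runif(8, 1, 40),
                     promiscuity = sample(1:4, 8, TRUE),
                     overlap_count = sample(0:3, 8, TRUE),
                     stringsAsFactors = FALSE)
  a <- rank_iars(iars)
  b <- rank_iars(iars[sample.int(8), ])
  expect_equal(b$mutation_id, a$mutation_id)
  c <- rank_iars(iars, weights = 3 * c(0.4, 0.3, 0.2, 0.1))
  expect_equal(c$mutation_id, a$mutation_id)
})

test_that("rank_neoepitopes runs windows through scoring to ranked IARs", {
  pr <- make_protein_with_mutation(21, 100, 50)
  w <- windows_from_variants(pr$variant, pr$proteome, c(9L, 10L))
  pred <- pssm_predictor(c("HLA-A", "HLA-B"), lengths = c(9L, 10L),
                         seed = 11, background_n = 20000L)
  res <- rank_neoepitopes(w, c("HLA-A", "HLA-B"), pred,
                          tool_config(percentile_cutoff = 50))
  expect_true(nrow(res$calls) > 0)
  expect_true(all(res$calls$percentile_rank <= 50))
  expect_true(all(c("self_rank", "better_than_self") %in% names(res$calls)))
  expect_equal(nrow(res$iars), 1)
  expect_equal(res$iars$rank, 1L)
})
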