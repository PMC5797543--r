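# Seeded generators for every input class the toolkit consumes: variant sets
# with planted artifacts, proteins with point mutations, allele families with
# controlled groove conservation, an idealized micro-groove peptide/MHC-like
# complex (optionally with an occluded B-pocket), and noisy melt curves.
# Every generator is a pure function of its arguments; identical calls give
# byte-identical outputs.

#' Synthetic variant set with planted filter truth
#'
#' Plants four unambiguous populations: clean passers, read-1/read-2-only
#' artifacts (OxoG-consistent substitutions, ALT support confined to one
#' mate), low-allele-fraction variants without RNA ALT evidence, and
#' variants in unexpressed genes. No record fires a clause other than its
#' label's.
#'
#' @param seed integer seed.
#' @param n total records.
#' @param oxog_fraction,low_af_fraction,unexpressed_fraction planted
#'   fractions (must sum to at most 1); counts are `round(n * fraction)`.
#' @param path optional prefix; when given, writes `<path>.vcf` and
#'   `<path>.truth.tsv`.
#' @return list with `variants` (as [read_variants()] layout), `truth`
#'   (data.frame `id`, `label`, `expected_stage`).
#' @export
make_variant_set <- function(seed, n, oxog_fraction = 0.2,
                             low_af_fraction = 0.1,
                             unexpressed_fraction = 0.1, path = NULL) {
  if (oxog_fraction + low_af_fraction + unexpressed_fraction > 1)
    stop("planted fractions sum to more than 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_oxog <- round(n * oxog_fraction)
  n_low <- round(n * low_af_fraction)
  n_unexp <- round(n * unexpressed_fraction)
  n_pass <- n - n_oxog - n_low - n_unexp
  labels <- c(rep("pass", n_pass), rep("oxog-artifact", n_oxog),
              rep("low-af-no-rna", n_low), rep("unexpressed-gene", n_unexp))
  labels <- sample(labels)
  clean_sub <- function(m) {
    pairs <- rbind(c("A", "G"), c("T", "C"), c("G", "A"), c("C", "T"))
    pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  }
  oxog_sub <- function(m) {
    pairs <- rbind(c("C", "A"), c("G", "T"))
    pairs[sample.int(2, m, replace = TRUE), , drop = FALSE]
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    sub <- if (lab == "oxog-artifact") oxog_sub(1) else clean_sub(1)
    r1 <- sample(2:8, 1); r2 <- sample(2:8, 1)
    af <- round(stats::runif(1, 0.2, 0.8), 3)
    rna_depth <- sample(20:60, 1); rna_alt <- sample(5:20, 1)
    rna_span <- sample(0:5, 1); gexp <- round(stats::runif(1, 1, 50), 2)
    if (lab == "oxog-artifact") {
      if (stats::runif(1) < 0.5) r2 <- 0L else r1 <- 0L
      af <- round(stats::runif(1, 0.02, 0.3), 3)
    } else if (lab == "low-af-no-rna") {
      af <- round(stats::runif(1, 0.01, 0.09), 3)
      rna_alt <- 0L
    } else if (lab == "unexpressed-gene") {
      gexp <- 0; rna_depth <- 0L; rna_alt <- 0L; rna_span <- 0L
    }
    pos <- 1000L + 10L * i
    rows[[i]] <- data.frame(
      id = paste0("chr1:", pos, ":", sub[1], ">", sub[2]),
      chrom = "chr1", pos = pos, ref_base = sub[1], alt_base = sub[2],
      mutect = "accepted", muse = "accepted", radia = "accepted",
      sniper = sample(c("accepted", "rejected"), 1),
      strelka = sample(c("accepted", "rejected", "absent"), 1),
      allele_fraction = af, alt_read1_count = r1, alt_read2_count = r2,
      rna_depth = rna_depth, rna_alt_count = rna_alt,
      rna_spanning_reads = rna_span, gene_expression = gexp,
      gene_id = paste0("GENE", (i %% 10) + 1),
      transcript_ids = paste0("TX", sprintf("%03d", (i %% 10) + 1)),
      protein_pos = sample(10:90, 1), ref_aa = "R", alt_aa = "Q",
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  truth <- data.frame(
    id = variants$id, label = labels,
    expected_stage = c(pass = "passed", `oxog-artifact` = "oxog",
                       `low-af-no-rna` = "oxog",
                       `unexpressed-gene` = "expression")[labels],
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_variants(variants, paste0(path, ".vcf"))
    utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(variants = variants, truth = truth)
}

#' Random protein with a planted missense mutation
#'
#' @param seed integer seed.
#' @param length protein length.
#' @param mut_pos 1-based mutated position.
#' @return list with `ref_seq`, `mut_seq`, `ref_aa`, `alt_aa`, `proteome`
#'   (one-record FASTA data.frame, id `TX001`) and `variant` (one-row
#'   variant record carrying the protein annotation).
#' @export
make_protein_with_mutation <- function(seed, length = 100L, mut_pos = 50L) {
  stopifnot(mut_pos >= 1, mut_pos <= length)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- paste(sample(AA_ONE, length, replace = TRUE), collapse = "")
  ref_aa <- substr(ref, mut_pos, mut_pos)
  alt_aa <- sample(setdiff(AA_ONE, ref_aa), 1)
  mut <- ref
  substr(mut, mut_pos, mut_pos) <- alt_aa
  variant <- data.frame(
    id = paste0("chr1:", 1000 + 3 * mut_pos, ":G>A"),
    chrom = "chr1", pos = 1000L + 3L * mut_pos, ref_base = "G",
    alt_base = "A", mutect = "accepted", muse = "accepted",
    radia = "accepted", sniper = "accepted", strelka = "accepted",
    allele_fraction = 0.45, alt_read1_count = 6L, alt_read2_count = 7L,
    rna_depth = 40L, rna_alt_count = 15L, rna_spanning_reads = 2L,
    gene_expression = 12.5, gene_id = "GENE1", transcript_ids = "TX001",
    protein_pos = as.integer(mut_pos), ref_aa = ref_aa, alt_aa = alt_aa,
    stringsAsFactors = FALSE)
  list(ref_seq = ref, mut_seq = mut, ref_aa = ref_aa, alt_aa = alt_aa,
       proteome = data.frame(id = "TX001", description = "synthetic",
                             seq = ref, stringsAsFactors = FALSE),
       variant = variant)
}

#' Allele family with controlled groove conservation
#'
#' Derives `n_alleles` sequences from a reference groove sequence by
#' per-position random substitution at rate `mutation_rate`, holding
#' `conserved_positions` invariant across the family.
#'
#' @param seed integer seed.
#' @param ref_groove_seq reference groove sequence.
#' @param n_alleles family size.
#' @param mutation_rate per-position substitution probability.
#' @param conserved_positions 1-based positions never mutated.
#' @return data.frame with `id`, `seq` (first record is the reference).
#' @export
make_allele_family <- function(seed, ref_groove_seq, n_alleles = 20L,
                               mutation_rate = 0.3,
                               conserved_positions = integer(0)) {
  L <- nchar(ref_groove_seq)
  if (any(conserved_positions < 1 | conserved_positions > L))
    stop("conserved positions outside the groove sequence")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- strsplit(ref_groove_seq, "")[[1]]
  seqs <- character(n_alleles)
  seqs[1] <- ref_groove_seq
  for (a in seq_len(n_alleles)[-1]) {
    s <- ref
    for (p in setdiff(seq_len(L), conserved_positions)) {
      if (stats::runif(1) < mutation_rate)
        s[p] <- sample(setdiff(AA_ONE, s[p]), 1)
    }
    seqs[a] <- paste(s, collapse = "")
  }
  data.frame(id = c("REF", paste0("FAM", sprintf("%03d", seq_len(n_alleles - 1)))),
             seq = seqs, stringsAsFactors = FALSE)
}

# -- micro-groove construction ------------------------------------------------

# Builds a chain residue by residue, choosing for each side chain the library
# rotamer with the least steric overlap against everything placed so far
# (ties broken by prior probability), so ideal-geometry fixtures come out
# clash-free where the sequence allows it.
#' @keywords internal
assemble_chain <- function(bb, aa_seq, chain, resseq_start,
                           rotlib = ROTAMER_LIBRARY) {
  aas <- strsplit(aa_seq, "")[[1]]
  stopifnot(length(aas) == length(bb))
  bbd_all <- lapply(seq_along(bb), function(i) {
    data.frame(name = c("N", "CA", "C", "O"),
               x = c(bb[[i]]$N[1], bb[[i]]$CA[1], bb[[i]]$C[1], bb[[i]]$O[1]),
               y = c(bb[[i]]$N[2], bb[[i]]$CA[2], bb[[i]]$C[2], bb[[i]]$O[2]),
               z = c(bb[[i]]$N[3], bb[[i]]$CA[3], bb[[i]]$C[3], bb[[i]]$O[3]),
               element = c("N", "C", "C", "O"),
               resseq = resseq_start + i - 1L, stringsAsFactors = FALSE)
  })
  placed <- do.call(rbind, bbd_all)  # whole backbone known before side chains
  rows <- list()
  for (i in seq_along(bb)) {
    res3 <- aa1to3(aas[i])
    rs <- resseq_start + i - 1L
    lib <- rotlib[[res3]]
    nrot <- max(1L, nrow(lib$chis))
    best_sc <- NULL; best_key <- c(Inf, -Inf)
    for (k in seq_len(nrot)) {
      chis <- if (ncol(lib$chis) > 0) lib$chis[k, ] else numeric(0)
      sc_k <- build_sidechain(res3, chis, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      strain <- 0
      if (nrow(sc_k) > 0) {
        env <- placed[placed$resseq != rs, , drop = FALSE]
        lim <- outer(vdw_radius(sc_k$element), vdw_radius(env$element),
                     "+") - 0.5
        d <- sqrt(outer(sc_k$x, env$x, "-")^2 +
                    outer(sc_k$y, env$y, "-")^2 +
                    outer(sc_k$z, env$z, "-")^2)
        strain <- sum(pmax(0, lim - d))
      }
      if (strain < best_key[1] - 1e-9 ||
          (abs(strain - best_key[1]) <= 1e-9 && lib$prob[k] > best_key[2])) {
        best_key <- c(strain, lib$prob[k]); best_sc <- sc_k
      }
    }
    resd <- rbind(bbd_all[[i]][, c("name", "x", "y", "z", "element")],
                  if (nrow(best_sc) > 0)
                    best_sc[, c("name", "x", "y", "z", "element")])
    resd$resname <- res3; resd$chain <- chain; resd$resseq <- rs
    if (nrow(best_sc) > 0) {
      sc_add <- best_sc[, c("name", "x", "y", "z", "element")]
      sc_add$resseq <- rs
      placed <- rbind(placed, sc_add)
    }
    rows[[i]] <- resd
  }
  out <- do.call(rbind, rows)
  data.frame(serial = seq_len(nrow(out)), name = out$name, altloc = "",
             resname = out$resname, chain = out$chain, resseq = out$resseq,
             icode = "", x = out$x, y = out$y, z = out$z, occupancy = 1,
             bfactor = 0, element = out$element, stringsAsFactors = FALSE)
}

# Rotate/translate atoms so the chain's CA centroid sits at the origin and
# the first->last CA vector points along +x (z chosen deterministically).
#' @keywords internal
orient_along_x <- function(atoms) {
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  xyz <- atom_xyz(atoms)
  v <- unit3(as.numeric(ca[nrow(ca), c("x", "y", "z")]) -
               as.numeric(ca[1, c("x", "y", "z")]))
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  zax <- unit3(cross3(v, ref))
  yax <- cross3(zax, v)
  R <- rbind(v, yax, zax)
  xyz <- xyz %*% t(R)
  ctr <- colMeans(xyz[atoms$name == "CA", , drop = FALSE])
  xyz <- sweep(xyz, 2, ctr)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' @keywords internal
min_dist <- function(atomsA, atomsB) {
  a <- atom_xyz(atomsA); b <- atom_xyz(atomsB)
  min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
             outer(a[, 3], b[, 3], "-")^2))
}

# Translate mobile atoms along `direction` (unit vector) in 0.25-A steps,
# starting from `from` A, until their minimum distance to `fixed` is at
# least `target`.
#' @keywords internal
shift_until_clear <- function(mobile, fixed, direction, target,
                              from = 2, step = 0.25) {
  offset <- from
  repeat {
    shifted <- mobile
    shifted$x <- mobile$x + offset * direction[1]
    shifted$y <- mobile$y + offset * direction[2]
    shifted$z <- mobile$z + offset * direction[3]
    if (min_dist(shifted, fixed) >= target) return(shifted)
    offset <- offset + step
    if (offset > 100) stop("failed to place fixture element")
  }
}

#' Idealized micro-groove peptide/MHC-like complex
#'
#' A small synthetic complex for fast, download-free structural tests: a
#' 9-mer peptide in ideal extended conformation (phi -120, psi 120) flanked
#' by two short ideal alpha-helices ("walls") and four extended strands
#' ("floor"), all built from ideal bond geometry (~60 residues). With
#' `occlude_pocket_b = TRUE`, additional wall residues are placed along the
#' reach of every bundled arginine rotamer at peptide position 2, so that a
#' long side chain there clashes in every rotamer while the native
#' glutamine fits.
#'
#' @param seed integer seed (reserved; the construction is deterministic).
#' @param occlude_pocket_b add the B-pocket occlusion blockers.
#' @param peptide_seq 9-mer peptide sequence (default AQDIYRASY).
#' @return a `StructureModel` with heavy chain `A` and peptide chain `C`.
#' @export
make_micro_groove <- function(seed = 1L, occlude_pocket_b = FALSE,
                              peptide_seq = "AQDIYRASY") {
  stopifnot(nchar(peptide_seq) == 9)
  pep <- assemble_chain(build_backbone(rep(-120, 9), rep(120, 9)),
                        peptide_seq, "C", 1L)
  pep <- orient_along_x(pep)
  helix_seq <- "AYTLSEKVAGQL"
  hel <- assemble_chain(build_backbone(rep(-57, 12), rep(-47, 12)),
                        helix_seq, "A", 1L)
  hel <- orient_along_x(hel)
  hel1 <- shift_until_clear(hel, pep, c(0, 1, 0), 3.3)
  hel2raw <- hel
  hel2raw$resseq <- hel2raw$resseq + 20L
  hel2 <- shift_until_clear(hel2raw, pep, c(0, -1, 0), 3.3)
  strand_seq <- "AVGTLSMI"
  strand <- assemble_chain(build_backbone(rep(-120, 8), rep(120, 8)),
                           strand_seq, "A", 1L)
  strand <- orient_along_x(strand)
  fixed <- rbind(pep, hel1, hel2)
  floor_parts <- list()
  for (j in 1:4) {
    s <- strand
    s$resseq <- s$resseq + 40L + 10L * (j - 1L)
    s$y <- s$y + c(-7.2, -2.4, 2.4, 7.2)[j]
    placed <- shift_until_clear(s, fixed, c(0, 0, -1), 3.3)
    fixed <- rbind(fixed, placed)
    floor_parts[[j]] <- placed
  }
  heavy <- rbind(hel1, hel2, do.call(rbind, floor_parts))
  if (occlude_pocket_b) {
    heavy <- rbind(heavy,
                   occlusion_blockers(pep, rbind(heavy, pep), resseq0 = 91L))
  }
  atoms <- rbind(heavy, pep)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, sprintf("micro-groove(seed=%d,occluded=%s)",
                                 seed, occlude_pocket_b))
}

# Blocking alanines placed just beyond the guanidinium reach of each
# arginine rotamer built at peptide position 2, skipping rotamers already
# blocked by existing atoms.
#' @keywords internal
occlusion_blockers <- function(pep, env, resseq0 = 91L, tol = 0.5) {
  # judge rotamer reach against what a threaded side chain would see: its
  # own residue and the adjacent covalent backbone are not obstacles
  pchain <- pep$chain[1]
  own <- env$chain == pchain & env$resseq == 2L
  adj <- env$chain == pchain & abs(env$resseq - 2L) == 1 &
    env$name %in% c(BACKBONE_ATOMS, "CB")
  env <- env[!own & !adj, , drop = FALSE]
  bb <- residue_backbone(pep, 2L)
  cb <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, 122.8)
  lib <- ROTAMER_LIBRARY$ARG
  blocks <- list()
  k_used <- 0L
  for (k in seq_len(nrow(lib$chis))) {
    sc <- build_sidechain("ARG", lib$chis[k, ], bb$N, bb$CA, bb$C)
    cz <- as.numeric(sc[sc$name == "CZ", c("x", "y", "z")])
    # skip only rotamers already *deeply* blocked (an atom overlapping the
    # environment by more than 1 Angstrom); gray-zone contacts still get a
    # dedicated blocker so the clash is energetic, not just geometric
    sc_rad <- vdw_radius(sc$element)
    env_rad <- vdw_radius(env$element)
    clash <- FALSE
    for (a in seq_len(nrow(sc))) {
      d <- sqrt((env$x - sc$x[a])^2 + (env$y - sc$y[a])^2 +
                  (env$z - sc$z[a])^2)
      if (any(d < sc_rad[a] + env_rad - 1.0)) { clash <- TRUE; break }
    }
    if (clash) next
    u <- unit3(cz - cb)
    point <- cz + 1.0 * u
    w0 <- if (abs(u[3]) < 0.9) unit3(cross3(u, c(0, 0, 1)))
          else unit3(cross3(u, c(0, 1, 0)))
    v0 <- cross3(u, w0)
    # dummy backbone strictly outward so only carbon sits in the reach zone
    best <- NULL; best_clear <- -Inf
    for (theta in seq(0, 330, by = 30) * pi / 180) {
      w <- cos(theta) * w0 + sin(theta) * v0
      CA <- point + 1.53 * u
      N <- CA + 1.458 * unit3(0.75 * u + 0.66 * w)
      C <- CA + 1.525 * unit3(0.75 * u - 0.66 * w)
      O <- C + 1.231 * u
      cand <- rbind(N, CA, C, O, point)
      dmin <- min(sqrt(outer(cand[, 1], env$x, "-")^2 +
                         outer(cand[, 2], env$y, "-")^2 +
                         outer(cand[, 3], env$z, "-")^2))
      if (dmin > best_clear) { best_clear <- dmin; best <- cand }
    }
    k_used <- k_used + 1L
    rs <- resseq0 + k_used - 1L
    newrows <- data.frame(
      serial = 0L, name = c("N", "CA", "C", "O", "CB"), altloc = "",
      resname = "ALA", chain = "A", resseq = rs, icode = "",
      x = best[, 1], y = best[, 2], z = best[, 3],
      occupancy = 1, bfactor = 0, element = c("N", "C", "C", "O", "C"),
      stringsAsFactors = FALSE)
    blocks[[k_used]] <- newrows
    env <- rbind(env, newrows[, names(env)])
    env_rad <- vdw_radius(env$element)
  }
  if (length(blocks) == 0) return(env[0, , drop = FALSE])
  do.call(rbind, blocks)
}

#' Ideal-geometry peptide model from phi/psi angles
#'
#' Single-chain helper for dihedral-classification tests.
#'
#' @param phi,psi per-residue dihedrals in degrees.
#' @param aa_seq one-letter sequence (defaults to polyalanine).
#' @param chain chain id.
#' @return a `StructureModel`.
#' @export
make_peptide_model <- function(phi, psi, aa_seq = NULL, chain = "C") {
  if (is.null(aa_seq)) aa_seq <- paste(rep("A", length(phi)), collapse = "")
  atoms <- assemble_chain(build_backbone(phi, psi), aa_seq, chain, 1L)
  structure_model(atoms, "ideal-peptide")
}

#' Seeded synthetic melt curves
#'
#' @param seed integer seed; curve i uses substream `seed + i`.
#' @param params list of parameter lists (`f_min`, `f_max`, `tm`, `k`).
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param path optional prefix; writes `<path>.curve<i>.tsv` per curve.
#' @return list of data.frames from [simulate_melt_curve()].
#' @export
make_melt_curves <- function(seed, params, noise_sd = 0, path = NULL) {
  curves <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    simulate_melt_curve(p$f_min, p$f_max, p$tm, p$k, noise_sd = noise_sd,
                        seed = seed + i)
  })
  if (!is.null(path)) {
    for (i in seq_along(curves))
      utils::write.table(curves[[i]], sprintf("%s.curve%d.tsv", path, i),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  curves
}
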