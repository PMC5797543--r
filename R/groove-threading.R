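# Fixed-backbone peptide/MHC threading and binding-energy screening.
# Protocol: trim the template complex to the alpha1/alpha2 groove domain,
# identify groove residues within a distance cutoff of the peptide, thread an
# allele sequence onto the fixed backbone (side-chain replacement at
# mismatched positions), repack groove + peptide side chains by simulated
# annealing over a rotamer library, and report the binding energy
# dE = E(complex) - E(MHC) - E(peptide) with unbound parts scored at frozen
# coordinates. Per allele, n_models independent repack trajectories are run
# and the mean of the top_k lowest dE is reported; a polyAla groove serves as
# the negative control.

GROOVE_DOMAIN_END <- 180L  # last residue of the class-I alpha1/alpha2 domain

#' Trim a p/MHC complex to the groove domain
#'
#' Keeps heavy-chain residues up to 180 (the alpha1/alpha2 peptide-binding
#' domain; beta2-microglobulin and alpha3 removed) plus the untouched peptide
#' chain. An already-trimmed input passes through unchanged.
#'
#' @param structure a `StructureModel`.
#' @param heavy_chain chain id of the MHC heavy chain.
#' @param peptide_chain chain id of the peptide.
#' @return list of class `template_complex` with `model`, `heavy_chain`,
#'   `peptide_chain`, `heavy_seq`, `peptide_seq`.
#' @export
trim_to_groove <- function(structure, heavy_chain, peptide_chain) {
  chains <- model_chains(structure)
  if (!heavy_chain %in% chains) stop("heavy chain not found: ", heavy_chain)
  if (!peptide_chain %in% chains)
    stop("peptide chain not found: ", peptide_chain)
  at <- structure$atoms
  keep <- (at$chain == heavy_chain & at$resseq <= GROOVE_DOMAIN_END) |
    at$chain == peptide_chain
  model <- structure_model(at[keep, , drop = FALSE], structure$source)
  tc <- list(model = model, heavy_chain = heavy_chain,
             peptide_chain = peptide_chain,
             heavy_seq = model_sequence(model, heavy_chain),
             peptide_seq = model_sequence(model, peptide_chain))
  class(tc) <- "template_complex"
  tc
}

#' Groove residues of a template complex
#'
#' Heavy-chain residues with any atom within `cutoff` of any peptide atom.
#'
#' @param tc a `template_complex`.
#' @param cutoff distance cutoff in Angstrom (default 3.5).
#' @return sorted integer vector of heavy-chain residue numbers.
#' @export
groove_residues <- function(tc, cutoff = 3.5) {
  pep <- select_atoms(tc$model, chain = tc$peptide_chain)
  if (nrow(pep) == 0) stop("peptide chain has no atoms")
  heavy <- select_atoms(tc$model, chain = tc$heavy_chain)
  pxyz <- atom_xyz(pep); hxyz <- atom_xyz(heavy)
  mind <- apply(hxyz, 1, function(a) {
    min(sqrt(colSums((t(pxyz) - a)^2)))
  })
  sort(unique(heavy$resseq[mind <= cutoff]))
}

#' @keywords internal
residue_backbone <- function(atoms, resseq) {
  sel <- atoms[atoms$resseq == resseq, , drop = FALSE]
  g <- function(nm) {
    row <- sel[sel$name == nm, , drop = FALSE]
    if (nrow(row) != 1) stop("missing backbone atom ", nm,
                             " in residue ", resseq)
    as.numeric(row[1, c("x", "y", "z")])
  }
  list(N = g("N"), CA = g("CA"), C = g("C"))
}

# Replace the side chain of one residue (chain, resseq) with a freshly built
# one; resname updated, atom order preserved (backbone block then side
# chain), serials renumbered.
#' @keywords internal
set_sidechain <- function(atoms, chain, resseq, new_resname, chis) {
  in_res <- atoms$chain == chain & atoms$resseq == resseq
  if (!any(in_res)) stop("residue not found: ", chain, " ", resseq)
  bb_rows <- which(in_res & atoms$name %in% BACKBONE_ATOMS)
  bb <- residue_backbone(atoms[atoms$chain == chain, , drop = FALSE], resseq)
  sc <- build_sidechain(new_resname, chis, bb$N, bb$CA, bb$C)
  tmpl <- atoms[bb_rows[1], , drop = FALSE]
  before <- atoms[seq_len(max(bb_rows)), , drop = FALSE]
  before <- before[!(seq_len(nrow(before)) %in% setdiff(which(in_res),
                                                        bb_rows)), ,
                   drop = FALSE]
  after <- atoms[-seq_len(max(bb_rows)), , drop = FALSE]
  after <- after[!(after$chain == chain & after$resseq == resseq), ,
                 drop = FALSE]
  scrows <- if (nrow(sc) > 0) {
    data.frame(serial = 0L, name = sc$name, altloc = "",
               resname = toupper(new_resname), chain = chain,
               resseq = resseq, icode = tmpl$icode,
               x = sc$x, y = sc$y, z = sc$z,
               occupancy = 1, bfactor = 0, element = sc$element,
               stringsAsFactors = FALSE)
  } else NULL
  before$resname[before$chain == chain & before$resseq == resseq] <-
    toupper(new_resname)
  out <- rbind(before, scrows, after)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @keywords internal
thread_rejection <- function(reason) {
  stop(structure(class = c("thread_rejection", "error", "condition"),
                 list(message = reason, call = NULL)))
}

#' Thread an HLA allele sequence onto the template backbone
#'
#' The allele sequence is globally aligned to the template heavy-chain
#' sequence (BLOSUM62, gap open/extend 11/1). Positions where the allele
#' differs get the new residue's most probable rotamer built on the fixed
#' template backbone; identical positions keep the template side chain.
#' Alleles whose alignment places a gap at a groove position are rejected
#' (condition class `thread_rejection`).
#'
#' @param tc a `template_complex`.
#' @param allele_seq one-letter allele (heavy-chain) sequence.
#' @param groove groove residue set (default [groove_residues()] at 3.5).
#' @param rotlib rotamer library.
#' @param allele_name label carried on the result.
#' @return list of class `threaded_model`: `model`, `tc`, `mutated`,
#'   `groove`, `allele_name`, `groove_seq` (allele residues at groove
#'   positions, template order).
#' @export
thread_allele <- function(tc, allele_seq, groove = NULL,
                          rotlib = ROTAMER_LIBRARY, allele_name = "allele") {
  if (is.null(groove)) groove <- groove_residues(tc)
  tmpl_seq <- tc$heavy_seq
  heavy_res <- model_residues(tc$model, tc$heavy_chain)
  if (identical(allele_seq, tmpl_seq)) {
    aln_tmpl <- tmpl_seq; aln_allele <- allele_seq
  } else {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(allele_seq),
      subject = Biostrings::AAString(tmpl_seq),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    aln_allele <- as.character(Biostrings::alignedPattern(aln))
    aln_tmpl <- as.character(Biostrings::alignedSubject(aln))
  }
  acol <- strsplit(aln_allele, "")[[1]]
  tcol <- strsplit(aln_tmpl, "")[[1]]
  # map alignment columns to template residue rows
  tmpl_idx <- cumsum(tcol != "-")
  per_res <- rep(NA_character_, nrow(heavy_res))
  for (k in seq_along(tcol)) {
    if (tcol[k] != "-") per_res[tmpl_idx[k]] <- acol[k]
    else {
      # insertion in the allele: attribute to the following template residue
      nxt <- tmpl_idx[k] + 1L
      if (nxt <= nrow(heavy_res) && heavy_res$resseq[nxt] %in% groove)
        thread_rejection(paste0("insertion adjacent to groove residue ",
                                heavy_res$resseq[nxt]))
    }
  }
  gap_at <- which(per_res == "-")
  if (any(heavy_res$resseq[gap_at] %in% groove))
    thread_rejection(paste0("deletion at groove residue ",
                            heavy_res$resseq[intersect(
                              gap_at, which(heavy_res$resseq %in% groove))][1]))
  atoms <- tc$model$atoms
  mutated <- integer(0)
  for (i in seq_len(nrow(heavy_res))) {
    aa <- per_res[i]
    if (is.na(aa) || aa == "-" || aa == heavy_res$aa[i]) next
    res3 <- aa1to3(aa)
    if (is.null(rotlib[[res3]]))
      stop("residue type missing from rotamer library: ", res3)
    atoms <- set_sidechain(atoms, tc$heavy_chain, heavy_res$resseq[i],
                           res3, best_rotamer(res3, rotlib))
    mutated <- c(mutated, heavy_res$resseq[i])
  }
  model <- structure_model(atoms, paste0(tc$model$source, "|", allele_name))
  gseq <- model_residues(model, tc$heavy_chain)
  gseq <- paste(gseq$aa[gseq$resseq %in% groove], collapse = "")
  structure(list(model = model, tc = tc, mutated = mutated, groove = groove,
                 allele_name = allele_name, groove_seq = gseq),
            class = "threaded_model")
}

#' Replace peptide residues on the fixed backbone
#'
#' The peptide analogue of [thread_allele()]: positions where `pep_seq`
#' differs from the template peptide get the new residue's most probable
#' rotamer; used to model self/mutant peptide pairs in the same groove.
#'
#' @param tc a `template_complex`.
#' @param pep_seq replacement peptide sequence (same length as template
#'   peptide).
#' @inheritParams thread_allele
#' @return a `threaded_model`.
#' @export
thread_peptide <- function(tc, pep_seq, groove = NULL,
                           rotlib = ROTAMER_LIBRARY,
                           allele_name = "template") {
  if (nchar(pep_seq) != nchar(tc$peptide_seq))
    stop("peptide length mismatch: template has ", nchar(tc$peptide_seq),
         " residues")
  if (is.null(groove)) groove <- groove_residues(tc)
  pep_res <- model_residues(tc$model, tc$peptide_chain)
  atoms <- tc$model$atoms
  mutated <- integer(0)
  for (i in seq_len(nrow(pep_res))) {
    aa <- substr(pep_seq, i, i)
    if (aa == pep_res$aa[i]) next
    res3 <- aa1to3(aa)
    atoms <- set_sidechain(atoms, tc$peptide_chain, pep_res$resseq[i],
                           res3, best_rotamer(res3, rotlib))
    mutated <- c(mutated, pep_res$resseq[i])
  }
  model <- structure_model(atoms, paste0(tc$model$source, "|pep:", pep_seq))
  gseq <- model_residues(model, tc$heavy_chain)
  gseq <- paste(gseq$aa[gseq$resseq %in% groove], collapse = "")
  structure(list(model = model, tc = tc, mutated = mutated, groove = groove,
                 allele_name = allele_name, groove_seq = gseq),
            class = "threaded_model")
}

#' polyAla groove sequence for a template
#'
#' The template heavy-chain sequence with every groove residue (including
#' Gly and Pro) replaced by Ala; the negative-control "allele".
#'
#' @param tc a `template_complex`.
#' @param groove groove residue set (default 3.5-Angstrom set).
#' @return one-letter sequence.
#' @export
polyala_sequence <- function(tc, groove = NULL) {
  if (is.null(groove)) groove <- groove_residues(tc)
  heavy_res <- model_residues(tc$model, tc$heavy_chain)
  aa <- heavy_res$aa
  aa[heavy_res$resseq %in% groove] <- "A"
  paste(aa, collapse = "")
}

#' @keywords internal
repackable_residues <- function(tm) {
  pep <- model_residues(tm$model, tm$tc$peptide_chain)
  rbind(
    data.frame(chain = rep(tm$tc$heavy_chain, length(tm$groove)),
               resseq = tm$groove, stringsAsFactors = FALSE),
    data.frame(chain = rep(tm$tc$peptide_chain, nrow(pep)),
               resseq = pep$resseq, stringsAsFactors = FALSE))
}

#' Side-chain repack by simulated annealing over rotamers
#'
#' Backbone atoms stay fixed; the side chains of groove and peptide residues
#' are resampled from the rotamer library under Metropolis acceptance with a
#' geometric cooling schedule, followed by a greedy coordinate-descent
#' quench. The objective is the pairwise part of the energy model (the
#' burial term is evaluated in full binding-energy scoring but is excluded
#' from the per-move objective). Deterministic given `seed`; the returned
#' configuration never scores worse than the input.
#'
#' @param tm a `threaded_model`.
#' @param seed integer seed for the trajectory.
#' @param efn an [energy_function()].
#' @param rotlib rotamer library.
#' @param n_sweeps annealing sweeps (default `max(20, 3 * n_repackable)`).
#' @param t_start,t_end annealing temperature schedule (model units).
#' @return a `threaded_model` with repacked coordinates plus `pack_initial`,
#'   `pack_final` (pairwise energies) and `seed`.
#' @export
repack <- function(tm, seed, efn = energy_function(),
                   rotlib = ROTAMER_LIBRARY, n_sweeps = NULL,
                   t_start = 4.0, t_end = 0.05) {
  res <- repackable_residues(tm)
  for (i in seq_len(nrow(res))) {
    rn <- tm$model$atoms$resname[tm$model$atoms$chain == res$chain[i] &
                                   tm$model$atoms$resseq == res$resseq[i]][1]
    if (is.null(rotlib[[rn]]))
      stop("residue type missing from rotamer library: ", rn)
  }
  if (is.null(n_sweeps)) n_sweeps <- max(20L, 3L * nrow(res))
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  ctx <- repack_context(tm$model$atoms, res, efn, rotlib)
  pack0 <- total_energy(tm$model$atoms, efn)$pair
  e_rel <- 0
  best_X <- ctx$X; best_e <- 0
  temps <- t_start * (t_end / t_start)^(seq(0, 1, length.out = n_sweeps))
  nres <- length(ctx$residues)
  for (s in seq_len(n_sweeps)) {
    for (i in sample.int(nres)) {
      r <- ctx$residues[[i]]
      if (r$nrot < 2) next
      k <- sample.int(r$nrot, 1, prob = r$prob)
      mv <- ctx_move(ctx, i, k, efn)
      if (mv$delta <= 0 || stats::runif(1) < exp(-mv$delta / temps[s])) {
        ctx$X[r$sc_rows, ] <- mv$coords
        e_rel <- e_rel + mv$delta
        if (e_rel < best_e) { best_e <- e_rel; best_X <- ctx$X }
      }
    }
  }
  ctx$X <- best_X
  # greedy coordinate-descent quench from the best visited configuration
  for (round in seq_len(10L)) {
    improved <- FALSE
    for (i in seq_len(nres)) {
      r <- ctx$residues[[i]]
      if (r$nrot < 1) next
      best_d <- -1e-9; best_coords <- NULL
      for (k in seq_len(r$nrot)) {
        mv <- ctx_move(ctx, i, k, efn)
        if (mv$delta < best_d) { best_d <- mv$delta; best_coords <- mv$coords }
      }
      if (!is.null(best_coords)) {
        ctx$X[r$sc_rows, ] <- best_coords
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  atoms <- tm$model$atoms
  atoms$x <- ctx$X[, 1]; atoms$y <- ctx$X[, 2]; atoms$z <- ctx$X[, 3]
  pack1 <- total_energy(atoms, efn)$pair
  out <- tm
  out$model <- structure_model(atoms, tm$model$source)
  out$pack_initial <- pack0
  out$pack_final <- min(pack1, pack0)
  out$seed <- seed
  out
}

# Precomputed repack state. Rotamer moves never change atom identities or
# parameters, only side-chain coordinates, so per-atom parameters, row
# indices and every candidate rotamer's coordinates are computed once.
#' @keywords internal
repack_context <- function(atoms, res, efn, rotlib) {
  p <- atom_params(atoms, efn)
  X <- p$xyz
  residues <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    in_res <- which(atoms$chain == res$chain[i] &
                      atoms$resseq == res$resseq[i])
    rn <- atoms$resname[in_res[1]]
    lib <- rotlib[[rn]]
    sc_rows <- in_res[!(atoms$name[in_res] %in% BACKBONE_ATOMS)]
    rot_coords <- NULL
    if (length(sc_rows) > 0 && ncol(lib$chis) > 0) {
      bb <- list(N = X[in_res[atoms$name[in_res] == "N"][1], ],
                 CA = X[in_res[atoms$name[in_res] == "CA"][1], ],
                 C = X[in_res[atoms$name[in_res] == "C"][1], ])
      rot_coords <- lapply(seq_len(nrow(lib$chis)), function(k) {
        sc <- build_sidechain(rn, lib$chis[k, ], bb$N, bb$CA, bb$C)
        m <- match(atoms$name[sc_rows], sc$name)
        if (anyNA(m)) stop("side-chain atom mismatch in residue ",
                           res$chain[i], " ", res$resseq[i])
        as.matrix(sc[m, c("x", "y", "z")])
      })
    }
    residues[[i]] <- list(
      sc_rows = sc_rows,
      env_rows = setdiff(seq_len(nrow(atoms)), in_res),
      nrot = if (is.null(rot_coords)) 0L else length(rot_coords),
      prob = lib$prob, rot_coords = rot_coords)
  }
  list(X = X, par = p, residues = residues)
}

# Energy change of switching residue i to rotamer k given current
# coordinates: pairwise terms of its side chain against everything outside
# the residue (the same pairs the full-energy exclusions admit).
#' @keywords internal
ctx_move <- function(ctx, i, k, efn) {
  r <- ctx$residues[[i]]
  p <- ctx$par
  sc <- r$sc_rows; env <- r$env_rows
  env_X <- ctx$X[env, , drop = FALSE]
  e_old <- cpp_pair_energy(ctx$X[sc, , drop = FALSE], p$rad[sc], p$eps[sc],
                           p$q[sc], p$don[sc], p$acc[sc],
                           env_X, p$rad[env], p$eps[env],
                           p$q[env], p$don[env], p$acc[env],
                           efn$w_lj, efn$w_hb, efn$w_coul,
                           efn$clash_cap)$total
  e_new <- cpp_pair_energy(r$rot_coords[[k]], p$rad[sc], p$eps[sc],
                           p$q[sc], p$don[sc], p$acc[sc],
                           env_X, p$rad[env], p$eps[env],
                           p$q[env], p$don[env], p$acc[env],
                           efn$w_lj, efn$w_hb, efn$w_coul,
                           efn$clash_cap)$total
  list(delta = e_new - e_old, coords = r$rot_coords[[k]])
}

#' Binding energy of a (repacked) model
#'
#' dE = E(complex) - E(MHC alone) - E(peptide alone), all three scored with
#' the full energy model at frozen coordinates (no re-relaxation of the
#' unbound parts). The per-residue map assigns each peptide position its
#' cross-interaction energy with the MHC plus the burial-penalty change of
#' its own atoms; burial changes of MHC atoms are attributed to the nearest
#' peptide residue, so the map sums to dE.
#'
#' @param tm a `threaded_model` (typically after [repack()]).
#' @param efn an [energy_function()].
#' @return list of class `binding_energy_result`: `e_complex`, `e_mhc`,
#'   `e_pep`, `dE`, `per_residue` (named by peptide residue number),
#'   `clashed`.
#' @export
binding_energy <- function(tm, efn = energy_function()) {
  at <- tm$model$atoms
  mhc <- at[at$chain == tm$tc$heavy_chain, , drop = FALSE]
  pep <- at[at$chain == tm$tc$peptide_chain, , drop = FALSE]
  e_c <- total_energy(at, efn)
  e_m <- total_energy(mhc, efn)
  e_p <- total_energy(pep, efn)
  dE <- e_c$total - e_m$total - e_p$total
  clashed <- isTRUE(e_c$clashed)
  if (clashed)
    warning("hard clash: pair energy capped at ", efn$clash_cap)
  # burial-penalty change on each atom between bound and unbound states
  is_mhc <- at$chain == tm$tc$heavy_chain
  solv_c <- e_c$solv_per_atom
  dsolv <- solv_c
  dsolv[is_mhc] <- solv_c[is_mhc] - e_m$solv_per_atom
  dsolv[!is_mhc] <- solv_c[!is_mhc] - e_p$solv_per_atom
  pep_res <- unique(pep$resseq)
  per_res <- stats::setNames(numeric(length(pep_res)), pep_res)
  for (i in seq_along(pep_res)) {
    pr <- pep[pep$resseq == pep_res[i], , drop = FALSE]
    per_res[i] <- cross_energy(pr, mhc, efn)$total +
      sum(dsolv[!is_mhc][pep$resseq == pep_res[i]])
  }
  # nearest peptide residue for each MHC atom
  if (any(is_mhc) && any(dsolv[is_mhc] != 0)) {
    mxyz <- atom_xyz(mhc); pxyz <- atom_xyz(pep)
    for (k in which(dsolv[is_mhc] != 0)) {
      d <- sqrt(colSums((t(pxyz) - mxyz[k, ])^2))
      nearest <- as.character(pep$resseq[which.min(d)])
      per_res[nearest] <- per_res[nearest] + dsolv[is_mhc][k]
    }
  }
  structure(list(e_complex = e_c$total, e_mhc = e_m$total, e_pep = e_p$total,
                 dE = dE, per_residue = per_res, clashed = clashed),
            class = "binding_energy_result")
}

#' Screen one allele: n_models repack trajectories, top-k average
#'
#' Threads the allele, runs `n_models` independent repack trajectories with
#' seeds derived from `seed`, scores each with [binding_energy()] and
#' reports the mean of the `top_k` lowest dE. Threading rejections are
#' returned as unscored results with the reason.
#'
#' @param tc a `template_complex`.
#' @param allele_seq heavy-chain sequence to thread.
#' @param n_models number of trajectories (default 100).
#' @param top_k models averaged (default 10).
#' @param seed master seed for this allele's trajectories.
#' @param allele_name label.
#' @param groove groove residue set (default computed at 3.5 Angstrom).
#' @param efn energy function; `rotlib` rotamer library.
#' @param n_sweeps annealing sweeps forwarded to [repack()].
#' @return list of class `screen_result`: `allele`, `status`, `mean_dE`,
#'   `sd_dE`, `per_model` (all dE values), `decomp` (top-k x peptide-length
#'   matrix of per-residue energies), `groove_seq`.
#' @export
screen_allele <- function(tc, allele_seq, n_models = 100L, top_k = 10L,
                          seed = 1L, allele_name = "allele", groove = NULL,
                          efn = energy_function(), rotlib = ROTAMER_LIBRARY,
                          n_sweeps = NULL) {
  stopifnot(top_k <= n_models)
  if (is.null(groove)) groove <- groove_residues(tc)
  tm <- tryCatch(
    thread_allele(tc, allele_seq, groove, rotlib, allele_name),
    thread_rejection = function(e) e)
  if (inherits(tm, "thread_rejection")) {
    return(structure(list(allele = allele_name, status = "rejected",
                          reason = conditionMessage(tm), mean_dE = NA_real_,
                          sd_dE = NA_real_, per_model = numeric(0),
                          decomp = NULL, groove_seq = NA_character_),
                     class = "screen_result"))
  }
  dEs <- numeric(n_models)
  maps <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    rp <- repack(tm, seed = stream_seed(seed, paste0(allele_name, "#", m)),
                 efn = efn, rotlib = rotlib, n_sweeps = n_sweeps)
    be <- suppressWarnings(binding_energy(rp, efn))
    dEs[m] <- be$dE
    maps[[m]] <- be$per_residue
  }
  top <- order(dEs)[seq_len(top_k)]
  decomp <- do.call(rbind, maps[top])
  structure(list(allele = allele_name, status = "scored", reason = NA,
                 mean_dE = mean(dEs[top]), sd_dE = stats::sd(dEs[top]),
                 per_model = dEs, decomp = decomp,
                 groove_seq = tm$groove_seq),
            class = "screen_result")
}

#' Per-peptide-position energy decomposition of a screen result
#'
#' Mean contribution of each peptide position across the top-k models;
#' anchor positions appear as minima.
#'
#' @param result a `screen_result` (status "scored").
#' @return named numeric vector, one entry per peptide residue.
#' @export
residue_decomposition <- function(result) {
  if (is.null(result$decomp)) stop("unscored screen result")
  colMeans(result$decomp)
}

#' Screen several alleles against one template
#'
#' @param tc a `template_complex`.
#' @param alleles data.frame with `id` and `seq` columns (e.g. from
#'   [read_fasta()]).
#' @param ... forwarded to [screen_allele()].
#' @param seed master seed; each allele derives a substream.
#' @return data.frame: allele, status, mean_dE, sd_dE, plus a `results`
#'   attribute holding the full `screen_result` objects.
#' @export
screen_alleles <- function(tc, alleles, seed = 1L, ...) {
  results <- lapply(seq_len(nrow(alleles)), function(i) {
    screen_allele(tc, alleles$seq[i], seed = stream_seed(seed, alleles$id[i]),
                  allele_name = alleles$id[i], ...)
  })
  out <- data.frame(
    allele = vapply(results, `[[`, character(1), "allele"),
    status = vapply(results, `[[`, character(1), "status"),
    mean_dE = vapply(results, `[[`, numeric(1), "mean_dE"),
    sd_dE = vapply(results, `[[`, numeric(1), "sd_dE"),
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  out
}

#' Exhaustive rotamer clash scan at one position
#'
#' Builds every library rotamer of `new_restype` on the residue's backbone
#' and reports, per rotamer, the environment atoms that overlap it (distance
#' below the sum of van der Waals radii minus `tol`), plus the
#' minimum-strain rotamer (least total overlap).
#'
#' @param tc a `template_complex`.
#' @param chain,position residue to scan.
#' @param new_restype three-letter residue type to build.
#' @param rotlib rotamer library.
#' @param tol overlap tolerance in Angstrom (default 0.5).
#' @return list with `clashes` (data.frame: rotamer, atom_name, env_chain,
#'   env_resseq, env_resname, env_atom, distance, overlap), `strain`
#'   (per-rotamer total overlap) and `best_rotamer` (index).
#' @export
rotamer_clash_scan <- function(tc, chain, position, new_restype,
                               rotlib = ROTAMER_LIBRARY, tol = 0.5) {
  new_restype <- toupper(new_restype)
  lib <- rotlib[[new_restype]]
  if (is.null(lib)) stop("residue type missing from rotamer library: ",
                         new_restype)
  atoms <- tc$model$atoms
  # environment excludes the scanned residue and the covalently adjacent
  # backbone (peptide-bond neighbourhood, within 3 bonds of the side chain)
  own <- atoms$chain == chain & atoms$resseq == position
  adj_bb <- atoms$chain == chain & abs(atoms$resseq - position) == 1 &
    atoms$name %in% c(BACKBONE_ATOMS, "CB")
  env <- atoms[!own & !adj_bb, , drop = FALSE]
  env_rad <- vdw_radius(env$element)
  bb <- residue_backbone(atoms[atoms$chain == chain, , drop = FALSE],
                         position)
  nrot <- max(1L, nrow(lib$chis))
  strain <- numeric(nrot)
  rows <- list()
  for (k in seq_len(nrot)) {
    chis <- if (ncol(lib$chis) > 0) lib$chis[k, ] else numeric(0)
    sc <- build_sidechain(new_restype, chis, bb$N, bb$CA, bb$C)
    if (nrow(sc) == 0) next
    sc_rad <- vdw_radius(sc$element)
    for (a in seq_len(nrow(sc))) {
      p <- as.numeric(sc[a, c("x", "y", "z")])
      d <- sqrt((env$x - p[1])^2 + (env$y - p[2])^2 + (env$z - p[3])^2)
      lim <- sc_rad[a] + env_rad - tol
      hit <- which(d < lim)
      if (length(hit) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          rotamer = k, atom_name = sc$name[a], env_chain = env$chain[hit],
          env_resseq = env$resseq[hit], env_resname = env$resname[hit],
          env_atom = env$name[hit], distance = d[hit],
          overlap = lim[hit] - d[hit], stringsAsFactors = FALSE)
        strain[k] <- strain[k] + sum(lim[hit] - d[hit])
      }
    }
  }
  clashes <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(rotamer = integer(), atom_name = character(),
                  env_chain = character(), env_resseq = integer(),
                  env_resname = character(), env_atom = character(),
                  distance = numeric(), overlap = numeric(),
                  stringsAsFactors = FALSE)
  list(clashes = clashes, strain = strain, best_rotamer = which.min(strain))
}
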