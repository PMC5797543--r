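# Peptide/HLA scoring and ImmunoActive-Region (IAR) analytics. The predictor
# is an interface: any object with a predict_rank() method that maps
# (peptide, allele) to a percentile rank in [0, 100], lower = stronger
# binding. The bundled position-specific scoring matrix (PSSM) predictor is a
# self-contained stand-in that makes the pipeline runnable end-to-end; it is
# NOT a reimplementation of any consensus MHC predictor and its ranks carry
# no immunological meaning beyond their calibration against its own random
# background. Precomputed ranks from an external predictor can be supplied
# through tsv_predictor().

#' Percentile rank of a score against a background
#'
#' Scores are oriented so that higher is better. The percentile rank is 100
#' times the fraction of background scores strictly better (greater) than
#' `score`: 0 means better than the whole background.
#'
#' @param score numeric score(s).
#' @param background_scores non-empty numeric background sample.
#' @return percentile rank(s) in `[0, 100]`.
#' @export
percentile_rank <- function(score, background_scores) {
  if (length(background_scores) == 0) stop("empty background")
  n <- length(background_scores)
  sorted <- sort(background_scores)
  # count of background strictly greater = n - count(<= score)
  100 * (n - findInterval(score, sorted)) / n
}

#' @keywords internal
stream_seed <- function(master_seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1977326743
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}

#' Bundled PSSM binding-score stand-in
#'
#' Builds, per allele and per peptide length, a random log-odds matrix
#' (length x 20) and a seeded background score sample used to calibrate
#' percentile ranks. Deterministic given `seed`.
#'
#' @param alleles character vector of allele names.
#' @param lengths peptide lengths to support (default 9 and 10).
#' @param seed integer seed; each (allele, length) pair derives its own
#'   substream.
#' @param background_n background sample size per matrix (default 100000).
#' @return object of class `pssm_predictor`.
#' @export
pssm_predictor <- function(alleles, lengths = c(9L, 10L), seed = 1L,
                           background_n = 100000L) {
  stopifnot(length(alleles) > 0, background_n > 0)
  models <- list()
  for (al in alleles) {
    for (n in lengths) {
      key <- paste0(al, "/", n)
      old <- .Random.seed_save()
      set.seed(stream_seed(seed, key))
      mat <- matrix(stats::rnorm(n * 20), nrow = n, ncol = 20,
                    dimnames = list(NULL, AA_ONE))
      letters_idx <- matrix(sample.int(20, background_n * n, replace = TRUE),
                            nrow = background_n)
      bg <- rowSums(matrix(mat[cbind(rep(seq_len(n), each = background_n),
                                     as.vector(letters_idx))],
                           nrow = background_n))
      .Random.seed_restore(old)
      models[[key]] <- list(matrix = mat, background = sort(bg))
    }
  }
  structure(list(models = models, alleles = alleles, lengths = lengths,
                 seed = seed, background_n = background_n),
            class = "pssm_predictor")
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @keywords internal
pssm_score <- function(model, peptides) {
  n <- nrow(model$matrix)
  idx <- lapply(strsplit(peptides, ""), function(a) match(a, AA_ONE))
  vapply(idx, function(ii) {
    if (anyNA(ii)) stop("non-standard residue in peptide")
    sum(model$matrix[cbind(seq_len(n), ii)])
  }, numeric(1))
}

#' Predict percentile ranks for peptide/allele pairs
#'
#' @param predictor a predictor object ([pssm_predictor()] or
#'   [tsv_predictor()]).
#' @param peptides character vector of peptides.
#' @param alleles character vector of allele names (recycled against
#'   `peptides`).
#' @return numeric percentile ranks in `[0, 100]`, lower = better.
#' @export
predict_rank <- function(predictor, peptides, alleles) {
  UseMethod("predict_rank")
}

#' @export
predict_rank.pssm_predictor <- function(predictor, peptides, alleles) {
  m <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, m); alleles <- rep_len(alleles, m)
  vapply(seq_len(m), function(i) {
    key <- paste0(alleles[i], "/", nchar(peptides[i]))
    model <- predictor$models[[key]]
    if (is.null(model))
      stop("no model for allele ", alleles[i], " at length ",
           nchar(peptides[i]))
    s <- pssm_score(model, peptides[i])
    percentile_rank(s, model$background)
  }, numeric(1))
}

#' Predictor backed by a precomputed (peptide, allele, percentile) table
#'
#' Lets real external predictor output (e.g. exported consensus percentile
#' ranks) drive the pipeline.
#'
#' @param table data.frame with columns `peptide`, `allele`, `percentile`.
#' @return object of class `tsv_predictor`.
#' @export
tsv_predictor <- function(table) {
  stopifnot(all(c("peptide", "allele", "percentile") %in% names(table)))
  if (any(table$percentile < 0 | table$percentile > 100))
    stop("percentile outside [0, 100]")
  structure(list(table = table), class = "tsv_predictor")
}

#' @export
predict_rank.tsv_predictor <- function(predictor, peptides, alleles) {
  m <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, m); alleles <- rep_len(alleles, m)
  hit <- match(paste(peptides, alleles),
               paste(predictor$table$peptide, predictor$table$allele))
  if (anyNA(hit))
    stop("no precomputed rank for ", peptides[is.na(hit)][1], " / ",
         alleles[is.na(hit)][1])
  predictor$table$percentile[hit]
}

#' Filter binding calls at the percentile cutoff
#'
#' Calls with a percentile rank strictly greater than `cutoff` are dropped as
#' non-binders; a rank exactly at the cutoff is kept.
#'
#' @param calls data.frame with a `percentile_rank` column.
#' @param cutoff percentile cutoff (default 5).
#' @return the kept subset.
#' @export
filter_binders <- function(calls, cutoff = 5.0) {
  calls[calls$percentile_rank <= cutoff, , drop = FALSE]
}

#' Attach the self-peptide rank to a kept call
#'
#' The self counterpart is scored with the identical predictor and
#' background. A neoepitope whose self peptide ranks worse (higher) is
#' flagged `better_than_self`; one that does not is retained with a warning.
#'
#' @param call one-row data.frame (or list) with `peptide`, `allele`,
#'   `percentile_rank`.
#' @param self_seq the unmutated counterpart peptide.
#' @param predictor predictor object.
#' @return the call with `self_rank` and logical `better_than_self` added.
#' @export
attach_self_rank <- function(call, self_seq, predictor) {
  if (identical(call$peptide, self_seq))
    stop("self peptide identical to mutant peptide")
  call$self_rank <- predict_rank(predictor, self_seq, call$allele)
  call$better_than_self <- call$percentile_rank < call$self_rank
  if (!call$better_than_self)
    warning("mutant ", call$peptide, " does not outrank its self peptide ",
            self_seq, " on ", call$allele)
  call
}

#' Group kept binding calls into ImmunoActive Regions
#'
#' One IAR per (mutation, transcript-set) group. Metrics: `best_rank` (the
#' minimum percentile among contained binders), `expression`
#' (transcript-level expression), `promiscuity` (distinct alleles with at
#' least one contained binder) and `overlap_count` (distinct 10-mers
#' overlapping a 9-mer that binds the same allele with similar affinity,
#' i.e. within `overlap_rank_window` percentile points).
#'
#' @param calls kept calls data.frame with columns `peptide`, `allele`, `n`,
#'   `start`, `percentile_rank`, `mutation_id`, `transcripts`, `expression`.
#' @param overlap_rank_window "similar affinity" tolerance in percentile
#'   points (default 2).
#' @return data.frame of IARs, one row per group.
#' @export
group_iars <- function(calls, overlap_rank_window = 2.0) {
  if (nrow(calls) == 0)
    return(data.frame(mutation_id = character(), transcripts = character(),
                      n_calls = integer(), best_rank = numeric(),
                      expression = numeric(), promiscuity = integer(),
                      overlap_count = integer(), stringsAsFactors = FALSE))
  key <- paste(calls$mutation_id, calls$transcripts, sep = "|")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ii) {
    g <- calls[ii, , drop = FALSE]
    ten <- g[g$n == 10, , drop = FALSE]
    nine <- g[g$n == 9, , drop = FALSE]
    overlapping <- vapply(unique(ten$peptide), function(p) {
      tc <- ten[ten$peptide == p, , drop = FALSE]
      any(vapply(seq_len(nrow(tc)), function(j) {
        partners <- nine[nine$allele == tc$allele[j], , drop = FALSE]
        if (nrow(partners) == 0) return(FALSE)
        same_aff <- abs(partners$percentile_rank - tc$percentile_rank[j]) <=
          overlap_rank_window
        overlap <- partners$start <= tc$start[j] + 9 &
          partners$start + 8 >= tc$start[j]
        any(same_aff & overlap)
      }, logical(1)))
    }, logical(1))
    data.frame(mutation_id = g$mutation_id[1], transcripts = g$transcripts[1],
               n_calls = nrow(g), best_rank = min(g$percentile_rank),
               expression = g$expression[1],
               promiscuity = length(unique(g$allele)),
               overlap_count = sum(overlapping), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank ImmunoActive Regions
#'
#' Composite score: `w1 * (1 - best_rank/100) + w2 * expression' +
#' w3 * promiscuity' + w4 * overlap_count'`, where primed quantities are
#' min-max normalized within the sample (a metric constant across IARs
#' contributes 0). Ties are broken deterministically by `mutation_id`.
#'
#' @param iars data.frame from [group_iars()].
#' @param weights 4 non-negative weights (affinity, expression, promiscuity,
#'   overlap), default `c(0.4, 0.3, 0.2, 0.1)`.
#' @return `iars` with `composite` and `rank` columns, ordered best-first.
#' @export
rank_iars <- function(iars, weights = c(0.4, 0.3, 0.2, 0.1)) {
  if (any(weights < 0)) stop("negative weights")
  if (nrow(iars) == 0) {
    iars$composite <- numeric(0); iars$rank <- integer(0)
    return(iars)
  }
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  comp <- weights[1] * (1 - iars$best_rank / 100) +
    weights[2] * minmax(iars$expression) +
    weights[3] * minmax(iars$promiscuity) +
    weights[4] * minmax(iars$overlap_count)
  ord <- order(-comp, iars$mutation_id)
  out <- iars[ord, , drop = FALSE]
  out$composite <- comp[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score windows and rank IARs end-to-end
#'
#' Scores every (window, allele) pair, applies the percentile cutoff,
#' attaches self-peptide ranks, groups into IARs and ranks them.
#'
#' @param windows data.frame from [windows_from_variants()].
#' @param alleles allele names to test.
#' @param predictor predictor object.
#' @param config a [tool_config()].
#' @return list with `calls` (kept, self-annotated calls) and `iars` (ranked).
#' @export
rank_neoepitopes <- function(windows, alleles, predictor,
                             config = tool_config()) {
  windows <- windows[windows$n %in% c(9L, 10L), , drop = FALSE]
  if (nrow(windows) == 0)
    return(list(calls = data.frame(), iars = group_iars(data.frame(
      peptide = character(), allele = character(), n = integer(),
      start = integer(), percentile_rank = numeric(),
      mutation_id = character(), transcripts = character(),
      expression = numeric()))))
  grid <- expand.grid(w = seq_len(nrow(windows)), allele = alleles,
                      stringsAsFactors = FALSE)
  calls <- data.frame(
    peptide = windows$seq[grid$w], allele = grid$allele,
    n = windows$n[grid$w], start = windows$start[grid$w],
    self_seq = windows$self_seq[grid$w],
    mutation_id = windows$mutation_id[grid$w],
    transcripts = windows$transcripts[grid$w],
    expression = windows$expression[grid$w], stringsAsFactors = FALSE)
  calls$percentile_rank <- predict_rank(predictor, calls$peptide, calls$allele)
  kept <- filter_binders(calls, config$percentile_cutoff)
  if (nrow(kept) > 0) {
    kept$self_rank <- predict_rank(predictor, kept$self_seq, kept$allele)
    kept$better_than_self <- kept$percentile_rank < kept$self_rank
  }
  iars <- rank_iars(group_iars(kept, config$overlap_rank_window),
                    config$iar_weights)
  list(calls = kept, iars = iars)
}
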