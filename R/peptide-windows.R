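# Translation of filtered missense SNVs into candidate epitopes: each variant
# yields a mutant context of length 2n-1 centred on the substituted residue
# (truncated at protein termini), from which every n-mer containing the
# mutation is enumerated and paired with its unmutated self counterpart.

#' Mutant 2n-1 context around a missense substitution
#'
#' @param protein_seq reference protein (one-letter string).
#' @param mut_pos 1-based position of the substituted residue.
#' @param alt_aa substituting residue (must differ from the reference).
#' @param n epitope length; the context spans `mut_pos - n + 1` to
#'   `mut_pos + n - 1`, clipped to the protein, so its full length is
#'   `2n - 1` away from the termini.
#' @return list with `context` (mutant string), `start` (1-based protein
#'   coordinate of the first context residue) and `mut_offset` (1-based
#'   position of the mutation within the context).
#' @export
mutant_context <- function(protein_seq, mut_pos, alt_aa, n) {
  L <- nchar(protein_seq)
  if (mut_pos < 1 || mut_pos > L)
    stop("mut_pos ", mut_pos, " out of range 1..", L)
  ref_aa <- substr(protein_seq, mut_pos, mut_pos)
  if (identical(ref_aa, alt_aa))
    stop("not a missense change: reference residue already ", alt_aa)
  if (!alt_aa %in% AA_ONE)
    stop("alt_aa must be one of the 20 standard residues, got ", alt_aa)
  if (alt_aa == "*" || ref_aa == "*")
    stop("stop codons are not windowed")
  start <- max(1L, mut_pos - n + 1L)
  end <- min(L, mut_pos + n - 1L)
  ctx <- substr(protein_seq, start, end)
  off <- mut_pos - start + 1L
  substr(ctx, off, off) <- alt_aa
  list(context = ctx, start = start, mut_offset = off)
}

#' Enumerate candidate n-mers containing the mutation
#'
#' All and only the length-`n` substrings of the context that contain the
#' mutated position, in N-to-C order. An untruncated 2n-1 context yields
#' exactly `n` windows.
#'
#' @param context mutant context string (from [mutant_context()]).
#' @param mut_offset_in_context 1-based mutation position within the context.
#' @param n window length.
#' @param context_start 1-based protein coordinate of the context's first
#'   residue (default 1), used to report window start coordinates.
#' @return data.frame with columns `seq`, `n`, `start` (1-based protein
#'   coordinate) and `mut_offset` (1-based within the window); empty (with a
#'   warning) if the context is shorter than `n`.
#' @export
enumerate_windows <- function(context, mut_offset_in_context, n,
                              context_start = 1L) {
  L <- nchar(context)
  if (L < n) {
    warning("context shorter than window length ", n, "; no windows")
    return(data.frame(seq = character(), n = integer(), start = integer(),
                      mut_offset = integer(), stringsAsFactors = FALSE))
  }
  starts <- seq.int(max(1L, mut_offset_in_context - n + 1L),
                    min(L - n + 1L, mut_offset_in_context))
  data.frame(
    seq = substring(context, starts, starts + n - 1L),
    n = n,
    start = context_start + starts - 1L,
    mut_offset = mut_offset_in_context - starts + 1L,
    stringsAsFactors = FALSE)
}

#' Self counterpart of a mutant window
#'
#' The reference-protein substring at the window's coordinates. It must
#' differ from the mutant window at exactly the mutated offset.
#'
#' @param window one row of [enumerate_windows()] output (list or data.frame
#'   row with `seq`, `n`, `start`, `mut_offset`).
#' @param protein_seq reference protein.
#' @return the self peptide string.
#' @export
self_counterpart <- function(window, protein_seq) {
  s <- window$start
  n <- window$n
  if (s < 1 || s + n - 1 > nchar(protein_seq))
    stop("window coordinates [", s, ", ", s + n - 1,
         "] fall outside the reference protein")
  self <- substr(protein_seq, s, s + n - 1)
  diff <- which(strsplit(self, "")[[1]] != strsplit(window$seq, "")[[1]])
  if (!identical(diff, as.integer(window$mut_offset)))
    stop("window does not match the reference at exactly the mutated offset")
  self
}

#' Collapse identical peptides from multiple transcripts
#'
#' Windows with identical (seq, n) are merged; their transcript origins are
#' unioned and per-origin coordinates retained.
#'
#' @param windows data.frame with at least `seq`, `n`, `transcripts` columns
#'   (comma-separated transcript ids) and optionally `start`.
#' @return deduplicated data.frame; `transcripts` holds the sorted union,
#'   `starts` the per-origin start coordinates (comma-separated).
#' @export
merge_transcripts <- function(windows) {
  if (nrow(windows) == 0) return(windows)
  key <- paste(windows$seq, windows$n)
  out <- windows[!duplicated(key), , drop = FALSE]
  out$transcripts <- vapply(unique(key), function(k) {
    tx <- unlist(strsplit(windows$transcripts[key == k], ",", fixed = TRUE))
    paste(sort(unique(tx)), collapse = ",")
  }, character(1))
  if ("start" %in% names(windows))
    out$starts <- vapply(unique(key), function(k) {
      paste(sort(unique(windows$start[key == k])), collapse = ",")
    }, character(1))
  rownames(out) <- NULL
  out
}

#' Windows for a table of filtered variants
#'
#' Convenience driver: for each missense variant and each configured length,
#' builds the mutant context, enumerates windows, attaches self peptides and
#' merges transcript duplicates per mutation.
#'
#' @param variants filtered variant data.frame (needs `id`, `transcript_ids`,
#'   `gene_id`, `gene_expression`, `protein_pos`, `ref_aa`, `alt_aa`).
#' @param proteome data.frame from [read_fasta()]; record ids must match the
#'   variants' transcript ids.
#' @param lengths integer vector of window lengths.
#' @return data.frame of windows with provenance columns `mutation_id`,
#'   `gene`, `transcripts`, `expression`, `self_seq`.
#' @export
windows_from_variants <- function(variants, proteome, lengths = c(9L, 10L)) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (is.na(v$protein_pos) || is.na(v$ref_aa) || is.na(v$alt_aa) ||
        v$ref_aa == v$alt_aa) next
    txs <- strsplit(v$transcript_ids, ",", fixed = TRUE)[[1]]
    per_tx <- list()
    for (tx in txs) {
      hit <- match(tx, proteome$id)
      if (is.na(hit)) {
        warning("transcript ", tx, " not in proteome; skipped")
        next
      }
      pseq <- proteome$seq[hit]
      if (substr(pseq, v$protein_pos, v$protein_pos) != v$ref_aa) {
        warning("reference residue mismatch for ", v$id, " on ", tx,
                "; skipped")
        next
      }
      for (n in lengths) {
        ctx <- mutant_context(pseq, v$protein_pos, v$alt_aa, n)
        w <- enumerate_windows(ctx$context, ctx$mut_offset, n, ctx$start)
        if (nrow(w) == 0) next
        w$self_seq <- vapply(seq_len(nrow(w)),
                             function(j) self_counterpart(w[j, ], pseq),
                             character(1))
        if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", w$seq))) {
          warning("non-standard residue in context of ", v$id, "; skipped")
          next
        }
        w$transcripts <- tx
        per_tx[[length(per_tx) + 1]] <- w
      }
    }
    if (length(per_tx) == 0) next
    merged <- merge_transcripts(do.call(rbind, per_tx))
    merged$mutation_id <- v$id
    merged$gene <- v$gene_id
    merged$expression <- v$gene_expression
    out[[length(out) + 1]] <- merged
  }
  if (length(out) == 0)
    return(data.frame(seq = character(), n = integer(), start = integer(),
                      mut_offset = integer(), self_seq = character(),
                      transcripts = character(), mutation_id = character(),
                      gene = character(), expression = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
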