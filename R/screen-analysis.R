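# Post-screen analytics: BLOSUM62 identity of groove sequences against a
# reference allele, good-binder selection relative to a threshold allele,
# Kullback-Leibler sequence logos of groove columns, and the tabular
# energy-vs-identity landscape.

#' BLOSUM62 identity of a groove sequence to a reference
#'
#' Sum of BLOSUM62 scores over aligned columns, normalized by the
#' reference's self-score; identity(x, x) is exactly 1.
#'
#' @param groove_seq,ref_groove_seq equal-length groove strings (columns from
#'   the threading alignment, so all alleles share coordinates).
#' @return unitless score, at most 1.
#' @export
identity_to_reference <- function(groove_seq, ref_groove_seq) {
  if (nchar(groove_seq) != nchar(ref_groove_seq))
    stop("groove strings differ in length: ", nchar(groove_seq), " vs ",
         nchar(ref_groove_seq))
  B <- blosum62()
  a <- strsplit(groove_seq, "")[[1]]
  b <- strsplit(ref_groove_seq, "")[[1]]
  sum(B[cbind(a, b)]) / sum(B[cbind(b, b)])
}

#' Select alleles binding better than a threshold allele
#'
#' @param screen_results data.frame from [screen_alleles()] (columns
#'   `allele`, `status`, `mean_dE`).
#' @param threshold_allele allele name whose mean dE is the cut; alleles with
#'   strictly lower (better) mean dE are returned.
#' @return subset of scored rows.
#' @export
select_good_binders <- function(screen_results, threshold_allele) {
  hit <- match(threshold_allele, screen_results$allele)
  if (is.na(hit)) stop("threshold allele not in results: ", threshold_allele)
  thr <- screen_results$mean_dE[hit]
  if (is.na(thr)) stop("threshold allele was not scored: ", threshold_allele)
  scored <- screen_results$status == "scored"
  screen_results[scored & screen_results$mean_dE < thr, , drop = FALSE]
}

#' Kullback-Leibler sequence logo matrix
#'
#' Per alignment column: observed letter frequencies, the column's KL
#' divergence from the background in bits, and letter heights
#' (frequency x KL). A fully conserved column against a uniform background
#' scores log2(20) bits. Zero-frequency letters contribute 0 by the
#' 0*log(0) = 0 convention; an optional pseudocount can be added for very
#' small sets (default 0 so that closed-form column values hold exactly).
#'
#' @param sequences equal-length aligned sequences.
#' @param background named probability vector over the 20 letters (default
#'   uniform). Every observed letter must have positive background mass.
#' @param pseudocount count added per letter per column before
#'   frequency estimation (default 0).
#' @return list of class `logo_matrix`: `freq` (L x 20), `kl` (bits, length
#'   L), `heights` (L x 20).
#' @export
kl_logo <- function(sequences, background = NULL, pseudocount = 0) {
  stopifnot(length(sequences) > 0)
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ONE)
  background <- background[AA_ONE]
  if (anyNA(background)) stop("background must cover the 20 standard letters")
  mat <- do.call(rbind, strsplit(sequences, ""))
  freq <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA_ONE))
  for (j in seq_len(L)) {
    counts <- table(factor(mat[, j], levels = AA_ONE)) + pseudocount
    if (any(counts > pseudocount & background == 0))
      stop("observed letter with zero background mass in column ", j)
    freq[j, ] <- counts / sum(counts)
  }
  kl <- vapply(seq_len(L), function(j) {
    p <- freq[j, ]
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  }, numeric(1))
  heights <- freq * kl
  structure(list(freq = freq, kl = kl, heights = heights),
            class = "logo_matrix")
}

#' Energy-vs-identity landscape table
#'
#' One row per scored allele: mean dE and BLOSUM62 identity of its groove
#' sequence to the reference allele's, sorted by dE; the reference and any
#' polyAla control row are flagged.
#'
#' @param screen_results data.frame from [screen_alleles()] (must carry the
#'   `results` attribute with groove sequences).
#' @param reference allele name identities are computed against (typically
#'   the top binder).
#' @param control_allele optional name of the polyAla control row.
#' @return data.frame: `allele`, `mean_dE`, `sd_dE`, `identity`,
#'   `is_reference`, `is_control`.
#' @export
landscape_table <- function(screen_results, reference,
                            control_allele = "polyAla") {
  results <- attr(screen_results, "results")
  gseq <- vapply(results, `[[`, character(1), "groove_seq")
  names(gseq) <- vapply(results, `[[`, character(1), "allele")
  if (!reference %in% names(gseq) || is.na(gseq[reference]))
    stop("reference allele not scored: ", reference)
  scored <- screen_results[screen_results$status == "scored", , drop = FALSE]
  scored$identity <- vapply(scored$allele, function(a) {
    identity_to_reference(gseq[[a]], gseq[[reference]])
  }, numeric(1))
  scored$is_reference <- scored$allele == reference
  scored$is_control <- scored$allele == control_allele
  scored <- scored[order(scored$mean_dE), , drop = FALSE]
  rownames(scored) <- NULL
  scored
}
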