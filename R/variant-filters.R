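# Post-calling filter chain for somatic SNVs. Three stages, applied in order:
#   consensus  — tolerate up to max_caller_reject rejections among the callers
#   oxog       — drop read-1-only / read-2-only support (the OxoG signature)
#                and low-allele-fraction calls with no RNA ALT evidence
#   expression — drop unexpressed genes, splice-skipped positions, and
#                positions with no ALT evidence in RNA
# A variant's verdict names the first failing stage only.

#' @keywords internal
verdict <- function(kept, stage, reason) {
  list(kept = kept, stage = stage, reason = reason)
}

#' Caller-consensus filter
#'
#' A variant passes if the number of callers that rejected it does not exceed
#' `max_reject`. Callers with no opinion ("absent") are not counted as
#' rejections.
#'
#' @param v one variant record (single row of [read_variants()] output, or a
#'   list with the caller status fields).
#' @param max_reject maximum tolerated rejections (default 2).
#' @return verdict list with `kept`, `stage`, `reason`.
#' @export
consensus_filter <- function(v, max_reject = 2L) {
  statuses <- vapply(tolower(CALLER_KEYS), function(k) as.character(v[[k]]),
                     character(1))
  if (all(statuses == "absent"))
    stop("no caller evidence on variant ", v$id %||% "<unknown>")
  n_rej <- sum(statuses == "rejected")
  if (n_rej > max_reject)
    verdict(FALSE, "consensus", sprintf("rejected-by-%d-callers", n_rej))
  else
    verdict(TRUE, "passed", "consensus-ok")
}

#' OxoG / read-provenance and low-allele-fraction filter
#'
#' Drops variants whose ALT support comes solely from read 1 or solely from
#' read 2 of the pairs (the signature of oxidative guanine damage introduced
#' during library preparation), and variants with allele fraction strictly
#' below `af_cutoff` that have no ALT evidence in RNA. The read-provenance
#' clause applies to all substitution types; whether the substitution is
#' OxoG-consistent (C>A or G>T) is annotated in the reason.
#'
#' @param v one variant record.
#' @param af_cutoff allele-fraction cutoff (default 0.1, strict comparison).
#' @return verdict list with `kept`, `stage`, `reason`.
#' @export
oxog_filter <- function(v, af_cutoff = 0.1) {
  r1 <- v$alt_read1_count; r2 <- v$alt_read2_count
  if (is.na(r1) || is.na(r2) || is.na(v$allele_fraction))
    stop("read counts / allele fraction not populated on ",
         v$id %||% "<unknown>")
  if (r1 == 0 && r2 == 0)
    stop("no ALT-supporting reads on variant ", v$id %||% "<unknown>")
  oxog_sub <- paste0(v$ref_base, ">", v$alt_base) %in% c("C>A", "G>T")
  tag <- if (oxog_sub) " (OxoG-consistent)" else ""
  if (r1 > 0 && r2 == 0)
    return(verdict(FALSE, "oxog", paste0("read1-only", tag)))
  if (r2 > 0 && r1 == 0)
    return(verdict(FALSE, "oxog", paste0("read2-only", tag)))
  rna_alt <- v$rna_alt_count
  if (v$allele_fraction < af_cutoff && (is.na(rna_alt) || rna_alt == 0))
    return(verdict(FALSE, "oxog", "low-AF-no-RNA"))
  verdict(TRUE, "passed", "oxog-ok")
}

#' RNA expression filter
#'
#' Drops variants in unexpressed genes, positions spliced around in the RNA
#' (spanning reads but zero depth), and positions with no ALT evidence in the
#' RNA, in that order of precedence.
#'
#' @param v one variant record.
#' @param expression_threshold gene expression at or below which the gene is
#'   unexpressed (default 0).
#' @return verdict list with `kept`, `stage`, `reason`.
#' @export
expression_filter <- function(v, expression_threshold = 0) {
  gexp <- v$gene_expression
  if (is.na(gexp))
    stop("gene expression not populated on ", v$id %||% "<unknown>")
  if (gexp <= expression_threshold)
    return(verdict(FALSE, "expression", "unexpressed-gene"))
  span <- v$rna_spanning_reads %||% NA
  depth <- v$rna_depth %||% NA
  if (!is.na(span) && !is.na(depth) && span > 0 && depth == 0)
    return(verdict(FALSE, "expression", "splice-variant"))
  alt <- v$rna_alt_count
  if (is.na(alt) || alt == 0)
    return(verdict(FALSE, "expression", "unexpressed-ALT"))
  verdict(TRUE, "passed", "expressed")
}

#' Run the full filter chain
#'
#' Applies consensus, OxoG and expression filters in order. Every input
#' record receives exactly one verdict, naming the first failing stage (or
#' `passed`).
#'
#' @param records variant data.frame from [read_variants()].
#' @param config a [tool_config()].
#' @return list with `kept` (subset of `records` passing all stages) and
#'   `audit` (data.frame: `id`, `stage`, `reason`, `kept`).
#' @export
run_filter_chain <- function(records, config = tool_config()) {
  if (nrow(records) == 0) {
    return(list(kept = records,
                audit = data.frame(id = character(), stage = character(),
                                   reason = character(), kept = logical(),
                                   stringsAsFactors = FALSE)))
  }
  verdicts <- lapply(seq_len(nrow(records)), function(i) {
    v <- as.list(records[i, ])
    for (f in list(function(v) consensus_filter(v, config$max_caller_reject),
                   function(v) oxog_filter(v, config$allele_fraction_cutoff),
                   function(v) expression_filter(v, config$expression_threshold))) {
      vd <- f(v)
      if (!vd$kept) return(vd)
    }
    vd
  })
  audit <- data.frame(
    id = records$id,
    stage = vapply(verdicts, `[[`, character(1), "stage"),
    reason = vapply(verdicts, `[[`, character(1), "reason"),
    kept = vapply(verdicts, `[[`, logical(1), "kept"),
    stringsAsFactors = FALSE)
  list(kept = records[audit$kept, , drop = FALSE], audit = audit)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
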