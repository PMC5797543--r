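# SNV-only VCF dialect. All bespoke evidence travels in INFO:
#   MUTECT/MUSE/RADIA/SNIPER/STRELKA = accepted|rejected   (per-caller status)
#   AF      tumor-DNA allele fraction in [0,1]
#   R1ALT   ALT-supporting reads that are read 1 of their pair
#   R2ALT   ALT-supporting reads that are read 2 of their pair
#   RNADP   RNA-seq depth covering the position
#   RNAALT  RNA-seq reads supporting the ALT allele
#   RNASPAN RNA-seq reads spanning (splicing across) the position
#   GEXP    gene-level expression value (non-negative)
#   GENE    gene id; TRANSCRIPTS comma-separated transcript ids
#   PPOS    1-based position of the substituted residue in the protein
#   PAA     ref/alt amino acids as "R/Q"
# Missing optional keys are recorded as NA (absent), never as zero.

CALLER_KEYS <- c("MUTECT", "MUSE", "RADIA", "SNIPER", "STRELKA")

#' Read an SNV variant table from VCF
#'
#' Biallelic single-nucleotide rows only; indel/MNV rows are skipped with a
#' warning reporting the count. Per-caller status and read/RNA/expression
#' evidence are parsed from the INFO keys documented in the package README.
#'
#' @param path VCF 4.x file.
#' @return data.frame of variant records, one row per SNV, with columns
#'   `id`, `chrom`, `pos`, `ref_base`, `alt_base`, one status column per
#'   caller (`accepted`/`rejected`/`absent`), `allele_fraction`,
#'   `alt_read1_count`, `alt_read2_count`, `rna_depth`, `rna_alt_count`,
#'   `rna_spanning_reads`, `gene_expression`, `gene_id`, `transcript_ids`
#'   (comma-separated), `protein_pos`, `ref_aa`, `alt_aa`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variant_table())
  is_snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snv)
  if (n_skip > 0)
    warning("skipped ", n_skip, " non-SNV row(s) (indel/MNV/multiallelic)")
  fix <- fix[is_snv, , drop = FALSE]
  if (nrow(fix) == 0) return(empty_variant_table())
  recs <- lapply(seq_len(nrow(fix)), function(i) {
    info <- parse_info(fix$INFO[i])
    row_id <- paste0(fix$CHROM[i], ":", fix$POS[i], ":",
                     fix$REF[i], ">", fix$ALT[i])
    statuses <- vapply(CALLER_KEYS, function(k) {
      v <- info[[k]]
      if (is.null(v)) "absent"
      else if (v %in% c("accepted", "rejected")) v
      else stop("invalid caller status '", v, "' for ", k, " at ", row_id)
    }, character(1))
    if (all(statuses == "absent"))
      stop("no caller status on variant ", row_id)
    af <- info_num(info, "AF")
    if (!is.na(af) && (af < 0 || af > 1))
      stop("allele fraction out of [0,1] at ", row_id, ": ", af)
    paa <- info[["PAA"]]
    aa <- if (is.null(paa)) c(NA_character_, NA_character_)
          else strsplit(paa, "/", fixed = TRUE)[[1]]
    data.frame(
      id = row_id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref_base = fix$REF[i], alt_base = fix$ALT[i],
      as.list(stats::setNames(statuses, tolower(CALLER_KEYS))),
      allele_fraction = af,
      alt_read1_count = info_int(info, "R1ALT"),
      alt_read2_count = info_int(info, "R2ALT"),
      rna_depth = info_int(info, "RNADP"),
      rna_alt_count = info_int(info, "RNAALT"),
      rna_spanning_reads = info_int(info, "RNASPAN"),
      gene_expression = info_num(info, "GEXP"),
      gene_id = info_chr(info, "GENE"),
      transcript_ids = info_chr(info, "TRANSCRIPTS"),
      protein_pos = info_int(info, "PPOS"),
      ref_aa = aa[1], alt_aa = if (length(aa) > 1) aa[2] else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  neg <- c("alt_read1_count", "alt_read2_count", "rna_depth",
           "rna_alt_count", "rna_spanning_reads", "gene_expression")
  for (cn in neg)
    if (any(out[[cn]] < 0, na.rm = TRUE)) stop("negative ", cn, " in ", path)
  bad <- out$ref_base == out$alt_base
  if (any(bad)) stop("REF == ALT at ", out$id[bad][1])
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_variant_table <- function() {
  out <- read_variants_template
  out[0, , drop = FALSE]
}

#' @keywords internal
read_variants_template <- data.frame(
  id = "", chrom = "", pos = 0L, ref_base = "", alt_base = "",
  mutect = "", muse = "", radia = "", sniper = "", strelka = "",
  allele_fraction = 0, alt_read1_count = 0L, alt_read2_count = 0L,
  rna_depth = 0L, rna_alt_count = 0L, rna_spanning_reads = 0L,
  gene_expression = 0, gene_id = "", transcript_ids = "",
  protein_pos = 0L, ref_aa = "", alt_aa = "", stringsAsFactors = FALSE)

#' @keywords internal
parse_info <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  stats::setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' @keywords internal
info_num <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) return(NA_real_)
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop("non-numeric INFO value for ", key, ": ", v)
  out
}

#' @keywords internal
info_int <- function(info, key) {
  v <- info_num(info, key)
  if (is.na(v)) NA_integer_ else as.integer(v)
}

#' @keywords internal
info_chr <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) NA_character_ else as.character(v)
}

#' Write variant records back to VCF (package dialect)
#'
#' @param records data.frame as returned by [read_variants()].
#' @param path output VCF path.
#' @export
write_variants <- function(records, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Caller status\">",
            CALLER_KEYS),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumor allele fraction\">",
    "##INFO=<ID=R1ALT,Number=1,Type=Integer,Description=\"ALT reads in read 1\">",
    "##INFO=<ID=R2ALT,Number=1,Type=Integer,Description=\"ALT reads in read 2\">",
    "##INFO=<ID=RNADP,Number=1,Type=Integer,Description=\"RNA depth\">",
    "##INFO=<ID=RNAALT,Number=1,Type=Integer,Description=\"RNA ALT reads\">",
    "##INFO=<ID=RNASPAN,Number=1,Type=Integer,Description=\"RNA spanning reads\">",
    "##INFO=<ID=GEXP,Number=1,Type=Float,Description=\"Gene expression\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=TRANSCRIPTS,Number=1,Type=String,Description=\"Transcript ids\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"Protein position\">",
    "##INFO=<ID=PAA,Number=1,Type=String,Description=\"Ref/alt amino acid\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_kv <- function(key, val) {
    ifelse(is.na(val), NA_character_, paste0(key, "=", val))
  }
  rows <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    status <- vapply(tolower(CALLER_KEYS), function(k) {
      if (r[[k]] == "absent") NA_character_
      else paste0(toupper(k), "=", r[[k]])
    }, character(1))
    info <- c(status,
              fmt_kv("AF", r$allele_fraction),
              fmt_kv("R1ALT", r$alt_read1_count),
              fmt_kv("R2ALT", r$alt_read2_count),
              fmt_kv("RNADP", r$rna_depth),
              fmt_kv("RNAALT", r$rna_alt_count),
              fmt_kv("RNASPAN", r$rna_spanning_reads),
              fmt_kv("GEXP", r$gene_expression),
              fmt_kv("GENE", r$gene_id),
              fmt_kv("TRANSCRIPTS", r$transcript_ids),
              fmt_kv("PPOS", r$protein_pos),
              fmt_kv("PAA", ifelse(is.na(r$ref_aa), NA,
                                   paste0(r$ref_aa, "/", r$alt_aa))))
    paste(r$chrom, r$pos, ".", r$ref_base, r$alt_base, ".", ".",
          paste(info[!is.na(info)], collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
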