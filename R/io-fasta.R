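# FASTA reading/writing via Biostrings, constrained to the 20 standard
# residues. Records keep file order; sequences are uppercased.

#' Read protein FASTA records
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` (first token of the header),
#'   `description` (remainder of the header, possibly empty) and `seq`
#'   (uppercase one-letter string restricted to the 20 standard residues).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (any(!nzchar(seqs)))
    stop("FASTA record with no sequence: ", ids[!nzchar(seqs)][1])
  bad <- grepl(paste0("[^", paste(AA_ONE, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-standard residue letters in record: ", ids[bad][1])
  data.frame(id = ids, description = desc, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein FASTA records
#'
#' @param records data.frame as returned by [read_fasta()] (columns `id`,
#'   optional `description`, `seq`).
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::AAStringSet(toupper(records$seq))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}
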