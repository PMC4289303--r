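# FASTA input/output for expressed V-segment transcripts. Metadata travels
# as key=value pairs on the header line (chain=, productive=, j_label=).

#' Write / read transcripts as annotated FASTA
#'
#' Headers carry `chain=`, `productive=` and `j_label=` key-value pairs,
#' e.g. `>tx_001 chain=TRA productive=true j_label=TRAJ3`.
#'
#' @param transcripts tibble with `transcript_id`, `v_segment` and
#'   optionally `chain`, `productive`, `j_label`.
#' @param path FASTA file path.
#' @return `write_transcript_fasta()` returns `path` invisibly;
#'   `read_transcript_fasta()` returns a transcripts tibble.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  hdr <- vapply(seq_len(nrow(transcripts)), function(i) {
    r <- transcripts[i, ]
    paste0(
      r$transcript_id,
      if (!is.null(r$chain)) paste0(" chain=", r$chain),
      if (!is.null(r$productive)) {
        paste0(" productive=", tolower(as.character(r$productive)))
      },
      if (!is.null(r$j_label) && !is.na(r$j_label)) {
        paste0(" j_label=", r$j_label)
      }
    )
  }, character(1))
  seqs <- Biostrings::DNAStringSet(transcripts$v_segment)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_transcript_fasta
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parse_kv <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  tibble(
    transcript_id = vapply(strsplit(headers, " "), `[[`, character(1), 1L),
    chain = vapply(headers, parse_kv, character(1), key = "chain",
                   USE.NAMES = FALSE),
    v_segment = as.character(seqs),
    j_label = vapply(headers, parse_kv, character(1), key = "j_label",
                     USE.NAMES = FALSE),
    productive = tolower(vapply(headers, parse_kv, character(1),
                                key = "productive",
                                USE.NAMES = FALSE)) %in% c("true", "1", "yes")
  )
}
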