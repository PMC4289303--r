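# Low-level sequence and bookkeeping helpers shared across the pipeline.

DNA_BASES <- c("A", "C", "G", "T")

# transition partner for each base; used for the 2:1 transition-biased
# substitution model of the simulator
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA sequence (frame 0, standard code)
#'
#' Trailing bases that do not fill a codon are dropped. Stop codons are
#' rendered as `*`.
#' @param x a single DNA string
#' @return a single amino-acid string
#' @keywords internal
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X"
  ))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Draw a substituted base under a 2:1 transition bias
#' @keywords internal
substitute_base <- function(base) {
  u <- runif(length(base))
  tv <- lapply(base, function(b) setdiff(DNA_BASES, c(b, TRANSITION[[b]])))
  out <- character(length(base))
  ts <- u < 0.5
  out[ts] <- TRANSITION[base[ts]]
  out[!ts] <- vapply(
    which(!ts),
    function(i) sample(tv[[i]], 1L),
    character(1)
  )
  out
}

#' Mutate exactly `n_mut` distinct positions of a sequence
#' @keywords internal
mutate_n_sites <- function(seq, n_mut, protect = integer(0)) {
  chars <- split_chars(seq)
  free <- setdiff(seq_along(chars), protect)
  n_mut <- min(n_mut, length(free))
  if (n_mut == 0L) return(seq)
  pos <- if (length(free) == 1L) free else sample(free, n_mut)
  chars[pos] <- substitute_base(chars[pos])
  paste(chars, collapse = "")
}

#' Mutate each free position independently at a per-site rate
#' @keywords internal
mutate_rate <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- split_chars(seq)
  free <- setdiff(seq_along(chars), protect)
  hit <- free[runif(length(free)) < rate]
  if (length(hit) == 0L) return(seq)
  chars[hit] <- substitute_base(chars[hit])
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Random open codon sequence (no stop codons)
#' @keywords internal
random_codons <- function(n_codons) {
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0
  ))
  open <- all_codons[!is_stop_codon(all_codons)]
  paste(sample(open, n_codons, replace = TRUE), collapse = "")
}

# Deterministic 32-bit integer derived from a string; used to give each
# subgroup label its own reproducible template stream.
label_seed <- function(label, base_seed = 0L) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

# FNV-1a hash of a serialized object, as 8 hex digits; stamped into report
# headers so outputs are traceable to the configuration that made them.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run a block with a private RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Write a tibble as TSV with a provenance header
#' @keywords internal
write_tsv_report <- function(x, path, header_lines = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in header_lines) writeLines(paste0("# ", line), con)
  x <- as.data.frame(lapply(x, function(col) {
    if (is.list(col)) {
      vapply(col, function(v) paste(unlist(v), collapse = ","), character(1))
    } else {
      col
    }
  }), check.names = FALSE, stringsAsFactors = FALSE)
  suppressWarnings(write.table(
    x, con, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
  ))
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#' @keywords internal
read_tsv_report <- function(path) {
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}
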