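# Locus annotation container and GFF3/FASTA input-output.
#
# Coordinates are 0-based half-open in memory and 1-based inclusive in GFF3
# on disk; the conversion lives here and nowhere else. All part sequences
# are stored in coding orientation (minus-strand parts are extracted as the
# reverse complement of the genomic slice), so downstream code never has to
# think about strand.

GENE_COLUMNS <- c(
  "gene_id", "type", "subgroup", "chain", "contig", "start", "end", "strand",
  "location_class",
  "l_start", "l_end", "v_start", "v_end", "rs_start", "rs_end",
  "d_start", "d_end",
  "l_seq", "intron_seq", "v_seq", "rs_seq", "donor_seq"
)

#' Construct a locus annotation
#'
#' @param genes tibble with one row per gene. Required columns: `gene_id`,
#'   `type` (`"V"`, `"J"`, `"D"` or `"C"`), `subgroup`, `chain`, `contig`,
#'   `start`, `end` (0-based half-open), `strand`, `location_class`, the part
#'   interval columns (`l_start`/`l_end`, `v_start`/`v_end`,
#'   `rs_start`/`rs_end`, `d_start`/`d_end`; `NA` when the part is absent)
#'   and the coding-orientation part sequences (`l_seq`, `intron_seq`,
#'   `v_seq`, `rs_seq`, `donor_seq`).
#' @param contigs named character vector of contig sequences.
#' @param provenance free-text source tag.
#' @return a `locus_annotation` object (list with `genes`, `contigs`,
#'   `provenance`).
#' @export
locus_annotation <- function(genes, contigs, provenance = "trlocus") {
  genes <- as_tibble(genes)
  missing_cols <- setdiff(GENE_COLUMNS, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("locus_annotation(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  genes <- genes[, GENE_COLUMNS]
  ann <- structure(
    list(genes = genes, contigs = contigs, provenance = provenance),
    class = "locus_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  genes <- ann$genes
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                       collapse = ", ")))
  }
  bad_contig <- setdiff(unique(genes$contig), names(ann$contigs))
  if (length(bad_contig) > 0) {
    abort(paste0("genes reference unknown contigs: ",
                 paste(bad_contig, collapse = ", ")))
  }
  lens <- nchar(ann$contigs)[genes$contig]
  out <- genes$start < 0 | genes$end > lens | genes$start >= genes$end
  if (any(out)) {
    abort(paste0("gene coordinates outside contig: ",
                 paste(genes$gene_id[out], collapse = ", ")))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    parts <- part_intervals(g)
    if (nrow(parts) > 1) {
      parts <- parts[order(parts$start), ]
      if (any(parts$end[-nrow(parts)] > parts$start[-1])) {
        abort(paste0("overlapping part intervals in gene ", g$gene_id))
      }
      # along-strand order: V genes leader -> V exon -> RS; J genes
      # 12-RS -> coding -> splice donor (reversed on minus strand)
      ord <- if (g$strand == "-") rev(parts$part) else parts$part
      expected <- if (identical(g$type, "J")) c("rs", "v", "d") else
        c("l", "v", "rs", "d")
      want <- intersect(expected, ord)
      if (!identical(ord, want)) {
        abort(paste0("part intervals out of strand order in gene ", g$gene_id))
      }
    }
  }
  invisible(ann)
}

part_intervals <- function(g) {
  parts <- tibble(
    part = c("l", "v", "rs", "d"),
    start = c(g$l_start, g$v_start, g$rs_start, g$d_start),
    end = c(g$l_end, g$v_end, g$rs_end, g$d_end)
  )
  parts[!is.na(parts$start), ]
}

#' @export
print.locus_annotation <- function(x, ...) {
  cat("<locus_annotation> ", nrow(x$genes), " genes on ",
      length(x$contigs), " contig(s) [", x$provenance, "]\n", sep = "")
  print(count(x$genes, .data$type, .data$subgroup))
  invisible(x)
}

extract_part <- function(contig_seq, start0, end0, strand) {
  s <- substr(contig_seq, start0 + 1L, end0)
  if (strand == "-") revcomp(s) else s
}

# Fill the sequence columns of a genes tibble from contig sequences.
# The intron is the gap between the leader exon and the V exon.
extract_gene_sequences <- function(genes, contigs) {
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cs <- contigs[[g$contig]]
    pull_part <- function(s0, e0) {
      if (is.na(s0)) NA_character_ else extract_part(cs, s0, e0, g$strand)
    }
    genes$l_seq[i] <- pull_part(g$l_start, g$l_end)
    genes$v_seq[i] <- pull_part(g$v_start, g$v_end)
    genes$rs_seq[i] <- pull_part(g$rs_start, g$rs_end)
    genes$donor_seq[i] <- pull_part(g$d_start, g$d_end)
    if (!is.na(g$l_start) && !is.na(g$v_start)) {
      if (g$strand == "-") {
        genes$intron_seq[i] <- pull_part(g$v_end, g$l_start)
      } else {
        genes$intron_seq[i] <- pull_part(g$l_end, g$v_start)
      }
    } else {
      genes$intron_seq[i] <- NA_character_
    }
  }
  genes
}

PART_FEATURES <- c(
  l = "five_prime_leader_exon",
  v = "V_exon",
  j = "J_exon",
  rs = "recombination_signal",
  d = "splice_donor"
)

#' Write an annotation to GFF3 + FASTA
#'
#' Gene parts are encoded as child features of type
#' `five_prime_leader_exon`, `V_exon` (`J_exon` for J genes),
#' `recombination_signal` and `splice_donor`, carrying a `Parent` attribute.
#' Coordinates are converted to the 1-based inclusive GFF3 convention.
#'
#' @param ann a `locus_annotation`.
#' @param gff_path,fasta_path output paths.
#' @return invisibly, a list with the two paths.
#' @export
write_annotation <- function(ann, gff_path, fasta_path) {
  genes <- ann$genes
  rows <- list()
  add_row <- function(id, type, parent, contig, s0, e0, strand, extra = list()) {
    rows[[length(rows) + 1L]] <<- c(
      list(seqid = contig, type = type, start = s0 + 1L, end = e0,
           strand = strand, ID = id, Parent = parent),
      extra
    )
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    add_row(g$gene_id, "gene", NA_character_, g$contig, g$start, g$end,
            g$strand,
            list(gene_type = g$type, subgroup = g$subgroup, chain = g$chain,
                 location_class = g$location_class))
    emit_part <- function(tag, s0, e0) {
      if (!is.na(s0)) {
        feat <- if (tag == "v" && g$type == "J") PART_FEATURES[["j"]] else
          PART_FEATURES[[tag]]
        add_row(paste0(g$gene_id, ":", tag), feat, g$gene_id, g$contig,
                s0, e0, g$strand)
      }
    }
    emit_part("l", g$l_start, g$l_end)
    emit_part("v", g$v_start, g$v_end)
    emit_part("rs", g$rs_start, g$rs_end)
    emit_part("d", g$d_start, g$d_end)
  }
  df <- bind_rows(lapply(rows, as_tibble))
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  for (col in c("gene_type", "subgroup", "chain", "location_class")) {
    if (col %in% names(df)) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  }
  rtracklayer::export.gff3(gr, gff_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ann$contigs), fasta_path
  )
  invisible(list(gff = gff_path, fasta = fasta_path))
}

#' Read an annotation from GFF3 + FASTA
#'
#' Coordinates are converted to the in-memory 0-based half-open convention
#' and all part sequences are extracted in coding orientation (minus-strand
#' parts reverse-complemented).
#'
#' @param gff_path GFF3 file whose features reference sequences in
#'   `fasta_path`; part features must carry a `Parent` attribute.
#' @param fasta_path FASTA of contig sequences.
#' @param provenance free-text source tag stored on the annotation.
#' @return a `locus_annotation`.
#' @export
read_annotation <- function(gff_path, fasta_path, provenance = gff_path) {
  contigs_set <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(contigs_set), names(contigs_set))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  known <- c("gene", unname(PART_FEATURES))
  if (any(!type %in% known)) {
    bad <- which(!type %in% known)[1L]
    abort(paste0("read_annotation(): unknown feature type '", type[bad],
                 "' (feature ", mc$ID[bad] %||% bad, ")"))
  }
  parent <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1L]])
  }, character(1))

  is_gene <- type == "gene"
  gene_ids <- as.character(mc$ID[is_gene])
  idx <- which(is_gene)
  get_attr <- function(col, i) {
    v <- mc[[col]]
    if (is.null(v)) NA_character_ else as.character(v[i])
  }
  genes <- tibble(
    gene_id = gene_ids,
    type = get_attr("gene_type", idx),
    subgroup = get_attr("subgroup", idx),
    chain = get_attr("chain", idx),
    contig = as.character(GenomicRanges::seqnames(gr))[idx],
    start = GenomicRanges::start(gr)[idx] - 1L,
    end = GenomicRanges::end(gr)[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    location_class = get_attr("location_class", idx),
    l_start = NA_integer_, l_end = NA_integer_,
    v_start = NA_integer_, v_end = NA_integer_,
    rs_start = NA_integer_, rs_end = NA_integer_,
    d_start = NA_integer_, d_end = NA_integer_,
    l_seq = NA_character_, intron_seq = NA_character_,
    v_seq = NA_character_, rs_seq = NA_character_,
    donor_seq = NA_character_
  )
  part_idx <- which(!is_gene)
  for (i in part_idx) {
    if (is.na(parent[i])) {
      abort(paste0("read_annotation(): part feature '", mc$ID[i] %||% i,
                   "' has no Parent attribute"))
    }
    row <- match(parent[i], genes$gene_id)
    if (is.na(row)) {
      abort(paste0("read_annotation(): Parent '", parent[i],
                   "' of feature '", mc$ID[i] %||% i, "' is not a gene"))
    }
    tag <- switch(type[i],
      five_prime_leader_exon = "l",
      V_exon = "v", J_exon = "v",
      recombination_signal = "rs",
      splice_donor = "d"
    )
    genes[[paste0(tag, "_start")]][row] <- GenomicRanges::start(gr)[i] - 1L
    genes[[paste0(tag, "_end")]][row] <- GenomicRanges::end(gr)[i]
  }
  bad_len <- genes$end > nchar(contigs)[genes$contig] | genes$start < 0
  if (any(bad_len)) {
    abort(paste0("read_annotation(): coordinates outside contig for gene ",
                 genes$gene_id[which(bad_len)[1L]]))
  }
  genes <- extract_gene_sequences(genes, contigs)
  locus_annotation(genes, contigs, provenance = provenance)
}
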