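# Rule-based functional-competence classification of V and J genes.
#
# A V gene is functionally competent when (i) its intron carries canonical
# GT..AG splice sites, (ii) the conceptually spliced leader+V exon is an
# open reading frame in the subgroup reference frame, (iii) the translation
# carries the conserved Cys/Trp/Cys anchors at IMGT positions 23/41/104,
# (iv) its recombination signal has an intact CAC heptamer, a near-consensus
# nonamer and a 23+-1 bp spacer, and (v) it maps to the locus chromosome or
# an unassigned contig. Any violated rule yields a machine-readable lesion;
# a gene with missing part sequence is "incomplete" (competence not
# assessable), which outranks "pseudogene".

lesion_row <- function(kind, detail = NA_character_, position = NA_integer_) {
  tibble(kind = kind, detail = detail, position = as.integer(position))
}

no_lesions <- function() lesion_row(character(0), character(0), integer(0))

#' Check splice sites of a V gene intron
#'
#' @param intron_seq intron sequence in coding orientation.
#' @return a lesion tibble; empty iff the intron begins `GT` and ends `AG`.
#' @export
#' @examples
#' nrow(check_splice("GTAAGTACAG"))  # 0
check_splice <- function(intron_seq) {
  lesions <- no_lesions()
  if (substr(intron_seq, 1L, 2L) != "GT") {
    lesions <- bind_rows(lesions, lesion_row(
      "splice_donor_mut", substr(intron_seq, 1L, 2L), 1L
    ))
  }
  n <- nchar(intron_seq)
  if (substr(intron_seq, n - 1L, n) != "AG") {
    lesions <- bind_rows(lesions, lesion_row(
      "splice_acceptor_mut", substr(intron_seq, n - 1L, n), n
    ))
  }
  lesions
}

#' Check the open reading frame of a conceptually spliced V gene
#'
#' The leader and V exons are spliced in silico and translated in frame 0
#' from the initiator. A V exon whose length differs from the subgroup
#' reference length by a non-multiple of 3 is called a frameshift (and
#' blocks further ORF interpretation); otherwise internal stop codons are
#' reported with their codon index.
#'
#' @param l_seq,v_seq leader and V exon sequences (coding orientation).
#' @param ref_v_length reference V exon length for the gene's subgroup;
#'   when `NULL` the frame is checked against the spliced length itself.
#' @return list with `lesions` (tibble) and `translation` (character or
#'   `NA` when no frame is defined).
#' @export
check_orf <- function(l_seq, v_seq, ref_v_length = NULL) {
  lesions <- no_lesions()
  shift <- if (!is.null(ref_v_length) && !is.na(ref_v_length)) {
    (nchar(v_seq) - ref_v_length) %% 3L
  } else {
    (nchar(l_seq) + nchar(v_seq)) %% 3L
  }
  if (shift != 0L) {
    return(list(
      lesions = lesion_row("frameshift", paste0("off_frame_", shift, "bp"),
                           nchar(l_seq) + 1L),
      translation = NA_character_
    ))
  }
  pep <- translate_dna(paste0(l_seq, v_seq))
  if (substr(l_seq, 1L, 3L) != "ATG") {
    lesions <- bind_rows(lesions, lesion_row(
      "initiator_mut", substr(l_seq, 1L, 3L), 1L
    ))
  }
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (stop_at > 0) {
    lesions <- bind_rows(lesions, lesion_row(
      "premature_stop", "stop_codon", as.integer(stop_at)
    ))
  }
  list(lesions = lesions, translation = pep)
}

#' Map IMGT V-domain positions onto a translated peptide
#'
#' With a subgroup reference peptide (whose IMGT position `p` sits at
#' peptide index `leader_codons + p`), the candidate translation is globally
#' aligned to the reference and reference indices are carried through the
#' alignment; positions landing on a gap are unalignable (`NA`). Without a
#' reference the identity map `leader_codons + p` is used.
#'
#' @param translation candidate peptide.
#' @param ref_peptide reference peptide or `NULL`.
#' @param leader_codons number of leader codons preceding IMGT position 1.
#' @param positions IMGT positions to map.
#' @return named integer vector (names = IMGT positions; `NA` = unalignable).
#' @export
imgt_position_map <- function(translation, ref_peptide = NULL,
                              leader_codons = LEADER_CODONS,
                              positions = V_ANCHORS) {
  target <- leader_codons + positions
  # without a reference, or when the candidate is colinear with it (equal
  # length, so the global alignment is the identity map), positions map
  # straight through
  if (is.null(ref_peptide) || nchar(translation) == nchar(ref_peptide)) {
    out <- ifelse(target <= nchar(translation), target, NA_integer_)
    return(setNames(as.integer(out), names(positions)))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(translation), Biostrings::AAString(ref_peptide),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  qa <- split_chars(as.character(Biostrings::alignedPattern(aln)))
  ra <- split_chars(as.character(Biostrings::alignedSubject(aln)))
  ref_pos <- cumsum(ra != "-")
  qry_pos <- cumsum(qa != "-")
  out <- vapply(target, function(p) {
    col <- match(p, ref_pos)
    if (is.na(col) || qa[col] == "-") NA_integer_ else as.integer(qry_pos[col])
  }, integer(1))
  setNames(out, names(positions))
}

#' Check the conserved Cys23 / Trp41 / Cys104 anchors
#'
#' @param translation candidate peptide (leader + V domain).
#' @param imgt_map named index vector from [imgt_position_map()].
#' @return lesion tibble with one row per violated or unalignable anchor.
#' @export
check_conserved_residues <- function(translation, imgt_map) {
  expected <- c(C23 = "C", W41 = "W", C104 = "C")
  lesions <- no_lesions()
  for (anchor in names(expected)) {
    idx <- imgt_map[[anchor]]
    kind <- paste0(anchor, "_mut")
    if (is.na(idx) || idx > nchar(translation)) {
      lesions <- bind_rows(lesions, lesion_row(kind, "unalignable", NA))
    } else {
      res <- substr(translation, idx, idx)
      if (res != expected[[anchor]]) {
        lesions <- bind_rows(lesions, lesion_row(kind, res, idx))
      }
    }
  }
  lesions
}

string_identity <- function(a, b) {
  ac <- split_chars(a)
  bc <- split_chars(b)
  n <- min(length(ac), length(bc))
  sum(ac[seq_len(n)] == bc[seq_len(n)])
}

#' Check a recombination signal sequence
#'
#' Valid when the heptamer starts `CAC` and matches `CACAGTG` at >= 5/7
#' positions, the nonamer matches `ACAAAAACC` at >= 6/9 positions, and the
#' spacer length is within 1 bp of the expected 12 or 23.
#'
#' @param rs_seq heptamer-spacer-nonamer sequence (coding orientation).
#' @param expected_spacer 12 or 23.
#' @return lesion tibble.
#' @export
#' @examples
#' nrow(check_rs(paste0("CACAGTG", strrep("A", 23), "ACAAAAACC"), 23))  # 0
check_rs <- function(rs_seq, expected_spacer = 23L) {
  lesions <- no_lesions()
  n <- nchar(rs_seq)
  heptamer <- substr(rs_seq, 1L, 7L)
  nonamer <- substr(rs_seq, n - 8L, n)
  spacer_len <- n - 16L
  if (substr(heptamer, 1L, 3L) != "CAC" ||
      string_identity(heptamer, RS_HEPTAMER) < 5L) {
    lesions <- bind_rows(lesions, lesion_row("RS_heptamer_mut", heptamer, 1L))
  }
  if (string_identity(nonamer, RS_NONAMER) < 6L) {
    lesions <- bind_rows(lesions, lesion_row("RS_nonamer_mut", nonamer,
                                             n - 8L))
  }
  if (abs(spacer_len - expected_spacer) > 1L) {
    lesions <- bind_rows(lesions, lesion_row(
      "RS_spacer_mut", paste0("spacer_", spacer_len, "bp"), 8L
    ))
  }
  lesions
}

classify_one_v <- function(g, ref) {
  lesions <- no_lesions()
  for (part in c("l", "intron", "v", "rs")) {
    seq_col <- c(l = "l_seq", intron = "intron_seq", v = "v_seq",
                 rs = "rs_seq")[[part]]
    if (is.na(g[[seq_col]])) {
      lesions <- bind_rows(lesions, lesion_row("missing_sequence", part, NA))
    }
  }
  translation <- NA_character_
  if (!is.na(g$intron_seq)) {
    lesions <- bind_rows(lesions, check_splice(g$intron_seq))
  }
  if (!is.na(g$l_seq) && !is.na(g$v_seq)) {
    orf <- check_orf(g$l_seq, g$v_seq,
                     ref_v_length = ref$ref_v_length %||% NULL)
    translation <- orf$translation
    lesions <- bind_rows(lesions, orf$lesions)
    if (nrow(orf$lesions) == 0L) {
      map <- imgt_position_map(
        translation,
        ref_peptide = ref$ref_peptide %||% NULL,
        leader_codons = (ref$leader_codons %||% (nchar(g$l_seq) %/% 3L))
      )
      lesions <- bind_rows(lesions,
                           check_conserved_residues(translation, map))
    }
  }
  if (!is.na(g$rs_seq)) {
    lesions <- bind_rows(lesions, check_rs(g$rs_seq, expected_spacer = 23L))
  }
  if (!is.na(g$location_class) &&
      !g$location_class %in% c("locus_chromosome", "unassigned_contig")) {
    lesions <- bind_rows(lesions, lesion_row("unmapped_location",
                                             g$location_class, NA))
  }
  status <- if ("missing_sequence" %in% lesions$kind) {
    "incomplete"
  } else if (nrow(lesions) > 0L) {
    "pseudogene"
  } else {
    "functional"
  }
  list(status = status, lesions = lesions, translation = translation)
}

#' Classify V genes as functional / pseudogene / incomplete
#'
#' @param genes a genes tibble (rows of type `"V"` are classified; see
#'   [locus_annotation()]) or a `locus_annotation`.
#' @param references optional per-subgroup reference tibble with columns
#'   `subgroup`, `ref_peptide`, `ref_v_length`, `leader_codons` (the
#'   simulator provides one in `truth$references`); used for frameshift
#'   detection relative to the reference length and IMGT anchor mapping by
#'   alignment. Subgroups without a reference fall back to positional
#'   mapping.
#' @return tibble of competence calls: `gene_id`, `subgroup`, `status`,
#'   `lesions` (list column of lesion tibbles), `lesion_kinds` (comma-sep
#'   summary), `translation`.
#' @export
#' @examples
#' sim <- simulate_locus(sim_config(rng_seed = 1))
#' calls <- classify_v_genes(sim$annotation, sim$truth$references)
#' table(calls$status)
classify_v_genes <- function(genes, references = NULL) {
  if (inherits(genes, "locus_annotation")) genes <- genes$genes
  genes <- genes[genes$type == "V", ]
  ref_by <- if (!is.null(references)) {
    split(references, references$subgroup)
  } else {
    list()
  }
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ref <- if (!is.na(g$subgroup) && g$subgroup %in% names(ref_by)) {
      as.list(ref_by[[g$subgroup]][1L, ])
    } else {
      list()
    }
    res <- classify_one_v(g, ref)
    out[[i]] <- tibble(
      gene_id = g$gene_id, subgroup = g$subgroup, status = res$status,
      lesions = list(res$lesions),
      lesion_kinds = paste(res$lesions$kind, collapse = ","),
      translation = res$translation
    )
  }
  structure(bind_rows(out), class = c("trl_competence", "tbl_df", "tbl",
                                      "data.frame"))
}

#' Classify J genes
#'
#' A J gene is functional when its coding region translates (frame 0)
#' with the canonical FGxG motif, its 12-spacer recombination signal is
#' valid and its 3' splice donor is `GT`.
#'
#' @param genes genes tibble or `locus_annotation`; rows of type `"J"` are
#'   classified (`v_seq` holds the coding region, `donor_seq` the splice
#'   donor).
#' @return tibble of competence calls as in [classify_v_genes()].
#' @export
classify_j_genes <- function(genes) {
  if (inherits(genes, "locus_annotation")) genes <- genes$genes
  genes <- genes[genes$type == "J", ]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lesions <- no_lesions()
    translation <- NA_character_
    for (part in c("v", "rs", "d")) {
      seq_col <- c(v = "v_seq", rs = "rs_seq", d = "donor_seq")[[part]]
      if (is.na(g[[seq_col]])) {
        lesions <- bind_rows(lesions, lesion_row("missing_sequence", part, NA))
      }
    }
    if (!is.na(g$v_seq)) {
      translation <- translate_dna(g$v_seq)
      if (!grepl("FG.G", translation)) {
        lesions <- bind_rows(lesions,
                             lesion_row("missing_FGxG", translation, NA))
      }
    }
    if (!is.na(g$rs_seq)) {
      lesions <- bind_rows(lesions, check_rs(g$rs_seq, expected_spacer = 12L))
    }
    if (!is.na(g$donor_seq) && g$donor_seq != "GT") {
      lesions <- bind_rows(lesions,
                           lesion_row("splice_donor_mut", g$donor_seq, 1L))
    }
    status <- if ("missing_sequence" %in% lesions$kind) {
      "incomplete"
    } else if (nrow(lesions) > 0L) {
      "pseudogene"
    } else {
      "functional"
    }
    out[[i]] <- tibble(
      gene_id = g$gene_id, subgroup = g$subgroup, status = status,
      lesions = list(lesions),
      lesion_kinds = paste(lesions$kind, collapse = ","),
      translation = translation
    )
  }
  structure(bind_rows(out), class = c("trl_competence", "tbl_df", "tbl",
                                      "data.frame"))
}

#' Summarize competence calls per subgroup
#'
#' Produces the per-subgroup accounting used for repertoire tables: total,
#' functional, pseudogene and incomplete counts plus percent functional
#' (denominator = all genes of the subgroup, incomplete included), with a
#' totals row appended.
#'
#' @param calls tibble with at least `subgroup` and `status` columns (e.g.
#'   from [classify_v_genes()]); genes without a subgroup are reported as
#'   `"unassigned"`.
#' @return a `trl_catalog_summary` tibble (columns `subgroup`, `total`,
#'   `functional`, `pseudogene`, `incomplete`, `pct_functional`).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   subgroup = c("DV1", "DV1", "V2"),
#'   status = c("functional", "pseudogene", "functional")
#' )
#' summarize_catalog(calls)
summarize_catalog <- function(calls) {
  calls <- as_tibble(calls)[, c("subgroup", "status")]
  calls$subgroup[is.na(calls$subgroup)] <- "unassigned"
  bad <- setdiff(unique(calls$status),
                 c("functional", "pseudogene", "incomplete"))
  if (length(bad) > 0) {
    abort(paste0("summarize_catalog(): unknown status: ",
                 paste(bad, collapse = ", ")))
  }
  order_levels <- unique(calls$subgroup)
  per <- calls %>%
    group_by(subgroup = factor(.data$subgroup, levels = order_levels)) %>%
    summarise(
      total = dplyr::n(),
      functional = sum(.data$status == "functional"),
      pseudogene = sum(.data$status == "pseudogene"),
      incomplete = sum(.data$status == "incomplete"),
      .groups = "drop"
    ) %>%
    arrange(.data$subgroup) %>%
    mutate(subgroup = as.character(.data$subgroup))
  totals <- tibble(
    subgroup = "Total",
    total = sum(per$total),
    functional = sum(per$functional),
    pseudogene = sum(per$pseudogene),
    incomplete = sum(per$incomplete)
  )
  out <- bind_rows(per, totals)
  out$pct_functional <- round(100 * out$functional / pmax(out$total, 1L), 1)
  structure(out, class = c("trl_catalog_summary", "tbl_df", "tbl",
                           "data.frame"))
}

#' Expand a per-subgroup count table into per-gene status calls
#'
#' Convenience inverse of [summarize_catalog()] for working from published
#' count tables: each subgroup row with `total`/`functional`/`pseudogene`/
#' `incomplete` counts becomes that many per-gene rows.
#'
#' @param counts tibble with columns `subgroup`, `functional`, `pseudogene`,
#'   `incomplete`.
#' @return tibble with `gene_id`, `subgroup`, `status`.
#' @export
counts_to_calls <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    status <- c(rep("functional", r$functional),
                rep("pseudogene", r$pseudogene),
                rep("incomplete", r$incomplete))
    if (length(status) == 0) return(NULL)
    tibble(
      gene_id = paste0(r$subgroup, "_", seq_along(status)),
      subgroup = r$subgroup,
      status = status
    )
  })
  bind_rows(rows)
}
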