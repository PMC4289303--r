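# Matching of expressed V segments against the genomic catalog and the
# identical / allelic-or-unassembled / novel trichotomy, plus subgroup
# usage frequencies, representation bias and dual-usage detection.
#
# Category convention: "identical" requires 100% identity; 97.0% exactly is
# inclusive to the middle class; below 97.0% an expressed sequence is
# considered the product of a gene absent from the assembly.

match_category <- function(identity_pct, threshold_pct = 97) {
  dplyr::case_when(
    identity_pct >= 100 - 1e-9 ~ "identical",
    identity_pct >= threshold_pct ~ "allelic_or_unassembled",
    TRUE ~ "novel"
  )
}

#' Match expressed V segments to a genomic V-gene catalog
#'
#' Each transcript's V segment is globally aligned to every catalog
#' V-REGION; the best hit is the maximal percent identity (pairwise
#' deletion), with ties broken by genomic order of the catalog.
#'
#' @param transcripts tibble with `transcript_id`, `v_segment` and
#'   optionally `chain`, `productive`, `j_label` (carried through).
#' @param catalog genes tibble or `locus_annotation`; V genes in genomic
#'   order supply the `v_seq` catalog.
#' @param threshold identity fraction separating the novel class
#'   (default 0.97).
#' @return a `trl_matches` tibble: inputs plus `best_hit`, `subgroup`
#'   (of the best hit), `identity` (percent) and `category`.
#' @export
#' @examples
#' sim <- simulate_locus(sim_config(rng_seed = 1))
#' tx <- simulate_transcripts(sim)
#' m <- match_v_segments(tx$transcripts[1:5, ], sim$annotation)
#' m$category
match_v_segments <- function(transcripts, catalog, threshold = 0.97) {
  if (inherits(catalog, "locus_annotation")) catalog <- catalog$genes
  catalog <- catalog[catalog$type == "V" & !is.na(catalog$v_seq), ]
  catalog <- arrange(catalog, .data$contig, .data$start)
  if (nrow(catalog) == 0) abort("match_v_segments(): empty catalog")
  if (any(!nzchar(transcripts$v_segment) |
            is.na(transcripts$v_segment))) {
    abort("match_v_segments(): empty transcript sequence")
  }
  ident <- matrix(NA_real_, nrow(transcripts), nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    ident[, j] <- identity_to_subject(transcripts$v_segment,
                                      catalog$v_seq[j])$identity
  }
  best <- apply(ident, 1L, which.max)   # first maximum = genomic order
  out <- transcripts
  out$best_hit <- catalog$gene_id[best]
  out$subgroup <- catalog$subgroup[best]
  out$identity <- round(100 * ident[cbind(seq_len(nrow(out)), best)], 2)
  out$category <- match_category(out$identity, 100 * threshold)
  structure(out, class = c("trl_matches", "tbl_df", "tbl", "data.frame"))
}

#' Summarize matches into the identical / allelic / novel trichotomy
#'
#' Counting is over unique expressed V sequences (exact nucleotide
#' deduplication on `v_segment`) when that column is present, otherwise
#' over rows.
#'
#' @param matches a `trl_matches` tibble (or any tibble with a `category`
#'   column).
#' @return a `trl_trichotomy` tibble: `category`, `n`, `pct` plus an
#'   `n_unique` attribute.
#' @export
#' @examples
#' m <- tibble::tibble(category = rep(
#'   c("identical", "allelic_or_unassembled", "novel"), c(67, 103, 21)
#' ))
#' summarize_matches(m)
summarize_matches <- function(matches) {
  x <- as_tibble(matches)
  if ("v_segment" %in% names(x)) {
    x <- distinct(x, .data$v_segment, .keep_all = TRUE)
  }
  levels_ <- c("identical", "allelic_or_unassembled", "novel")
  out <- x %>%
    count(category = factor(.data$category, levels = levels_),
          name = "n", .drop = FALSE) %>%
    mutate(category = as.character(.data$category),
           pct = round(100 * .data$n / sum(.data$n), 1))
  attr(out, "n_unique") <- nrow(x)
  structure(out, class = c("trl_trichotomy", "tbl_df", "tbl", "data.frame"))
}

#' Subgroup usage frequencies in an expressed repertoire
#'
#' Percentages of productive transcripts of one chain using each subgroup
#' (novel transcripts take the subgroup of their best genomic hit).
#'
#' @param matches a `trl_matches` tibble with `chain` and `productive`.
#' @param chain `"TRA"` or `"TRD"`.
#' @param productive_only drop non-productive transcripts (default TRUE).
#' @return a `trl_usage` tibble: `subgroup`, `n`, `pct`.
#' @export
usage_frequencies <- function(matches, chain, productive_only = TRUE) {
  x <- matches[matches$chain == chain, ]
  if (productive_only && "productive" %in% names(x)) {
    x <- x[x$productive, ]
  }
  if (nrow(x) == 0) abort("usage_frequencies(): empty transcript set")
  out <- x %>%
    count(.data$subgroup, name = "n") %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    arrange(dplyr::desc(.data$pct))
  structure(out, class = c("trl_usage", "tbl_df", "tbl", "data.frame"))
}

#' Representation bias of expressed vs genomic subgroup frequencies
#'
#' @param expressed usage tibble (`subgroup`, `pct`), e.g. from
#'   [usage_frequencies()].
#' @param genomic_functional tibble (`subgroup`, `pct`) of the functional
#'   genomic repertoire percentages over the same subgroup universe.
#' @param over,under ratio thresholds for the over-/under-represented calls.
#' @return tibble: `subgroup`, `expressed_pct`, `genomic_pct`, `ratio`,
#'   `call` (`over_represented` / `under_represented` / `neutral` /
#'   `undefined` when the genomic share is zero).
#' @export
#' @examples
#' representation_bias(
#'   tibble::tibble(subgroup = "VX", pct = 23),
#'   tibble::tibble(subgroup = "VX", pct = 8)
#' )$ratio  # 2.875
representation_bias <- function(expressed, genomic_functional,
                                over = 2, under = 0.5) {
  subgroups <- union(expressed$subgroup, genomic_functional$subgroup)
  e <- setNames(rep(0, length(subgroups)), subgroups)
  g <- e
  e[expressed$subgroup] <- expressed$pct
  g[genomic_functional$subgroup] <- genomic_functional$pct
  ratio <- ifelse(g > 0, e / g, NA_real_)
  call <- dplyr::case_when(
    g == 0 & e > 0 ~ "undefined",
    g == 0 ~ "absent",
    ratio >= over ~ "over_represented",
    ratio <= under ~ "under_represented",
    TRUE ~ "neutral"
  )
  tibble(
    subgroup = subgroups,
    expressed_pct = unname(e), genomic_pct = unname(g),
    ratio = unname(ratio), call = unname(call)
  )
}

#' Subgroups expressed in both TRA and TRD chains
#'
#' @param matches a `trl_matches` tibble covering both chains (only
#'   productive transcripts count).
#' @return character vector of dual-usage subgroup labels.
#' @export
dual_usage <- function(matches) {
  x <- matches
  if ("productive" %in% names(x)) x <- x[x$productive, ]
  by_chain <- split(x$subgroup, x$chain)
  if (!all(c("TRA", "TRD") %in% names(by_chain))) {
    abort("dual_usage(): need transcripts from both chains")
  }
  sort(intersect(unique(by_chain$TRA), unique(by_chain$TRD)))
}
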