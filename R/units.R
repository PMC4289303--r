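# Homology-unit discovery from repeated gene-order motifs, replicon
# alignment and indel calling, unit coverage, and a dotplot-style identity
# profiler used as confirmatory evidence.
#
# Repeat detection operates on subgroup labels (the field's motif notation,
# e.g. "12-11-10-9"), not on gene ids; strand is recorded but ignored for
# matching.

#' Encode the gene order of an annotation as label strings
#'
#' @param genes genes tibble or `locus_annotation`; V genes are tokenized
#'   per contig in coordinate order. Genes without a subgroup become the
#'   never-matching token `"?"`.
#' @return tibble: `contig`, `position` (1-based order index), `token`
#'   (subgroup label), `strand`, `gene_id`.
#' @export
encode_gene_order <- function(genes) {
  if (inherits(genes, "locus_annotation")) genes <- genes$genes
  genes <- genes[genes$type == "V", ]
  genes %>%
    arrange(.data$contig, .data$start) %>%
    group_by(.data$contig) %>%
    mutate(position = row_number()) %>%
    ungroup() %>%
    mutate(token = ifelse(is.na(.data$subgroup), "?", .data$subgroup)) %>%
    select("contig", "position", "token", "strand", "gene_id")
}

# Greedy leftmost non-overlapping occurrences of `motif` (character vector)
# in token vector `tokens`; returns start positions.
motif_occurrences <- function(tokens, motif) {
  k <- length(motif)
  n <- length(tokens)
  if (k > n) return(integer(0))
  starts <- integer(0)
  i <- 1L
  while (i <= n - k + 1L) {
    if (all(tokens[i:(i + k - 1L)] == motif)) {
      starts <- c(starts, i)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  starts
}

# TRUE when motif is a whole-number repetition of a shorter period
is_periodic <- function(motif) {
  k <- length(motif)
  for (p in seq_len(k %/% 2)) {
    if (k %% p == 0L && all(motif == rep(motif[seq_len(p)], k %/% p))) {
      return(TRUE)
    }
  }
  FALSE
}

# TRUE when `motif` is a window of the infinite repetition of the shorter
# motif `period` (any phase): such motifs are artefacts of reading a tandem
# array through a frame wider than its repeating unit
is_array_window <- function(motif, period) {
  k <- length(motif)
  p <- length(period)
  if (p >= k) return(FALSE)
  stream <- rep(period, ceiling(k / p) + 1L)
  for (phase in seq_len(p)) {
    if (identical(stream[phase:(phase + k - 1L)], motif)) return(TRUE)
  }
  FALSE
}

# TRUE when a and b are circular rotations of one another (equal length)
is_rotation <- function(a, b) {
  k <- length(a)
  if (length(b) != k || k < 2L) return(FALSE)
  stream <- c(b, b)
  for (phase in seq_len(k)) {
    if (identical(stream[phase:(phase + k - 1L)], a)) return(TRUE)
  }
  FALSE
}

#' Find repeated gene-order motifs
#'
#' Enumerates all label subsequences of length >= `min_len` occurring at
#' least `min_occ` times across the contig token strings (occurrences
#' resolved greedily to non-overlapping instances, leftmost first). Motifs
#' containing the unassigned token `"?"` never match. Three reductions keep
#' the result interpretable: periodic motifs (a shorter motif repeated
#' whole) are dropped in favour of their period, array windows of a shorter
#' candidate are dropped (see Details), and motifs contained in a longer
#' motif with at least the same instance count are dropped as non-maximal.
#' The survivors are ordered longest first (then by instance count), the
#' order in which [build_homology_units()] lets them claim gene positions.
#'
#' @param orders gene-order tibble from [encode_gene_order()].
#' @param min_len minimum motif length in genes.
#' @param min_occ minimum number of instances.
#' @details The "array window" reduction removes motifs that are a
#'   phase-shifted window of a shorter candidate's infinite repetition.
#'   Reading a tandem array of `A-B` copies through any wider frame
#'   produces motifs like `A-B-A` whose occurrences are artefacts of the
#'   array, not independent repeats; dropping them leaves the primitive
#'   repeating unit. Among equal-length circular rotations of one gene
#'   order (`B-A` vs `A-B`) only the best-supported rotation is kept
#'   (higher instance count, ties to the lexicographically smaller motif).
#' @return tibble: `motif` (labels joined by `-`), `length`, `n_instances`,
#'   `instances` (list column of tibbles `contig`, `start`, `end`,
#'   `gene_ids`).
#' @export
find_repeated_motifs <- function(orders, min_len = 2L, min_occ = 2L) {
  stopifnot(min_len >= 2L, min_occ >= 2L)
  by_contig <- split(orders, orders$contig)
  token_sets <- lapply(by_contig, function(df) {
    df <- df[order(df$position), ]
    list(tokens = df$token, gene_ids = df$gene_id, contig = df$contig[1])
  })

  max_len <- max(vapply(token_sets, function(x) length(x$tokens), integer(1)))
  candidates <- new.env(parent = emptyenv())
  for (ts in token_sets) {
    n <- length(ts$tokens)
    for (len in min_len:min(max_len, n)) {
      for (s in seq_len(n - len + 1L)) {
        m <- ts$tokens[s:(s + len - 1L)]
        if ("?" %in% m) next
        key <- paste(m, collapse = "\r")
        if (!exists(key, candidates)) assign(key, m, candidates)
      }
    }
  }

  rows <- list()
  motif_vecs <- list()
  for (key in ls(candidates)) {
    motif <- get(key, candidates)
    inst <- list()
    for (ts in token_sets) {
      for (s in motif_occurrences(ts$tokens, motif)) {
        inst[[length(inst) + 1L]] <- tibble(
          contig = ts$contig, start = s, end = s + length(motif) - 1L,
          gene_ids = list(ts$gene_ids[s:(s + length(motif) - 1L)])
        )
      }
    }
    if (length(inst) >= min_occ && !is_periodic(motif)) {
      motif_len <- length(motif)
      rows[[length(rows) + 1L]] <- tibble(
        motif = paste(motif, collapse = "-"),
        length = motif_len,
        n_instances = length(inst),
        instances = list(bind_rows(inst))
      )
      motif_vecs[[length(motif_vecs) + 1L]] <- motif
    }
  }
  if (length(rows) == 0) {
    return(tibble(motif = character(0), length = integer(0),
                  n_instances = integer(0), instances = list()))
  }
  out <- bind_rows(rows)

  # drop array windows of shorter candidates, and among equal-length
  # rotations of one circular order keep the best-supported (see Details)
  lens <- vapply(motif_vecs, length, integer(1))
  window_drop <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      if (lens[j] < lens[i] &&
          is_array_window(motif_vecs[[i]], motif_vecs[[j]])) {
        window_drop[i] <- TRUE
        break
      }
      if (lens[j] == lens[i] &&
          is_rotation(motif_vecs[[i]], motif_vecs[[j]]) &&
          (out$n_instances[j] > out$n_instances[i] ||
             (out$n_instances[j] == out$n_instances[i] &&
                out$motif[j] < out$motif[i]))) {
        window_drop[i] <- TRUE
        break
      }
    }
  }
  out <- out[!window_drop, ]
  motif_vecs <- motif_vecs[!window_drop]

  # maximality: drop motifs contained in a longer motif with equal count
  contained_in <- function(short, long) {
    s <- strsplit(short, "-", fixed = TRUE)[[1]]
    l <- strsplit(long, "-", fixed = TRUE)[[1]]
    length(motif_occurrences(l, s)) > 0 ||
      any(vapply(seq_len(length(l) - length(s) + 1L), function(i) {
        all(l[i:(i + length(s) - 1L)] == s)
      }, logical(1)))
  }
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j && out$length[j] > out$length[i] &&
          out$n_instances[j] >= out$n_instances[i] &&
          contained_in(out$motif[i], out$motif[j])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out[keep, ] %>%
    arrange(dplyr::desc(.data$length), dplyr::desc(.data$n_instances),
            .data$motif)
}

# label-level global alignment (unit cost); returns aligned label vectors
# with NA for gaps
align_labels <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(
        D[i, j] + (a[i] != b[j]),
        D[i, j + 1] + 1,
        D[i + 1, j] + 1
      )
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (a[i] != b[j])) {
      ai <- c(a[i], ai); bi <- c(b[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1) {
      ai <- c(a[i], ai); bi <- c(NA, bi); i <- i - 1
    } else {
      ai <- c(NA, ai); bi <- c(b[j], bi); j <- j - 1
    }
  }
  list(a = ai, b = bi, dist = D[n + 1, m + 1])
}

label_edit_distance <- function(a, b) align_labels(a, b)$dist

#' Build homology units from repeated motifs
#'
#' The strongest motifs (by token coverage) claim their instances first;
#' instances overlapping already-claimed tokens are discarded. Motifs within
#' `merge_edit_distance` label edits of a unit's consensus are merged into
#' that unit as variant instances. Each instance is aligned to the unit
#' consensus at the label level, yielding per-copy missing-gene / extra-gene
#' calls; units whose instances differ in 5'/3' extent are flagged
#' `variable_content`, internal gaps flag `post_replication_indel`.
#'
#' @param motifs tibble from [find_repeated_motifs()].
#' @param orders gene-order tibble from [encode_gene_order()].
#' @param merge_edit_distance label edits tolerated when absorbing motif
#'   variants into a unit.
#' @param min_motif_genes minimum consensus length.
#' @param genes optional genes tibble (for genomic spans / unit size).
#' @return a `trl_units` tibble: `unit`, `motif`, `n_genes`, `n_instances`,
#'   `size_kb`, `variable_content`, `post_replication_indel`, `instances`
#'   (list column: `contig`, `start`, `end`, `gene_ids`, `missing`,
#'   `extra`).
#' @export
build_homology_units <- function(motifs, orders, merge_edit_distance = 2L,
                                 min_motif_genes = 2L, genes = NULL) {
  if (inherits(genes, "locus_annotation")) genes <- genes$genes
  motifs <- motifs[motifs$length >= min_motif_genes, ]
  if (nrow(motifs) == 0) {
    return(structure(
      tibble(unit = integer(0), motif = character(0), n_genes = integer(0),
             n_instances = integer(0), size_kb = numeric(0),
             variable_content = logical(0),
             post_replication_indel = logical(0), instances = list()),
      class = c("trl_units", "tbl_df", "tbl", "data.frame")
    ))
  }
  claimed <- new.env(parent = emptyenv())   # contig -> claimed positions
  claim_key <- function(contig) contig
  is_free <- function(contig, s, e) {
    taken <- if (exists(claim_key(contig), claimed)) {
      get(claim_key(contig), claimed)
    } else {
      integer(0)
    }
    !any(s:e %in% taken)
  }
  claim <- function(contig, s, e) {
    old <- if (exists(claim_key(contig), claimed)) {
      get(claim_key(contig), claimed)
    } else {
      integer(0)
    }
    assign(claim_key(contig), c(old, s:e), claimed)
  }

  units <- list()
  for (i in seq_len(nrow(motifs))) {
    inst <- motifs$instances[[i]]
    free <- vapply(seq_len(nrow(inst)), function(r) {
      is_free(inst$contig[r], inst$start[r], inst$end[r])
    }, logical(1))
    inst <- inst[free, ]
    if (nrow(inst) >= 2) {
      for (r in seq_len(nrow(inst))) {
        claim(inst$contig[r], inst$start[r], inst$end[r])
      }
      units[[length(units) + 1L]] <- list(
        consensus = strsplit(motifs$motif[i], "-", fixed = TRUE)[[1]],
        instances = inst
      )
    }
  }

  # absorb variant replicon copies: align unclaimed token runs against each
  # unit consensus and accept windows within merge_edit_distance label edits
  if (length(units) > 0 && merge_edit_distance > 0) {
    by_contig <- split(orders, orders$contig)
    for (df in by_contig) {
      df <- df[order(df$position), ]
      repeat {
        taken <- if (exists(claim_key(df$contig[1]), claimed)) {
          get(claim_key(df$contig[1]), claimed)
        } else {
          integer(0)
        }
        open <- setdiff(which(df$token != "?"), taken)
        if (length(open) == 0) break
        best <- NULL
        for (u in seq_along(units)) {
          cons <- units[[u]]$consensus
          for (L in max(2L, length(cons) - merge_edit_distance):
                 (length(cons) + merge_edit_distance)) {
            for (s in open) {
              e <- s + L - 1L
              if (e > nrow(df) || !all(s:e %in% open)) next
              dd <- label_edit_distance(df$token[s:e], cons)
              if (dd >= 1 && dd <= merge_edit_distance &&
                  (is.null(best) || dd < best$d ||
                     (dd == best$d && s < best$s))) {
                best <- list(u = u, s = s, e = e, d = dd)
              }
            }
          }
        }
        if (is.null(best)) break
        claim(df$contig[1], best$s, best$e)
        units[[best$u]]$instances <- bind_rows(
          units[[best$u]]$instances,
          tibble(contig = df$contig[1], start = best$s, end = best$e,
                 gene_ids = list(df$gene_id[best$s:best$e]))
        )
      }
    }
  }

  # flank co-extension: when replicon copies share an exact core but
  # differ by an inserted or deleted gene, exact repeat finding only sees
  # the core. Extend all instances of a unit outward in lock-step while at
  # least two instances agree on the next token, allowing an instance to
  # skip over up to merge_edit_distance copy-specific inserted genes; the
  # consensus grows with the agreed tokens and skipped genes surface as
  # extra-gene calls in the per-instance alignment.
  if (merge_edit_distance > 0) {
    tok_by_contig <- lapply(split(orders, orders$contig), function(df) {
      df[order(df$position), ]
    })
    for (u in seq_along(units)) {
      inst <- units[[u]]$instances
      if (nrow(inst) < 2) next
      consensus <- units[[u]]$consensus
      skips <- rep(0L, nrow(inst))
      max_side <- length(consensus) + merge_edit_distance
      for (side in c("left", "right")) {
        grown_side <- 0L
        repeat {
          if (grown_side >= max_side) break
          # candidate next token per instance (with optional skip-ahead)
          step <- if (side == "left") -1L else 1L
          edge <- if (side == "left") inst$start else inst$end
          cand <- lapply(seq_len(nrow(inst)), function(r) {
            df <- tok_by_contig[[inst$contig[r]]]
            p1 <- edge[r] + step
            ok <- function(p) {
              p >= 1 && p <= nrow(df) && df$token[p] != "?" &&
                is_free(inst$contig[r], p, p)
            }
            if (!ok(p1)) return(NULL)
            out <- list(direct = df$token[p1], direct_pos = p1,
                        skip = NULL, skip_pos = NULL)
            p2 <- p1 + step
            if (skips[r] < merge_edit_distance && ok(p2)) {
              out$skip <- df$token[p2]
              out$skip_pos <- p2
            }
            out
          })
          direct <- vapply(cand, function(x) {
            if (is.null(x)) NA_character_ else x$direct
          }, character(1))
          counts <- table(direct[!is.na(direct)])
          if (length(counts) == 0) break
          # best-supported label, counting skip-assisted agreement
          support_of <- function(t) {
            sum(vapply(cand, function(x) {
              !is.null(x) && (x$direct == t ||
                                (!is.null(x$skip) && x$skip == t))
            }, logical(1)))
          }
          labels_ <- sort(names(counts))
          supp <- vapply(labels_, support_of, numeric(1))
          best <- labels_[order(-supp, labels_)][1]
          if (supp[best] < 2) break
          for (r in seq_len(nrow(inst))) {
            x <- cand[[r]]
            if (is.null(x)) next
            if (x$direct == best) {
              take <- x$direct_pos
            } else if (!is.null(x$skip) && x$skip == best) {
              take <- c(x$direct_pos, x$skip_pos)   # skipped gene + match
              skips[r] <- skips[r] + 1L
            } else {
              next
            }
            claim(inst$contig[r], min(take), max(take))
            if (side == "left") {
              inst$start[r] <- min(take)
            } else {
              inst$end[r] <- max(take)
            }
            df <- tok_by_contig[[inst$contig[r]]]
            inst$gene_ids[[r]] <- df$gene_id[inst$start[r]:inst$end[r]]
          }
          consensus <- if (side == "left") c(best, consensus) else
            c(consensus, best)
          grown_side <- grown_side + 1L
        }
      }
      units[[u]]$instances <- inst
      units[[u]]$consensus <- consensus
    }
  }

  gene_span <- function(ids) {
    if (is.null(genes)) return(NA_real_)
    gs <- genes[genes$gene_id %in% ids, ]
    (max(gs$end) - min(gs$start)) / 1000
  }

  rows <- list()
  for (u in seq_along(units)) {
    consensus <- units[[u]]$consensus
    inst <- units[[u]]$instances
    inst$missing <- vector("list", nrow(inst))
    inst$extra <- vector("list", nrow(inst))
    lead_gap <- logical(nrow(inst)); internal_gap <- logical(nrow(inst))
    for (r in seq_len(nrow(inst))) {
      inst_labels <- orders$token[match(inst$gene_ids[[r]], orders$gene_id)]
      al <- align_labels(inst_labels, consensus)
      gap_inst <- is.na(al$a)        # consensus label absent from instance
      gap_cons <- is.na(al$b)        # instance label beyond consensus
      inst$missing[[r]] <- al$b[gap_inst]
      inst$extra[[r]] <- al$a[gap_cons]
      gap_any <- gap_inst | gap_cons
      if (any(gap_any)) {
        # leading/trailing gap columns = differing 5'/3' extent; internal
        # gap columns = genes gained or lost after replication
        inner_cols <- cumsum(!gap_any) > 0 & rev(cumsum(rev(!gap_any))) > 0
        lead_gap[r] <- any(gap_any & !inner_cols)
        internal_gap[r] <- any(gap_any & inner_cols)
      }
    }
    sizes <- vapply(inst$gene_ids, gene_span, numeric(1))
    rows[[length(rows) + 1L]] <- tibble(
      unit = u,
      motif = paste(consensus, collapse = "-"),
      n_genes = length(consensus),
      n_instances = nrow(inst),
      size_kb = if (all(is.na(sizes))) NA_real_ else
        round(max(sizes, na.rm = TRUE), 1),
      variable_content = any(lead_gap),
      post_replication_indel = any(internal_gap),
      instances = list(inst)
    )
  }
  structure(bind_rows(rows),
            class = c("trl_units", "tbl_df", "tbl", "data.frame"))
}

#' Fraction of V genes located inside homology units
#'
#' @param genes genes tibble or `locus_annotation` (V genes counted).
#' @param units a `trl_units` tibble.
#' @return list: `genes_in_units`, `total`, `fraction`, `pct`.
#' @export
#' @examples
#' unit_coverage_counts(288, 371)$pct  # 77.6
unit_coverage <- function(genes, units) {
  if (inherits(genes, "locus_annotation")) genes <- genes$genes
  total <- sum(genes$type == "V")
  in_units <- unique(unlist(lapply(units$instances, function(inst) {
    unlist(inst$gene_ids)
  })))
  in_units <- intersect(in_units, genes$gene_id[genes$type == "V"])
  unit_coverage_counts(length(in_units), total)
}

#' @rdname unit_coverage
#' @param genes_in_units,total counts (direct-entry form).
#' @export
unit_coverage_counts <- function(genes_in_units, total) {
  frac <- if (total > 0) genes_in_units / total else 0
  list(genes_in_units = genes_in_units, total = total,
       fraction = frac, pct = round(100 * frac, 1))
}

# ---- dotplot ----------------------------------------------------------------

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

chain_diagonal <- function(positions, k, max_gap) {
  # positions: sorted starts of seed matches on one diagonal
  segs <- list()
  s <- positions[1]; prev <- positions[1]
  for (p in positions[-1]) {
    if (p - prev <= max_gap) {
      prev <- p
    } else {
      segs[[length(segs) + 1L]] <- c(s, prev + k - 1L)
      s <- p; prev <- p
    }
  }
  segs[[length(segs) + 1L]] <- c(s, prev + k - 1L)
  segs
}

#' Dotplot-style identity segments between two sequences
#'
#' Exact k-mer seed matches are chained along diagonals (seeds on the same
#' diagonal separated by at most `max_gap` bp join one segment); segments
#' shorter than `min_run` are dropped. Both strands are scanned.
#'
#' @param seq_a,seq_b DNA sequences.
#' @param k word size (>= 8).
#' @param min_run minimum reported segment length (bp).
#' @param max_gap maximum seed gap within a segment (default `k`).
#' @return a `trl_dotplot` tibble: `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based inclusive, `seq_b` forward coordinates), `strand`, `length`,
#'   `pct_identity` (seed-covered fraction of the segment).
#' @export
identity_dotplot <- function(seq_a, seq_b, k = 12L, min_run = 100L,
                             max_gap = k) {
  stopifnot(k >= 8L)
  scan_strand <- function(b_seq, strand) {
    ka <- kmer_starts(seq_a, k)
    kb <- kmer_starts(b_seq, k)
    if (length(ka) == 0 || length(kb) == 0) return(NULL)
    kb_index <- split(seq_along(kb), kb)
    rows <- list()
    hits_i <- integer(0); hits_j <- integer(0)
    present <- ka %in% names(kb_index)
    for (i in which(present)) {
      js <- kb_index[[ka[i]]]
      hits_i <- c(hits_i, rep(i, length(js)))
      hits_j <- c(hits_j, js)
    }
    if (length(hits_i) == 0) return(NULL)
    diagonal <- hits_i - hits_j
    for (d in unique(diagonal)) {
      pos <- sort(hits_i[diagonal == d])
      covered <- unique(unlist(lapply(pos, function(p) p:(p + k - 1L))))
      for (seg in chain_diagonal(pos, k, max_gap)) {
        len <- seg[2] - seg[1] + 1L
        if (len < min_run) next
        n_cov <- sum(covered >= seg[1] & covered <= seg[2])
        b1 <- seg[1] - d; b2 <- seg[2] - d
        if (strand == "-") {
          nb <- nchar(b_seq)
          tmp <- c(nb - b2 + 1L, nb - b1 + 1L)
          b1 <- tmp[1]; b2 <- tmp[2]
        }
        rows[[length(rows) + 1L]] <- tibble(
          a_start = as.integer(seg[1]), a_end = as.integer(seg[2]),
          b_start = as.integer(b1), b_end = as.integer(b2),
          strand = strand, length = as.integer(len),
          pct_identity = round(100 * n_cov / len, 1)
        )
      }
    }
    if (length(rows) > 0) bind_rows(rows) else NULL
  }
  out <- bind_rows(
    scan_strand(seq_b, "+"),
    scan_strand(revcomp(seq_b), "-")
  )
  if (nrow(out) == 0) {
    out <- tibble(a_start = integer(0), a_end = integer(0),
                  b_start = integer(0), b_end = integer(0),
                  strand = character(0), length = integer(0),
                  pct_identity = numeric(0))
  }
  structure(arrange(out, .data$a_start),
            class = c("trl_dotplot", "tbl_df", "tbl", "data.frame"))
}
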