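# Pairwise nucleotide identity, subgroup clustering at the 75% convention,
# and orthology-guided subgroup naming.

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: alignment columns where either sequence has a gap
#' (`-`) are excluded; the distance is the fraction of differing bases over
#' the remaining comparable sites.
#'
#' @param a,b aligned sequences of equal length (may contain `-`).
#' @return list with `distance`, `sites` (comparable site count) and
#'   `identity` (= 1 - distance).
#' @export
#' @examples
#' p_distance("ACGTT", "ACGTA")$distance  # 0.2
#' p_distance("AC-GT", "ACAGT")$distance  # 0 over 4 sites
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("p_distance(): aligned lengths differ")
  }
  ac <- split_chars(a)
  bc <- split_chars(b)
  keep <- ac != "-" & bc != "-"
  n <- sum(keep)
  if (n == 0L) {
    abort("p_distance(): no comparable sites (all columns gapped)")
  }
  d <- sum(ac[keep] != bc[keep]) / n
  list(distance = d, sites = n, identity = 1 - d)
}

#' Globally align two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap open
#' -4, gap extend -1; deterministic and self-contained, so pairwise
#' identities do not depend on a multiple alignment.
#'
#' @param a,b unaligned DNA sequences.
#' @return list of the two aligned strings.
#' @export
align_pair <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Aligned p-distance of two unaligned sequences
#'
#' Sequences of equal length are compared site-wise: at the divergences
#' where identity matters here (subgroup membership, transcript matching)
#' the optimal global alignment of equal-length sequences is gap-free, so
#' the site-wise comparison equals the alignment result. Unequal lengths
#' go through [align_pair()].
#'
#' @inheritParams align_pair
#' @return as [p_distance()].
#' @export
aligned_p_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) return(p_distance(a, b))
  aln <- align_pair(a, b)
  p_distance(aln$a, aln$b)
}

# identity of many target sequences against one subject, batching the
# equal-length targets into a vectorized site-wise comparison and the rest
# into one vectorized global alignment call
identity_to_subject <- function(targets, subject) {
  n <- length(targets)
  ident <- numeric(n)
  sites <- integer(n)
  same <- which(nchar(targets) == nchar(subject))
  diff <- setdiff(seq_len(n), same)
  if (length(same) > 0) {
    for (i in same) {
      pd <- p_distance(targets[[i]], subject)
      ident[i] <- pd$identity
      sites[i] <- pd$sites
    }
  }
  if (length(diff) > 0) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    )
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(targets[diff]),
      Biostrings::DNAString(subject),
      type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1
    )
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(diff)) {
      pd <- p_distance(pa[k], sa[k])
      ident[diff[k]] <- pd$identity
      sites[diff[k]] <- pd$sites
    }
  }
  list(identity = ident, sites = sites)
}

#' All-pairs identity matrix over a set of V gene sequences
#'
#' Each pair is globally aligned ([align_pair()]) and its p-distance taken
#' with pairwise deletion.
#'
#' @param seqs named character vector of sequences (names become ids).
#' @return a `trl_identity_matrix`: list with `ids`, `distance` (symmetric
#'   p-distance matrix), `sites` (comparable-site counts).
#' @export
identity_matrix <- function(seqs) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(nchar(seqs), n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      rest <- (i + 1):n
      res <- identity_to_subject(unname(seqs[rest]), seqs[[i]])
      d[i, rest] <- d[rest, i] <- 1 - res$identity
      sites[i, rest] <- sites[rest, i] <- res$sites
    }
  }
  structure(list(ids = ids, distance = d, sites = sites),
            class = "trl_identity_matrix")
}

#' Cluster genes into subgroups by nucleotide identity
#'
#' Subgroups are the connected components of the graph with an edge between
#' every pair of genes at identity >= `threshold` (conventionally 0.75).
#' Because the convention is not transitive, the diagnostics report
#' within-cluster pairs that fall below the threshold (joined through
#' intermediates) and near-threshold pairs within 2 percentage points.
#'
#' @param im a `trl_identity_matrix` from [identity_matrix()].
#' @param threshold identity threshold (fraction).
#' @return a `trl_clusters`: list with `membership` tibble (`gene_id`,
#'   `cluster`) and `diagnostics` tibble (`gene_id_a`, `gene_id_b`,
#'   `identity`, `note`).
#' @export
cluster_by_identity <- function(im, threshold = 0.75) {
  ident <- 1 - im$distance
  n <- length(im$ids)
  adj <- ident >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  membership <- tibble(gene_id = im$ids, cluster = as.integer(comp))
  diag_rows <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- comp[i] == comp[j]
        idv <- ident[i, j]
        if (same && idv < threshold) {
          diag_rows[[length(diag_rows) + 1L]] <- tibble(
            gene_id_a = im$ids[i], gene_id_b = im$ids[j],
            identity = idv, note = "within_cluster_below_threshold"
          )
        } else if (!same && idv >= threshold - 0.02) {
          diag_rows[[length(diag_rows) + 1L]] <- tibble(
            gene_id_a = im$ids[i], gene_id_b = im$ids[j],
            identity = idv, note = "cross_cluster_near_threshold"
          )
        }
      }
    }
  }
  diagnostics <- if (length(diag_rows) > 0) bind_rows(diag_rows) else
    tibble(gene_id_a = character(0), gene_id_b = character(0),
           identity = numeric(0), note = character(0))
  structure(list(membership = membership, diagnostics = diagnostics,
                 threshold = threshold),
            class = "trl_clusters")
}

#' Name clusters after orthologous reference subgroups
#'
#' A cluster inherits a reference subgroup name when its mean member
#' identity to that reference subgroup is maximal among references and at
#' least `identity_floor`, and (when a joint tree is supplied) the cluster
#' members are monophyletic with that reference's genes. Clusters claiming
#' the same reference are resolved in favour of the higher mean identity.
#' Remaining clusters receive alphabetic designations (X, Y, Z, ...) in
#' genomic order of their first member.
#'
#' @param clusters a `trl_clusters`.
#' @param seqs named sequences of the clustered genes.
#' @param references tibble with `ref_id`, `subgroup`, `seq` (reference V
#'   genes, e.g. human/murine orthologs).
#' @param joint_tree optional rooted `phylo` over cluster members and
#'   reference ids, used for the monophyly condition.
#' @param identity_floor minimum mean identity for orthology naming.
#' @param genomic_order optional character vector of gene ids in genomic
#'   order (defaults to membership order).
#' @return tibble: `cluster`, `name`, `mean_identity`, `basis`
#'   (`"orthology"` or `"alphabetic"`).
#' @export
assign_orthologous_names <- function(clusters, seqs, references,
                                     joint_tree = NULL,
                                     identity_floor = 0.631,
                                     genomic_order = NULL) {
  mem <- clusters$membership
  genomic_order <- genomic_order %||% mem$gene_id
  cl_ids <- sort(unique(mem$cluster))
  ref_groups <- split(references, references$subgroup)

  mean_ident <- function(members, ref_df) {
    vals <- vapply(seq_len(nrow(ref_df)), function(k) {
      mean(identity_to_subject(unname(seqs[members]),
                               ref_df$seq[k])$identity)
    }, numeric(1))
    mean(vals)
  }

  monophyletic_with <- function(members, ref_df) {
    if (is.null(joint_tree)) return(TRUE)
    tips <- c(members, ref_df$ref_id)
    tips <- intersect(tips, joint_tree$tip.label)
    if (length(tips) < 2) return(FALSE)
    ape::is.monophyletic(joint_tree, tips)
  }

  claims <- list()
  for (cl in cl_ids) {
    members <- mem$gene_id[mem$cluster == cl]
    mi <- vapply(ref_groups, function(rg) mean_ident(members, rg), numeric(1))
    best <- names(mi)[which.max(mi)]
    ok <- mi[[best]] >= identity_floor &&
      monophyletic_with(members, ref_groups[[best]])
    claims[[length(claims) + 1L]] <- tibble(
      cluster = cl, candidate = if (ok) best else NA_character_,
      mean_identity = mi[[best]],
      first_gene_rank = min(match(members, genomic_order))
    )
  }
  claims <- bind_rows(claims)

  # resolve conflicting claims: higher mean identity wins
  claims <- claims %>% arrange(dplyr::desc(.data$mean_identity))
  taken <- character(0)
  claims$name <- NA_character_
  for (i in seq_len(nrow(claims))) {
    cand <- claims$candidate[i]
    if (!is.na(cand) && !cand %in% taken) {
      claims$name[i] <- cand
      taken <- c(taken, cand)
    }
  }
  unnamed <- which(is.na(claims$name))
  unnamed <- unnamed[order(claims$first_gene_rank[unnamed])]
  alpha <- c("X", "Y", "Z", paste0("Z", seq_len(50)))
  for (k in seq_along(unnamed)) {
    claims$name[unnamed[k]] <- alpha[k]
  }
  claims %>%
    mutate(basis = ifelse(is.na(.data$candidate) |
                            .data$candidate != .data$name,
                          "alphabetic", "orthology")) %>%
    arrange(.data$cluster) %>%
    select("cluster", "name", "mean_identity", "basis")
}
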