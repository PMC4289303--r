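# Distance-tree construction on p-distances, bootstrap support, outgroup
# rooting and assignment of genes to monophyletic groups.
#
# Neighbour-joining is the primary builder (exact on additive matrices);
# UPGMA and an OLS minimum-evolution approximation are provided as
# robustness checks behind the same interface.

#' p-distance matrix from an aligned sequence matrix
#'
#' @param aln character matrix (rows = taxa, columns = aligned sites; gaps
#'   as `-`) or a named character vector of equal-length aligned sequences.
#' @return symmetric p-distance matrix (pairwise deletion per pair).
#' @export
aligned_distance_matrix <- function(aln) {
  if (!is.matrix(aln)) {
    aln <- do.call(rbind, lapply(aln, function(s) split_chars(s)))
  }
  n <- nrow(aln)
  ids <- rownames(aln) %||% paste0("t", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      keep <- aln[i, ] != "-" & aln[j, ] != "-"
      ns <- sum(keep)
      if (ns == 0L) {
        abort(paste0("no comparable sites between ", ids[i], " and ", ids[j]))
      }
      d[i, j] <- d[j, i] <- sum(aln[i, keep] != aln[j, keep]) / ns
    }
  }
  d
}

check_dist_input <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || !isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    abort("distance matrix must be square and symmetric")
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  dm
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; exact on additive matrices. Negative branch
#' length estimates are clamped to zero for display with the raw values
#' retained in `tree$raw.edge.length`. For two taxa the single edge is
#' split equally (NJ proper is undefined at n = 2).
#'
#' @param dm symmetric zero-diagonal distance matrix (or `dist`).
#' @param method `"nj"` (default), `"upgma"`, or `"me"` (OLS minimum
#'   evolution via NJ + nearest-neighbour interchange).
#' @return an `ape` `phylo` tree.
#' @export
#' @examples
#' d <- matrix(0.3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' diag(d) <- 0
#' nj_tree(d)$edge.length  # three branches of 0.15
nj_tree <- function(dm, method = c("nj", "upgma", "me")) {
  method <- match.arg(method)
  dm <- check_dist_input(dm)
  n <- nrow(dm)
  if (n < 2) abort("nj_tree(): need at least 2 taxa")
  if (n == 2) {
    tree <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);", rownames(dm)[1], dm[1, 2] / 2,
      rownames(dm)[2], dm[1, 2] / 2
    ))
    tree$raw.edge.length <- tree$edge.length
    return(tree)
  }
  tree <- switch(method,
    nj = ape::nj(stats::as.dist(dm)),
    upgma = {
      hc <- stats::hclust(stats::as.dist(dm), method = "average")
      ape::as.phylo(hc)
    },
    me = ape::fastme.ols(stats::as.dist(dm), nni = TRUE)
  )
  tree$raw.edge.length <- tree$edge.length
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Bootstrap support for the bipartitions of an NJ tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate's p-distance matrix is rebuilt into an NJ tree and the
#' fraction of replicates containing each internal bipartition of the
#' original tree is reported as a percentage.
#'
#' @param aln aligned sequences (matrix or named vector, as
#'   [aligned_distance_matrix()]).
#' @param n_reps bootstrap replicates.
#' @param seed integer seed; fixed seed gives identical supports.
#' @param method tree builder passed to [nj_tree()].
#' @return list with `tree` (original tree, support in `node.label`) and
#'   `support` tibble (`node`, `support`, `clade` leaf list).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              method = "nj") {
  if (!is.matrix(aln)) {
    aln <- do.call(rbind, lapply(aln, function(s) split_chars(s)))
  }
  if (ncol(aln) < 1) abort("bootstrap_support(): empty alignment")
  main <- nj_tree(aligned_distance_matrix(aln), method = method)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      nj_tree(aligned_distance_matrix(aln[, cols, drop = FALSE]),
              method = method)
    })
  })
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps, 1)
  main$node.label <- as.character(support)
  tbl <- tibble(
    node = ape::Ntip(main) + seq_along(support),
    support = support,
    clade = lapply(ape::prop.part(main), function(idx) {
      main$tip.label[idx]
    })
  )
  list(tree = main, support = tbl)
}

#' Root a tree on an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge, so
#' all leaf-to-leaf path lengths are preserved.
#'
#' @param tree a `phylo`.
#' @param outgroup_id a leaf label.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label) {
    abort(paste0("root_with_outgroup(): unknown leaf '", outgroup_id, "'"))
  }
  tip <- match(outgroup_id, tree$tip.label)
  pend <- which(tree$edge[, 2] == tip)
  pend_len <- tree$edge.length[pend]
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  root_node <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  # split the outgroup's pendant edge equally across the two root edges
  if (length(kids) == 2) {
    total <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- total / 2
  }
  rooted
}

#' Assign leaves to phylogenetic groups from anchor leaves
#'
#' Each group is the smallest clade of the rooted tree containing all of
#' its anchors; leaves in no anchor clade are unassigned. Nested or
#' overlapping anchor clades are an error carrying a structured conflict
#' report.
#'
#' @param tree rooted `phylo`.
#' @param anchors named list: group label -> character vector of anchor
#'   leaf labels (disjoint sets).
#' @return a `trl_groups` tibble: `gene_id`, `group`.
#' @export
assign_phylo_groups <- function(tree, anchors) {
  stopifnot(is.list(anchors), length(anchors) >= 1)
  all_anchors <- unlist(anchors)
  if (anyDuplicated(all_anchors)) {
    abort("assign_phylo_groups(): anchor sets overlap")
  }
  missing <- setdiff(all_anchors, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("anchors not in tree: ", paste(missing, collapse = ", ")))
  }
  clades <- lapply(anchors, function(a) {
    if (length(a) == 1) return(a)
    node <- ape::getMRCA(tree, a)
    ape::extract.clade(tree, node)$tip.label
  })
  for (i in seq_along(clades)) {
    for (j in seq_along(clades)) {
      if (i < j && length(intersect(clades[[i]], clades[[j]])) > 0) {
        abort(paste0(
          "assign_phylo_groups(): anchor clades overlap: '",
          names(anchors)[i], "' and '", names(anchors)[j], "' share ",
          length(intersect(clades[[i]], clades[[j]])), " leaves"
        ))
      }
    }
  }
  assignment <- setNames(rep(NA_character_, length(tree$tip.label)),
                         tree$tip.label)
  for (g in names(clades)) assignment[clades[[g]]] <- g
  structure(
    tibble(gene_id = tree$tip.label,
           group = ifelse(is.na(assignment), "unassigned",
                          unname(assignment))),
    class = c("trl_groups", "tbl_df", "tbl", "data.frame")
  )
}

#' Percentage of genes per phylogenetic group
#'
#' @param assignment tibble from [assign_phylo_groups()].
#' @param subset optional character vector of gene ids to restrict to
#'   (e.g. functional genes only).
#' @return tibble: `group`, `n`, `pct` (percentages sum to 100 over
#'   assigned + unassigned genes of the subset).
#' @export
group_distribution <- function(assignment, subset = NULL) {
  x <- assignment
  if (!is.null(subset)) x <- x[x$gene_id %in% subset, ]
  if (nrow(x) == 0) abort("group_distribution(): empty subset")
  x %>%
    count(.data$group, name = "n") %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    arrange(.data$group)
}
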