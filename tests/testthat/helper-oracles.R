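# Shared fixtures and independent oracles used across the suite.

# Default simulation and derived objects shared by the integration-style
# tests (each built once per run).
.trl_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .trl_test_cache)) {
    assign(key, force(expr), .trl_test_cache)
  }
  get(key, .trl_test_cache)
}

default_sim <- function(seed = 1L) {
  cached(paste0("sim", seed), simulate_locus(sim_config(rng_seed = seed)))
}

default_tx <- function(seed = 1L) {
  cached(paste0("tx", seed), simulate_transcripts(default_sim(seed)))
}

default_matches <- function(seed = 1L) {
  cached(paste0("m", seed), {
    match_v_segments(default_tx(seed)$transcripts,
                     default_sim(seed)$annotation)
  })
}

default_calls <- function(seed = 1L) {
  cached(paste0("calls", seed), {
    classify_v_genes(default_sim(seed)$annotation,
                     default_sim(seed)$truth$references)
  })
}

# Turn a V template into a one-row genes tibble (coordinates are dummies;
# classification only reads sequences and location_class).
template_gene_row <- function(parts, id = "g1",
                              location_class = "locus_chromosome") {
  tibble::tibble(
    gene_id = id, type = "V", subgroup = parts$subgroup, chain = "TRA",
    contig = "c1", start = 0L, end = 1000L, strand = "+",
    location_class = location_class,
    l_start = NA_integer_, l_end = NA_integer_,
    v_start = NA_integer_, v_end = NA_integer_,
    rs_start = NA_integer_, rs_end = NA_integer_,
    d_start = NA_integer_, d_end = NA_integer_,
    l_seq = parts$l_seq, intron_seq = parts$intron_seq,
    v_seq = parts$v_seq, rs_seq = parts$rs_seq,
    donor_seq = NA_character_
  )
}

template_reference <- function(parts) {
  tibble::tibble(
    subgroup = parts$subgroup,
    ref_peptide = parts$ref_peptide,
    ref_v_length = parts$ref_v_length,
    leader_codons = parts$leader_codons
  )
}

# ---- brute-force repeated-motif oracle -------------------------------------
# Independent enumeration: every substring of every string, counted by an
# iterative leftmost non-overlapping scan, with periodicity checked through
# divisors and maximality through superstring containment on position sets.

oracle_count_nonoverlap <- function(tokens, motif) {
  k <- length(motif)
  count <- 0L
  i <- 1L
  while (i + k - 1L <= length(tokens)) {
    if (identical(tokens[i:(i + k - 1L)], motif)) {
      count <- count + 1L
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  count
}

oracle_is_periodic <- function(motif) {
  k <- length(motif)
  divisors <- which(k %% seq_len(k - 1) == 0)
  for (p in divisors) {
    ok <- TRUE
    for (i in seq_len(k)) {
      if (motif[i] != motif[((i - 1L) %% p) + 1L]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

oracle_repeated_motifs <- function(token_strings, min_len = 2L,
                                   min_occ = 2L) {
  cand <- list()
  for (tokens in token_strings) {
    n <- length(tokens)
    for (len in min_len:n) {
      if (len > n) break
      for (s in 1:(n - len + 1L)) {
        m <- tokens[s:(s + len - 1L)]
        if ("?" %in% m) next
        cand[[paste(m, collapse = "\r")]] <- m
      }
    }
  }
  counts <- vapply(cand, function(m) {
    sum(vapply(token_strings, oracle_count_nonoverlap, integer(1), motif = m))
  }, integer(1))
  keep <- counts >= min_occ &
    !vapply(cand, oracle_is_periodic, logical(1))
  motifs <- cand[keep]
  counts <- counts[keep]
  if (length(motifs) == 0) return(character(0))
  # array windows: motif readable from the infinite repetition of a shorter
  # kept motif at some phase (modular-index comparison); among equal-length
  # rotations only the best-supported survives
  is_window_of <- function(m, per) {
    if (length(per) >= length(m)) return(FALSE)
    for (phase in 0:(length(per) - 1L)) {
      idx <- ((phase + seq_along(m) - 1L) %% length(per)) + 1L
      if (all(m == per[idx])) return(TRUE)
    }
    FALSE
  }
  rotation_of <- function(m, other) {
    if (length(m) != length(other) || length(m) < 2) return(FALSE)
    any(vapply(0:(length(m) - 1L), function(phase) {
      idx <- ((phase + seq_along(m) - 1L) %% length(m)) + 1L
      all(m == other[idx])
    }, logical(1)))
  }
  keystr <- vapply(motifs, paste, character(1), collapse = "-")
  win <- vapply(seq_along(motifs), function(i) {
    any(vapply(seq_along(motifs), function(j) {
      if (i == j) return(FALSE)
      if (is_window_of(motifs[[i]], motifs[[j]])) return(TRUE)
      rotation_of(motifs[[i]], motifs[[j]]) &&
        (counts[j] > counts[i] ||
           (counts[j] == counts[i] && keystr[j] < keystr[i]))
    }, logical(1)))
  }, logical(1))
  motifs <- motifs[!win]
  counts <- counts[!win]
  if (length(motifs) == 0) return(character(0))
  is_sub <- function(short, long) {
    ks <- length(short)
    any(vapply(seq_len(length(long) - ks + 1L), function(i) {
      identical(long[i:(i + ks - 1L)], short)
    }, logical(1)))
  }
  maximal <- rep(TRUE, length(motifs))
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i != j && length(motifs[[j]]) > length(motifs[[i]]) &&
          counts[j] >= counts[i] && is_sub(motifs[[i]], motifs[[j]])) {
        maximal[i] <- FALSE
        break
      }
    }
  }
  sort(unname(vapply(motifs[maximal], paste, character(1), collapse = "-")))
}

# ---- least-squares tree oracle ---------------------------------------------
# OLS branch-length fit for a fixed topology; exhaustive over all unrooted
# topologies (small n) this recovers the generating tree of an additive
# matrix with zero residual.

ols_fit_rss <- function(topology, dm) {
  topo <- ape::unroot(topology)
  n_tip <- ape::Ntip(topo)
  edges <- topo$edge
  n_edge <- nrow(edges)
  # tips under each edge's child node: an edge lies on the i-j path iff
  # exactly one of i, j is below it
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    kids <- edges[edges[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  below <- lapply(edges[, 2], tips_under)
  pairs <- utils::combn(n_tip, 2)
  X <- matrix(0, ncol(pairs), n_edge)
  d <- numeric(ncol(pairs))
  tipnames <- topo$tip.label
  for (pc in seq_len(ncol(pairs))) {
    i <- pairs[1, pc]; j <- pairs[2, pc]
    X[pc, ] <- vapply(below, function(b) {
      xor(i %in% b, j %in% b)
    }, logical(1))
    d[pc] <- dm[tipnames[i], tipnames[j]]
  }
  fit <- stats::lm.fit(X, d)
  sum(fit$residuals^2)
}

oracle_best_topology <- function(dm) {
  n <- nrow(dm)
  all_topos <- phangorn::allTrees(n, rooted = FALSE,
                                  tip.label = rownames(dm))
  rss <- vapply(all_topos, ols_fit_rss, numeric(1), dm = dm)
  all_topos[[which.min(rss)]]
}

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.4))
  tr
}
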