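# Birth-and-death locus simulator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: an ancestral set of subgroup template V genes, tandem duplication
# of multi-gene segments ("homology units") with per-copy substitutions,
# per-gene pseudogenizing lesions planted at subgroup-specific death rates,
# and expressed transcripts drawn from functional genes with small allelic
# divergence plus a configurable fraction from genes hidden from the
# assembly. Every event is logged so recovery by the pipeline can be checked
# exactly.

LEADER_CODONS <- 16L          # leader incl. initiator ATG (48 bp)
VREG_CODONS <- 104L           # V-REGION codons 1..104 (312 bp)
INTRON_LEN <- 87L
RS_HEPTAMER <- "CACAGTG"
RS_NONAMER <- "ACAAAAACC"
V_ANCHORS <- c(C23 = 23L, W41 = 41L, C104 = 104L)

anchor_nt_positions <- function() {
  as.vector(vapply(V_ANCHORS, function(p) (p - 1L) * 3L + 1:3, integer(3)))
}

protected_positions <- function() {
  list(
    l = 1:3,                                  # initiator ATG
    intron = c(1:2, INTRON_LEN - 1L, INTRON_LEN),
    v = anchor_nt_positions(),
    rs23 = c(1:7, 31:39),                     # heptamer + nonamer
    rs12 = c(1:7, 20:28)
  )
}

# Revert any stop codons created in the conceptually spliced leader+V ORF.
repair_stops <- function(l_seq, v_seq, l_ref, v_ref) {
  spliced <- paste0(l_seq, v_seq)
  ref <- paste0(l_ref, v_ref)
  cods <- codons_of(spliced)
  bad <- which(is_stop_codon(cods))
  for (i in bad) {
    substr(spliced, 3L * i - 2L, 3L * i) <- substr(ref, 3L * i - 2L, 3L * i)
  }
  nl <- nchar(l_seq)
  list(l_seq = substr(spliced, 1L, nl),
       v_seq = substr(spliced, nl + 1L, nchar(spliced)))
}

# Substitute sites of a V gene part set while preserving functional
# competence (anchors, splice dinucleotides, RS consensus and ORF openness
# are protected; created stops are reverted).
mutate_v_parts <- function(parts, rate) {
  if (rate <= 0) return(parts)
  prot <- protected_positions()
  out <- parts
  out$l_seq <- mutate_rate(parts$l_seq, rate, prot$l)
  out$intron_seq <- mutate_rate(parts$intron_seq, rate, prot$intron)
  out$v_seq <- mutate_rate(parts$v_seq, rate, prot$v)
  if (!is.na(parts$rs_seq)) {
    out$rs_seq <- mutate_rate(parts$rs_seq, rate, prot$rs23)
  }
  fixed <- repair_stops(out$l_seq, out$v_seq, parts$l_seq, parts$v_seq)
  out$l_seq <- fixed$l_seq
  out$v_seq <- fixed$v_seq
  out
}

#' Build a functional V gene template for a subgroup
#'
#' Templates are deterministic per subgroup label (each label seeds its own
#' stream) with a small amount of per-call jitter drawn from the ambient RNG,
#' so two templates of the same subgroup are closely related while templates
#' of different subgroups are unrelated random sequences. By construction a
#' fresh template is functionally competent: `GT..AG` intron, in-frame
#' leader+V exon with no stop codons, cysteine/tryptophan/cysteine at IMGT
#' positions 23/41/104, and a canonical heptamer-23 bp spacer-nonamer
#' recombination signal.
#'
#' @param subgroup_label subgroup name; determines the template core.
#' @param base_seed integer folded into the label seed so different
#'   simulations get different template sets.
#' @param jitter per-site substitution rate applied on top of the label
#'   template (at unconstrained sites only).
#' @param plant_lesion optional lesion kind to plant (see
#'   [lesion_kinds()]).
#' @return a list with coding-orientation part sequences (`l_seq`,
#'   `intron_seq`, `v_seq`, `rs_seq`), the planted `lesions` tibble and the
#'   reference translation used for IMGT anchor mapping.
#' @export
#' @examples
#' tpl <- make_v_gene_template("V3", base_seed = 1)
#' nchar(tpl$v_seq)
make_v_gene_template <- function(subgroup_label, base_seed = 0L,
                                 jitter = 0.02, plant_lesion = NULL) {
  core <- with_seed(label_seed(subgroup_label, base_seed), {
    l_seq <- paste0("ATG", random_codons(LEADER_CODONS - 1L))
    v_seq <- random_codons(VREG_CODONS)
    for (i in seq_along(V_ANCHORS)) {
      p <- V_ANCHORS[[i]]
      codon <- c("TGT", "TGG", "TGC")[i]
      substr(v_seq, 3L * p - 2L, 3L * p) <- codon
    }
    list(
      l_seq = l_seq,
      intron_seq = paste0("GT", random_dna(INTRON_LEN - 4L), "AG"),
      v_seq = v_seq,
      rs_seq = paste0(RS_HEPTAMER, random_dna(23L), RS_NONAMER)
    )
  })
  parts <- mutate_v_parts(core, jitter)
  parts$subgroup <- subgroup_label
  parts$lesions <- tibble(kind = character(0), detail = character(0),
                          position = integer(0))
  parts$ref_peptide <- translate_dna(paste0(parts$l_seq, parts$v_seq))
  parts$leader_codons <- LEADER_CODONS
  parts$ref_v_length <- nchar(parts$v_seq)
  if (!is.null(plant_lesion)) parts <- plant_lesion(parts, plant_lesion)
  parts
}

#' Lesion kinds known to the simulator
#'
#' The menu mirrors the defect classes a rule-based competence classifier
#' can call: premature stop codons, 1/2/4 bp frameshifting deletions,
#' disrupted splice donor/acceptor sites, loss of the conserved C23/W41/C104
#' anchors, a mutated recombination-signal heptamer, and truncation (loss of
#' part of the gene sequence, rendering competence unassessable).
#' @return character vector of lesion kind names.
#' @export
lesion_kinds <- function() {
  c("premature_stop", "frameshift_del", "splice_donor_mut",
    "splice_acceptor_mut", "C23_mut", "W41_mut", "C104_mut",
    "RS_heptamer_mut", "truncation")
}

#' Plant a pseudogenizing lesion into a template's parts
#' @param parts a template from [make_v_gene_template()].
#' @param kind one of [lesion_kinds()].
#' @return the modified parts with the lesion appended to `parts$lesions`.
#' @export
plant_lesion <- function(parts, kind) {
  add <- function(kind, detail, position) {
    parts$lesions <<- bind_rows(
      parts$lesions,
      tibble(kind = kind, detail = detail, position = as.integer(position))
    )
  }
  if (kind == "premature_stop") {
    avoid <- c(V_ANCHORS, V_ANCHORS + 1L)
    cp <- sample(setdiff(30:95, avoid), 1L)
    substr(parts$v_seq, 3L * cp - 2L, 3L * cp) <- "TAA"
    add(kind, "TAA", LEADER_CODONS + cp)
  } else if (kind == "frameshift_del") {
    nb <- sample(c(1L, 2L, 4L), 1L)
    pos <- sample(130:250, 1L)
    parts$v_seq <- paste0(substr(parts$v_seq, 1L, pos - 1L),
                          substr(parts$v_seq, pos + nb, nchar(parts$v_seq)))
    add("frameshift", paste0("del_", nb, "bp"), pos)
  } else if (kind == "splice_donor_mut") {
    substr(parts$intron_seq, 1L, 1L) <- "A"
    add(kind, "GT>AT", 1L)
  } else if (kind == "splice_acceptor_mut") {
    substr(parts$intron_seq, nchar(parts$intron_seq),
           nchar(parts$intron_seq)) <- "C"
    add(kind, "AG>AC", nchar(parts$intron_seq))
  } else if (kind %in% c("C23_mut", "W41_mut", "C104_mut")) {
    p <- V_ANCHORS[[sub("_mut$", "", kind)]]
    repl <- switch(kind, C23_mut = "CGT", W41_mut = "CGG", C104_mut = "GGT")
    substr(parts$v_seq, 3L * p - 2L, 3L * p) <- repl
    add(kind, repl, LEADER_CODONS + p)
  } else if (kind == "RS_heptamer_mut") {
    substr(parts$rs_seq, 1L, 1L) <- "G"
    add(kind, "CAC>GAC", 1L)
  } else if (kind == "truncation") {
    parts$rs_seq <- NA_character_
    add("missing_sequence", "rs", NA)
  } else {
    abort(paste0("unknown lesion kind: ", kind))
  }
  parts
}

# ---- J gene templates -------------------------------------------------------

J_CODONS <- 19L   # ~57 bp coding region
J_FGXG_AT <- 9L   # FGxG motif starts at codon 9

make_j_gene_template <- function(label, base_seed = 0L, jitter = 0.02,
                                 plant_lesion = NULL) {
  core <- with_seed(label_seed(label, base_seed), {
    coding <- random_codons(J_CODONS)
    substr(coding, 3L * J_FGXG_AT - 2L, 3L * J_FGXG_AT) <- "TTT"      # F
    substr(coding, 3L * (J_FGXG_AT + 1L) - 2L, 3L * (J_FGXG_AT + 1L)) <- "GGA"
    substr(coding, 3L * (J_FGXG_AT + 3L) - 2L, 3L * (J_FGXG_AT + 3L)) <- "GGC"
    list(
      coding = coding,
      rs_seq = paste0(RS_HEPTAMER, random_dna(12L), RS_NONAMER),
      donor_seq = "GT"
    )
  })
  prot_coding <- as.vector(vapply(
    J_FGXG_AT + c(0L, 1L, 3L), function(p) (p - 1L) * 3L + 1:3, integer(3)
  ))
  out <- core
  out$coding <- mutate_rate(core$coding, jitter, prot_coding)
  cods <- codons_of(out$coding)
  for (i in which(is_stop_codon(cods))) {
    substr(out$coding, 3L * i - 2L, 3L * i) <-
      substr(core$coding, 3L * i - 2L, 3L * i)
  }
  out$rs_seq <- mutate_rate(core$rs_seq, jitter, protected_positions()$rs12)
  out$lesions <- tibble(kind = character(0), detail = character(0),
                        position = integer(0))
  if (!is.null(plant_lesion)) {
    add <- function(kind, detail, position) {
      out$lesions <<- bind_rows(out$lesions, tibble(
        kind = kind, detail = detail, position = as.integer(position)
      ))
    }
    if (plant_lesion == "missing_FGxG") {
      substr(out$coding, 3L * J_FGXG_AT - 2L, 3L * J_FGXG_AT) <- "CTT"
      add("missing_FGxG", "F>L", J_FGXG_AT)
    } else if (plant_lesion == "RS_heptamer_mut") {
      substr(out$rs_seq, 1L, 1L) <- "G"
      add("RS_heptamer_mut", "CAC>GAC", 1L)
    } else if (plant_lesion == "splice_donor_mut") {
      out$donor_seq <- "AT"
      add("splice_donor_mut", "GT>AT", 1L)
    } else {
      abort(paste0("unknown J lesion kind: ", plant_lesion))
    }
  }
  out
}

# ---- simulation configuration ----------------------------------------------

#' Simulation configuration
#'
#' Defaults define a desk-scale locus with the structural features of a
#' ruminant TRA/TRD V-gene region: eight subgroups with heterogeneous death
#' rates, three homology units replicated 3-6 times, occasional truncation
#' and post-duplication gene deletion, and an expressed repertoire with an
#' 11 percent unassembled-gene ("novel") fraction, 0-3 percent allelic
#' divergence and TRD usage dominated by a single subgroup.
#'
#' @param subgroups tibble with columns `label`, `chain`, `n_ancestral`,
#'   `death_prob`.
#' @param events tibble of duplication events with columns `start`, `end`
#'   (gene-order indices at the time the event is applied), `n_copies`,
#'   `subs_rate` (per-site substitutions per copy), `trunc_prob`.
#' @param lesion_menu named weights over pseudogenizing lesion kinds.
#' @param post_dup_deletion_prob probability that a duplicated gene copy is
#'   subsequently lost from the locus.
#' @param n_traj,n_trdj number of J genes per chain.
#' @param j_pseudo_n exact number of J genes carrying a planted lesion.
#' @param spacer_range intergenic spacer length range (bp).
#' @param invert_gene_ids gene ids to place on the minus strand in the
#'   assembled contig (the locus carries inverted V genes in real life).
#' @param transcript_params list: `n_tra`, `n_trd`, `novel_fraction`,
#'   `identical_fraction` (of non-novel transcripts), `allelic_divergence`
#'   (range), `novel_divergence` (range), `usage` (per-chain named subgroup
#'   weight lists), `nonproductive_fraction`.
#' @param rng_seed mandatory integer seed.
#' @return a `trl_sim_config` list.
#' @export
sim_config <- function(subgroups = NULL, events = NULL,
                       lesion_menu = NULL,
                       post_dup_deletion_prob = 0.03,
                       n_traj = 12L, n_trdj = 3L, j_pseudo_n = 2L,
                       spacer_range = c(200L, 400L),
                       invert_gene_ids = character(0),
                       transcript_params = list(),
                       rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) {
    abort("sim_config(): `rng_seed` is mandatory")
  }
  if (is.null(subgroups)) {
    subgroups <- tibble(
      label = c("V2", "V3", "V8", "V9", "V23", "V25", "VX", "DV1"),
      chain = c(rep("TRA", 7), "TRD"),
      n_ancestral = 1L,
      death_prob = c(0.20, 0.10, 0.50, 0.60, 0.70, 0.30, 0.15, 0.20)
    )
  }
  if (is.null(events)) {
    events <- tibble(
      start = c(1L, 15L, 23L),
      end = c(2L, 16L, 26L),
      n_copies = c(6L, 3L, 4L),
      subs_rate = 0.01,
      trunc_prob = 0.02
    )
  }
  if (is.null(lesion_menu)) {
    lesion_menu <- c(
      premature_stop = 3, frameshift_del = 2, splice_donor_mut = 1,
      splice_acceptor_mut = 1, C23_mut = 1, W41_mut = 1, C104_mut = 1,
      RS_heptamer_mut = 2
    )
  }
  tp <- utils::modifyList(list(
    n_tra = 60L, n_trd = 60L,
    novel_fraction = 0.11,
    identical_fraction = 0.393,
    allelic_divergence = c(0.004, 0.029),
    novel_divergence = c(0.036, 0.079),
    usage = list(
      TRA = c(VX = 0.23, V3 = 0.11),
      TRD = c(DV1 = 0.90)
    ),
    nonproductive_fraction = 0.05
  ), transcript_params)
  stopifnot(
    all(subgroups$death_prob >= 0 & subgroups$death_prob <= 1),
    all(events$n_copies >= 1),
    tp$novel_fraction >= 0, tp$novel_fraction <= 1
  )
  structure(
    list(
      subgroups = subgroups, events = events, lesion_menu = lesion_menu,
      post_dup_deletion_prob = post_dup_deletion_prob,
      n_traj = as.integer(n_traj), n_trdj = as.integer(n_trdj),
      j_pseudo_n = as.integer(j_pseudo_n),
      spacer_range = as.integer(spacer_range),
      invert_gene_ids = invert_gene_ids,
      transcript_params = tp,
      rng_seed = as.integer(rng_seed)
    ),
    class = "trl_sim_config"
  )
}

# ---- locus simulation -------------------------------------------------------

#' Simulate an annotated locus with ground truth
#'
#' Applies the configured tandem duplication events in order, planting
#' substitutions and lesions on each copy, then assembles the locus sequence
#' and annotation. The returned truth log records gene ancestry, every
#' duplication event, all planted lesions, the true homology-unit instances
#' and the true competence status of every gene.
#'
#' @param config a [sim_config()].
#' @return a `trl_simulation`: list with `annotation` (a
#'   [locus_annotation()]), `truth` (ancestry/events/lesions/units/status
#'   tibbles plus the subgroup reference table) and `config`.
#' @export
#' @examples
#' sim <- simulate_locus(sim_config(rng_seed = 1))
#' nrow(sim$annotation$genes)
simulate_locus <- function(config) {
  stopifnot(inherits(config, "trl_sim_config"))
  with_seed(config$rng_seed, simulate_locus_impl(config))
}

simulate_locus_impl <- function(config) {
  sg <- config$subgroups
  counters <- setNames(rep(0L, nrow(sg)), sg$label)
  next_id <- function(label) {
    counters[label] <<- counters[label] + 1L
    paste0(label, ".", counters[label])
  }
  death_prob <- setNames(sg$death_prob, sg$label)
  chain_of <- setNames(sg$chain, sg$label)

  references <- list()
  make_gene <- function(label, jitter = 0.01) {
    parts <- make_v_gene_template(label, base_seed = config$rng_seed,
                                  jitter = jitter)
    if (is.null(references[[label]])) {
      references[[label]] <<- tibble(
        subgroup = label,
        ref_peptide = parts$ref_peptide,
        ref_v_length = parts$ref_v_length,
        leader_codons = parts$leader_codons
      )
    }
    list(
      gene_id = next_id(label), subgroup = label,
      chain = chain_of[[label]], parts = parts,
      status = "functional",
      lesions = parts$lesions, ancestor = NA_character_
    )
  }

  # ancestral locus
  genes <- list()
  for (i in seq_len(nrow(sg))) {
    for (k in seq_len(sg$n_ancestral[i])) {
      genes[[length(genes) + 1L]] <- make_gene(sg$label[i])
    }
  }

  lesion_log <- list()
  plant_on_copy <- function(g, trunc_prob) {
    if (runif(1) < trunc_prob) {
      g$parts <- plant_lesion(g$parts, "truncation")
      g$status <- "incomplete"
    } else if (runif(1) < death_prob[[g$subgroup]]) {
      kind <- sample(names(config$lesion_menu), 1L,
                     prob = config$lesion_menu)
      g$parts <- plant_lesion(g$parts, kind)
      g$status <- "pseudogene"
    }
    g$lesions <- g$parts$lesions
    g
  }

  events_log <- list()
  units <- list()
  ev <- config$events
  for (e in seq_len(nrow(ev))) {
    s <- ev$start[e]; t <- ev$end[e]
    if (s < 1 || t > length(genes) || s > t) {
      abort(paste0("simulate_locus(): event ", e,
                   " span exceeds current locus (", length(genes), " genes)"))
    }
    source_genes <- genes[s:t]
    motif <- vapply(source_genes, function(g) g$subgroup, character(1))
    instances <- list(vapply(source_genes, function(g) g$gene_id,
                             character(1)))
    copies <- list()
    for (k in seq_len(ev$n_copies[e])) {
      copy_ids <- character(0)
      for (src in source_genes) {
        g <- src
        g$gene_id <- next_id(g$subgroup)
        g$ancestor <- src$gene_id
        g$parts <- mutate_v_parts(g$parts, ev$subs_rate[e])
        g$parts$lesions <- src$parts$lesions[0, ]
        g <- plant_on_copy(g, ev$trunc_prob[e])
        if (nrow(g$lesions) > 0) {
          lesion_log[[length(lesion_log) + 1L]] <-
            mutate(g$lesions, gene_id = g$gene_id)
        }
        copies[[length(copies) + 1L]] <- g
        copy_ids <- c(copy_ids, g$gene_id)
      }
      instances[[length(instances) + 1L]] <- copy_ids
    }
    genes <- append(genes, copies, after = t)
    events_log[[e]] <- tibble(
      event = e, source_start = s, source_end = t,
      n_copies = ev$n_copies[e],
      source_ids = paste(instances[[1L]], collapse = ","),
      motif = paste(motif, collapse = "-")
    )
    units[[e]] <- tibble(
      unit = e, motif = list(motif), instances = list(instances)
    )
  }

  # post-duplication gene loss (copies only, never ancestral genes)
  deleted <- character(0)
  if (config$post_dup_deletion_prob > 0) {
    is_copy <- vapply(genes, function(g) !is.na(g$ancestor), logical(1))
    drop <- is_copy & runif(length(genes)) < config$post_dup_deletion_prob
    deleted <- vapply(genes[drop], function(g) g$gene_id, character(1))
    genes <- genes[!drop]
    if (length(deleted) > 0) {
      units <- lapply(units, function(u) {
        u$instances[[1L]] <- lapply(u$instances[[1L]], setdiff, y = deleted)
        u
      })
    }
  }

  # J genes
  j_genes <- list()
  j_labels <- c(
    if (config$n_traj > 0) paste0("TRAJ", seq_len(config$n_traj)),
    if (config$n_trdj > 0) paste0("TRDJ", seq_len(config$n_trdj))
  )
  j_lesioned <- if (config$j_pseudo_n > 0 && length(j_labels) > 0) {
    sample(j_labels, min(config$j_pseudo_n, length(j_labels)))
  } else {
    character(0)
  }
  j_menu <- c("missing_FGxG", "RS_heptamer_mut", "splice_donor_mut")
  for (lab in j_labels) {
    lk <- if (lab %in% j_lesioned) sample(j_menu, 1L) else NULL
    tpl <- make_j_gene_template(lab, base_seed = config$rng_seed,
                                plant_lesion = lk)
    j_genes[[length(j_genes) + 1L]] <- list(
      gene_id = lab, subgroup = NA_character_,
      chain = if (grepl("^TRAJ", lab)) "TRA" else "TRD",
      parts = tpl,
      status = if (lab %in% j_lesioned) "pseudogene" else "functional",
      lesions = tpl$lesions, ancestor = NA_character_
    )
    if (nrow(tpl$lesions) > 0) {
      lesion_log[[length(lesion_log) + 1L]] <-
        mutate(tpl$lesions, gene_id = lab)
    }
  }

  assembled <- assemble_contig(genes, j_genes, config)

  truth <- list(
    ancestry = tibble(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      ancestor = vapply(genes, `[[`, character(1), "ancestor")
    ),
    events = bind_rows(events_log),
    planted_lesions = if (length(lesion_log) > 0) {
      bind_rows(lesion_log)[, c("gene_id", "kind", "detail", "position")]
    } else {
      tibble(gene_id = character(0), kind = character(0),
             detail = character(0), position = integer(0))
    },
    true_units = bind_rows(units),
    deleted_genes = deleted,
    status = tibble(
      gene_id = c(vapply(genes, `[[`, character(1), "gene_id"),
                  vapply(j_genes, `[[`, character(1), "gene_id")),
      status = c(vapply(genes, `[[`, character(1), "status"),
                 vapply(j_genes, `[[`, character(1), "status"))
    ),
    references = bind_rows(references)
  )

  structure(
    list(annotation = assembled, truth = truth, config = config),
    class = "trl_simulation"
  )
}

# Lay genes along a single contig with random intergenic spacers, computing
# genomic part coordinates (minus-strand blocks are reverse complemented).
assemble_contig <- function(genes, j_genes, config) {
  contig_name <- "sim_contig_1"
  chunks <- character(0)
  cur <- 0L
  rows <- list()
  sp <- config$spacer_range

  push_spacer <- function() {
    n <- sample(sp[1]:sp[2], 1L)
    chunks[[length(chunks) + 1L]] <<- random_dna(n)
    cur <<- cur + n
  }

  add_gene <- function(g, type) {
    strand <- if (g$gene_id %in% config$invert_gene_ids) "-" else "+"
    p <- g$parts
    if (type == "V") {
      seqs <- c(l = p$l_seq, intron = p$intron_seq, v = p$v_seq,
                rs = p$rs_seq)
    } else {
      seqs <- c(rs = p$rs_seq, v = p$coding, d = p$donor_seq)
    }
    seqs <- seqs[!is.na(seqs)]
    lens <- nchar(seqs)
    offs <- cumsum(c(0L, lens))[seq_along(seqs)]
    block <- paste(seqs, collapse = "")
    blen <- nchar(block)
    coords <- lapply(seq_along(seqs), function(i) {
      s <- offs[i]; e <- offs[i] + lens[i]
      if (strand == "-") c(cur + blen - e, cur + blen - s) else
        c(cur + s, cur + e)
    })
    names(coords) <- names(seqs)
    getc <- function(tag, j) {
      if (tag %in% names(coords)) as.integer(coords[[tag]][j]) else NA_integer_
    }
    rows[[length(rows) + 1L]] <<- tibble(
      gene_id = g$gene_id, type = type, subgroup = g$subgroup,
      chain = g$chain, contig = contig_name,
      start = cur, end = cur + blen, strand = strand,
      location_class = "locus_chromosome",
      l_start = getc("l", 1), l_end = getc("l", 2),
      v_start = getc("v", 1), v_end = getc("v", 2),
      rs_start = getc("rs", 1), rs_end = getc("rs", 2),
      d_start = getc("d", 1), d_end = getc("d", 2),
      l_seq = if (type == "V") p$l_seq else NA_character_,
      intron_seq = if (type == "V") p$intron_seq else NA_character_,
      v_seq = if (type == "V") p$v_seq else p$coding,
      rs_seq = if (type == "V" && is.na(p$rs_seq)) NA_character_ else p$rs_seq,
      donor_seq = if (type == "V") NA_character_ else p$donor_seq
    )
    chunks[[length(chunks) + 1L]] <<-
      if (strand == "-") revcomp(block) else block
    cur <<- cur + blen
  }

  for (g in genes) {
    push_spacer()
    add_gene(g, "V")
  }
  for (g in j_genes) {
    push_spacer()
    add_gene(g, "J")
  }
  push_spacer()

  contig <- paste(chunks, collapse = "")
  locus_annotation(bind_rows(rows), setNames(contig, contig_name),
                   provenance = "trlocus-simulation")
}

# ---- transcript simulation --------------------------------------------------

#' Simulate expressed TRA/TRD transcripts from a simulated locus
#'
#' Each transcript's V segment is copied from a functional gene of the
#' requested chain with an exact number of substituted sites drawn from the
#' configured allelic divergence range (a configured fraction is copied
#' unchanged). A `novel_fraction` of transcripts is instead drawn from a
#' hidden gene: a functional gene diverged into the sub-97 percent identity
#' band and excluded from the annotation, emulating genes absent from a
#' fragmented assembly. Subgroup usage follows the configured per-chain
#' weights.
#'
#' @param sim a `trl_simulation` from [simulate_locus()].
#' @param seed optional seed; defaults to the simulation seed plus one.
#' @return list with `transcripts` (tibble: `transcript_id`, `chain`,
#'   `v_segment`, `j_label`, `productive`) and `truth` (tibble:
#'   `transcript_id`, `origin`, `category_true`, `n_mut`, `subgroup_true`).
#' @export
simulate_transcripts <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "trl_simulation"))
  seed <- seed %||% (sim$config$rng_seed + 1L)
  with_seed(seed, simulate_transcripts_impl(sim))
}

simulate_transcripts_impl <- function(sim) {
  tp <- sim$config$transcript_params
  genes <- sim$annotation$genes
  status <- sim$truth$status
  vg <- genes[genes$type == "V", ]
  vg <- left_join(vg, status, by = "gene_id")
  functional <- vg[vg$status == "functional", ]
  j_ok <- genes$type == "J" &
    genes$gene_id %in% status$gene_id[status$status == "functional"]
  j_pool <- split(genes$gene_id[j_ok], genes$chain[j_ok])

  draw_for_chain <- function(chain, n) {
    pool <- functional[functional$chain == chain, ]
    if (nrow(pool) == 0) {
      abort(paste0("simulate_transcripts(): no functional ", chain, " genes"))
    }
    weights <- tp$usage[[chain]] %||% numeric(0)
    labs <- unique(pool$subgroup)
    w <- setNames(rep(0, length(labs)), labs)
    named <- intersect(names(weights), labs)
    w[named] <- weights[named]
    rest <- setdiff(labs, named)
    if (length(rest) > 0) w[rest] <- max(0, 1 - sum(w[named])) / length(rest)
    if (sum(w) <= 0) w[] <- 1
    out <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- sample(labs, 1L, prob = w[labs])
      cand <- pool[pool$subgroup == lab, ]
      g <- cand[sample(nrow(cand), 1L), ]
      len <- nchar(g$v_seq)
      if (runif(1) < tp$novel_fraction) {
        lo <- ceiling(tp$novel_divergence[1] * len)
        hi <- floor(tp$novel_divergence[2] * len)
        n_mut <- sample(lo:hi, 1L)
        seqv <- mutate_n_sites(g$v_seq, n_mut)
        cat_true <- "novel"
        origin <- "novel"
      } else if (runif(1) < tp$identical_fraction) {
        n_mut <- 0L
        seqv <- g$v_seq
        cat_true <- "identical"
        origin <- g$gene_id
      } else {
        lo <- max(1L, ceiling(tp$allelic_divergence[1] * len))
        hi <- floor(tp$allelic_divergence[2] * len)
        n_mut <- sample(lo:hi, 1L)
        seqv <- mutate_n_sites(g$v_seq, n_mut)
        cat_true <- "allelic_or_unassembled"
        origin <- g$gene_id
      }
      jl <- j_pool[[chain]]
      out[[i]] <- tibble(
        chain = chain, v_segment = seqv,
        j_label = if (length(jl) > 0) sample(jl, 1L) else NA_character_,
        productive = runif(1) >= tp$nonproductive_fraction,
        origin = origin, category_true = cat_true,
        n_mut = n_mut, subgroup_true = g$subgroup, source_gene = g$gene_id
      )
    }
    bind_rows(out)
  }

  res <- bind_rows(
    draw_for_chain("TRA", tp$n_tra),
    draw_for_chain("TRD", tp$n_trd)
  )
  res$transcript_id <- sprintf("tx_%03d", seq_len(nrow(res)))
  list(
    transcripts = res[, c("transcript_id", "chain", "v_segment", "j_label",
                          "productive")],
    truth = res[, c("transcript_id", "origin", "category_true", "n_mut",
                    "subgroup_true", "source_gene", "chain")]
  )
}
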