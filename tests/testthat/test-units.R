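# Gene-order motifs, homology-unit building, coverage and the dotplot.

orders_from_tokens <- function(tokens, contig = "c1") {
  tibble::tibble(
    contig = contig, position = seq_along(tokens), token = tokens,
    strand = "+", gene_id = paste0(contig, "_g", seq_along(tokens))
  )
}

test_that("gene order encoding follows coordinates with '?' for unassigned", {
  sim <- default_sim()
  orders <- encode_gene_order(sim$annotation)
  vg <- sim$annotation$genes[sim$annotation$genes$type == "V", ]
  vg <- vg[order(vg$contig, vg$start), ]
  expect_identical(orders$gene_id, vg$gene_id)
  expect_identical(orders$token, vg$subgroup)

  vg2 <- vg
  vg2$subgroup[3] <- NA
  orders2 <- encode_gene_order(vg2)
  expect_identical(orders2$token[3], "?")
  # unassigned tokens never match
  motifs <- find_repeated_motifs(orders_from_tokens(c("?", "A", "?", "A")))
  expect_identical(nrow(motifs), 0L)
})

test_that("motif finding handles trivial and textbook cases", {
  expect_identical(
    nrow(find_repeated_motifs(orders_from_tokens(c("A", "B", "C", "D")))),
    0L
  )
  m <- find_repeated_motifs(
    orders_from_tokens(c("A", "B", "X", "A", "B", "Y", "A", "B"))
  )
  expect_identical(m$motif, "A-B")
  expect_identical(m$n_instances, 3L)
})

test_that("motif finder agrees with the brute-force enumerator on random strings", {
  trlocus:::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(8:30, 1)
      tokens <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
      mine <- find_repeated_motifs(orders_from_tokens(tokens))
      oracle <- oracle_repeated_motifs(list(tokens))
      expect_identical(sort(mine$motif), oracle,
                       info = paste(tokens, collapse = " "))
    }
  })
})

test_that("a quadruplet motif recurring six times in a tandem array is recovered", {
  # layout like a V-gene region where the ordered quadruplet 12-11-10-9
  # recurs six times between flanking singleton genes
  tokens <- c("5", rep(c("12", "11", "10", "9"), 6), "38", "37")
  m <- find_repeated_motifs(orders_from_tokens(tokens))
  hit <- m[m$motif == "12-11-10-9", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_instances, 6L)
  units <- build_homology_units(m, orders_from_tokens(tokens))
  expect_identical(units$motif, "12-11-10-9")
  expect_identical(units$n_instances, 6L)
})

test_that("periodic composites are reduced to their repeating period", {
  tokens <- rep(c("A", "B"), 7)
  m <- find_repeated_motifs(orders_from_tokens(tokens))
  expect_true("A-B" %in% m$motif)
  expect_false(any(grepl("^A-B-A-B$", m$motif)))
})

test_that("two identical instances form one unflagged unit", {
  tokens <- c("A", "B", "C", "Z", "A", "B", "C")
  orders <- orders_from_tokens(tokens)
  units <- build_homology_units(find_repeated_motifs(orders), orders)
  expect_identical(nrow(units), 1L)
  expect_identical(units$motif, "A-B-C")
  expect_false(units$variable_content)
  expect_false(units$post_replication_indel)
})

test_that("an extra gene in one instance flags post-replication indel", {
  base <- c("33", "29", "28", "33", "34", "26", "33")
  with_extra <- c("33", "29", "28", "28", "33", "34", "26", "33")
  tokens <- c(base, "Z1", with_extra)
  orders <- orders_from_tokens(tokens)
  units <- build_homology_units(find_repeated_motifs(orders), orders,
                                merge_edit_distance = 2)
  expect_identical(nrow(units), 1L)
  expect_identical(units$n_instances, 2L)
  expect_true(units$post_replication_indel)
  extras <- unlist(units$instances[[1]]$extra)
  expect_identical(extras, "28")
})

test_that("a post-duplication deletion yields exactly one missing-gene call", {
  cfg <- sim_config(
    subgroups = tibble::tibble(label = c("VA", "VB", "VC"), chain = "TRA",
                               n_ancestral = 1L, death_prob = 0),
    events = tibble::tibble(start = 1L, end = 3L, n_copies = 3L,
                            subs_rate = 0, trunc_prob = 0),
    post_dup_deletion_prob = 0, n_traj = 0L, n_trdj = 0L, j_pseudo_n = 0L,
    rng_seed = 61
  )
  sim <- simulate_locus(cfg)
  genes <- sim$annotation$genes
  # delete the middle gene of the third copy
  victim <- genes$gene_id[genes$subgroup == "VB"][3]
  genes <- genes[genes$gene_id != victim, ]
  orders <- encode_gene_order(genes)
  units <- build_homology_units(find_repeated_motifs(orders), orders,
                                genes = genes)
  expect_identical(nrow(units), 1L)
  expect_identical(units$n_instances, 4L)
  missing <- unlist(units$instances[[1]]$missing)
  expect_identical(missing, "VB")
  expect_true(units$post_replication_indel)
})

test_that("units reproduce simulation truth exactly at zero substitution rate", {
  cfg <- sim_config(post_dup_deletion_prob = 0, rng_seed = 63,
                    events = tibble::tibble(
                      start = c(1L, 15L, 23L), end = c(2L, 16L, 26L),
                      n_copies = c(6L, 3L, 4L), subs_rate = 0,
                      trunc_prob = 0
                    ))
  sim <- simulate_locus(cfg)
  orders <- encode_gene_order(sim$annotation)
  units <- build_homology_units(find_repeated_motifs(orders), orders)
  truth <- sim$truth$true_units
  expect_identical(nrow(units), nrow(truth))
  truth_motifs <- vapply(truth$motif, paste, character(1), collapse = "-")
  expect_setequal(units$motif, truth_motifs)
  for (k in seq_len(nrow(truth))) {
    u <- units[units$motif == truth_motifs[k], ]
    true_sets <- lapply(truth$instances[[k]], sort)
    got_sets <- lapply(u$instances[[1]]$gene_ids, sort)
    expect_identical(length(got_sets), length(true_sets))
    for (s in true_sets) {
      expect_true(any(vapply(got_sets, identical, logical(1), y = s)))
    }
  }
})

test_that("unit coverage counts genes once and is monotone in merge distance", {
  tokens <- c("A", "B", "C", "Z", "A", "B", "C", "Q", "A", "C")
  orders <- orders_from_tokens(tokens)
  genes <- tibble::tibble(gene_id = orders$gene_id, type = "V",
                          start = seq_along(tokens) * 100,
                          end = seq_along(tokens) * 100 + 50)
  motifs <- find_repeated_motifs(orders)
  cov <- vapply(0:2, function(d) {
    units <- build_homology_units(motifs, orders, merge_edit_distance = d,
                                  genes = genes)
    unit_coverage(genes, units)$fraction
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[1], 6 / 10)   # two exact A-B-C instances
  expect_equal(cov[3], 8 / 10)   # + the A-C variant absorbed

  none <- build_homology_units(motifs[0, ], orders, genes = genes)
  expect_identical(unit_coverage(genes, none)$fraction, 0)
  expect_identical(unit_coverage_counts(3, 4)$fraction, 0.75)
})

test_that("dotplot reports self-identity, planted duplications and reverse strand", {
  bg <- trlocus:::with_seed(71, trlocus:::random_dna(6000))
  block <- substr(bg, 1000, 2499)
  planted <- paste0(substr(bg, 1, 3999), block, substr(bg, 4000, 6000))
  dp <- identity_dotplot(planted, planted, k = 16, min_run = 500)
  main <- dp[dp$a_start == 1 & dp$strand == "+", ]
  expect_identical(main$a_end, nchar(planted))
  expect_identical(main$pct_identity, 100)
  off <- dp[dp$a_start != 1 & dp$strand == "+", ]
  expect_identical(nrow(off), 2L)
  expect_true(all(abs(off$length - 1500) < 50))

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(block)))
  dp2 <- identity_dotplot(block, rc, k = 16, min_run = 500)
  expect_identical(unique(dp2$strand), "-")
  expect_identical(dp2$length[1], nchar(block))
})
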