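# Rule-based competence classification: individual checks, planted-lesion
# recovery and catalog accounting.

test_that("splice check accepts GT..AG and reports each violated site", {
  expect_identical(nrow(check_splice("GTAAATTTAG")), 0L)
  expect_identical(check_splice("ATAAATTTAG")$kind, "splice_donor_mut")
  expect_identical(check_splice("GTAAATTTAC")$kind, "splice_acceptor_mut")
  expect_setequal(check_splice("ATAAATTTAC")$kind,
                  c("splice_donor_mut", "splice_acceptor_mut"))
})

test_that("ORF check finds internal stops at the codon reported by a brute-force scan", {
  tpl <- trlocus:::with_seed(21, make_v_gene_template("VO", 21))
  clean <- check_orf(tpl$l_seq, tpl$v_seq, tpl$ref_v_length)
  expect_identical(nrow(clean$lesions), 0L)
  expect_identical(nchar(clean$translation),
                   (nchar(tpl$l_seq) + nchar(tpl$v_seq)) %/% 3L)

  # plant TAA at a known V codon and compare against scanning every codon
  for (codon in c(31L, 57L, 90L)) {
    v <- tpl$v_seq
    substr(v, 3L * codon - 2L, 3L * codon) <- "TAA"
    res <- check_orf(tpl$l_seq, v, tpl$ref_v_length)
    spliced <- paste0(tpl$l_seq, v)
    brute <- which(vapply(seq_len(nchar(spliced) %/% 3L), function(i) {
      substr(spliced, 3L * i - 2L, 3L * i) %in% c("TAA", "TAG", "TGA")
    }, logical(1)))[1]
    expect_identical(res$lesions$kind, "premature_stop")
    expect_identical(res$lesions$position, as.integer(brute))
  }
})

test_that("a 4 bp V-exon deletion is called as a frameshift", {
  tpl <- trlocus:::with_seed(22, make_v_gene_template("VF", 22))
  v <- paste0(substr(tpl$v_seq, 1, 149), substr(tpl$v_seq, 154,
                                                nchar(tpl$v_seq)))
  res <- check_orf(tpl$l_seq, v, tpl$ref_v_length)
  expect_identical(res$lesions$kind, "frameshift")
  expect_true(is.na(res$translation))
})

test_that("anchor residues are checked through the IMGT map", {
  tpl <- trlocus:::with_seed(23, make_v_gene_template("VR", 23))
  pep <- tpl$ref_peptide
  map <- imgt_position_map(pep, tpl$ref_peptide, tpl$leader_codons)
  expect_identical(nrow(check_conserved_residues(pep, map)), 0L)

  mutated <- pep
  substr(mutated, map[["C23"]], map[["C23"]]) <- "R"
  expect_identical(check_conserved_residues(mutated, map)$kind, "C23_mut")

  truncated <- substr(pep, 1, map[["C104"]] - 5L)
  map_t <- imgt_position_map(truncated, tpl$ref_peptide, tpl$leader_codons)
  res <- check_conserved_residues(truncated, map_t)
  expect_true("C104_mut" %in% res$kind)
  expect_identical(res$detail[res$kind == "C104_mut"], "unalignable")
})

test_that("RS scoring follows the CAC / 5-of-7 / 6-of-9 / spacer tolerance rules", {
  rs_ok <- paste0("CACAGTG", strrep("A", 23), "ACAAAAACC")
  expect_identical(nrow(check_rs(rs_ok, 23)), 0L)
  expect_identical(check_rs(sub("^CACAGTG", "GACAGTG", rs_ok), 23)$kind,
                   "RS_heptamer_mut")
  # spacer tolerance verified by enumerating lengths 20..26
  for (sp in 20:26) {
    rs <- paste0("CACAGTG", strrep("A", sp), "ACAAAAACC")
    lesions <- check_rs(rs, 23)
    if (abs(sp - 23) <= 1) {
      expect_identical(nrow(lesions), 0L)
    } else {
      expect_identical(lesions$kind, "RS_spacer_mut")
    }
  }
  bad_nonamer <- paste0("CACAGTG", strrep("A", 23), "GGGGTAACC")
  expect_identical(check_rs(bad_nonamer, 23)$kind, "RS_nonamer_mut")
})

test_that("missing part sequence yields incomplete, outranking other lesions", {
  tpl <- trlocus:::with_seed(24, {
    make_v_gene_template("VT", 24, plant_lesion = "truncation")
  })
  call <- classify_v_genes(template_gene_row(tpl), template_reference(tpl))
  expect_identical(call$status, "incomplete")
  expect_true("missing_sequence" %in% call$lesions[[1]]$kind)
})

test_that("a gene mapped off the locus acquires an unmapped_location lesion", {
  tpl <- trlocus:::with_seed(25, make_v_gene_template("VU", 25))
  row <- template_gene_row(tpl, location_class = "other")
  call <- classify_v_genes(row, template_reference(tpl))
  expect_identical(call$status, "pseudogene")
  expect_identical(call$lesions[[1]]$kind, "unmapped_location")
})

test_that("planted lesions are recovered exactly across the whole menu", {
  kinds <- lesion_kinds()
  reps <- 20L  # 9 kinds x 20 genes; the large-batch version runs in the
               # acceptance suite
  rows <- list(); refs <- list(); expected <- list()
  counter <- 0L
  for (kind in kinds) {
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      sg <- paste0("S", (counter %% 7L) + 1L)
      tpl <- trlocus:::with_seed(1000L + counter, {
        make_v_gene_template(sg, 5L, plant_lesion = kind)
      })
      id <- paste0("g", counter)
      rows[[counter]] <- template_gene_row(tpl, id = id)
      refs[[sg]] <- template_reference(tpl)
      expected[[id]] <- sort(tpl$lesions$kind)
    }
  }
  genes <- dplyr::bind_rows(rows)
  references <- dplyr::bind_rows(refs[!duplicated(names(refs))])
  calls <- classify_v_genes(genes, references)
  recovered <- vapply(seq_len(nrow(calls)), function(i) {
    identical(sort(calls$lesions[[i]]$kind), expected[[calls$gene_id[i]]])
  }, logical(1))
  expect_true(all(recovered))
  # status trichotomy follows from the lesions
  expect_true(all(calls$status[calls$lesion_kinds == ""] == "functional"))
  expect_true(all(calls$status[grepl("missing_sequence",
                                     calls$lesion_kinds)] == "incomplete"))
})

test_that("J classification mirrors a 52-of-62 functional repertoire", {
  cfg <- sim_config(
    subgroups = tibble::tibble(label = "VA", chain = "TRA",
                               n_ancestral = 1L, death_prob = 0),
    events = tibble::tibble(start = integer(0), end = integer(0),
                            n_copies = integer(0), subs_rate = numeric(0),
                            trunc_prob = numeric(0)),
    post_dup_deletion_prob = 0,
    n_traj = 59L, n_trdj = 3L, j_pseudo_n = 10L, rng_seed = 31
  )
  sim <- simulate_locus(cfg)
  calls <- classify_j_genes(sim$annotation)
  expect_identical(nrow(calls), 62L)
  expect_identical(sum(calls$status == "functional"), 52L)
  # lesion kinds match what was planted
  truth <- sim$truth$planted_lesions
  for (i in seq_len(nrow(calls))) {
    planted <- sort(truth$kind[truth$gene_id == calls$gene_id[i]])
    expect_identical(sort(calls$lesions[[i]]$kind), planted)
  }
  # FGxG absence alone is a pseudogene call
  tpl <- trlocus:::with_seed(3, {
    trlocus:::make_j_gene_template("JX", 3, plant_lesion = "missing_FGxG")
  })
  row <- tibble::tibble(
    gene_id = "JX", type = "J", subgroup = NA_character_, chain = "TRA",
    contig = "c1", start = 0L, end = 100L, strand = "+",
    location_class = "locus_chromosome",
    l_start = NA_integer_, l_end = NA_integer_, v_start = NA_integer_,
    v_end = NA_integer_, rs_start = NA_integer_, rs_end = NA_integer_,
    d_start = NA_integer_, d_end = NA_integer_,
    l_seq = NA_character_, intron_seq = NA_character_,
    v_seq = tpl$coding, rs_seq = tpl$rs_seq, donor_seq = tpl$donor_seq
  )
  call <- classify_j_genes(row)
  expect_identical(call$status, "pseudogene")
  expect_identical(call$lesions[[1]]$kind, "missing_FGxG")
})

test_that("catalog summary reproduces published per-subgroup accounting", {
  counts <- bovine_catalog_counts()
  calls <- counts_to_calls(counts)
  summary <- summarize_catalog(calls)
  dv1 <- summary[summary$subgroup == "TRDV1", ]
  expect_identical(dv1$total, 60L)
  expect_identical(dv1$functional, 48L)
  expect_identical(dv1$pseudogene, 8L)
  expect_identical(dv1$incomplete, 4L)
  expect_identical(dv1$pct_functional, 80.0)
  totals <- summary[summary$subgroup == "Total", ]
  expect_identical(totals$total, 371L)
  expect_identical(totals$functional, 215L)
  expect_identical(totals$pseudogene, 138L)
  expect_identical(totals$incomplete, 18L)
  expect_identical(totals$pct_functional, 58.0)
})

test_that("catalog summary handles empty input and ignores gene order", {
  empty <- summarize_catalog(tibble::tibble(subgroup = character(0),
                                            status = character(0)))
  expect_identical(empty$subgroup, "Total")
  expect_identical(empty$total, 0L)

  calls <- counts_to_calls(bovine_catalog_counts())
  shuffled <- calls[trlocus:::with_seed(4, sample(nrow(calls))), ]
  s1 <- summarize_catalog(calls)
  s2 <- summarize_catalog(shuffled)
  s2 <- s2[match(s1$subgroup, s2$subgroup), ]
  expect_equal(s1$pct_functional, s2$pct_functional)
  expect_equal(s1$total, s2$total)
  # statuses partition every subgroup's total
  expect_true(all(s1$functional + s1$pseudogene + s1$incomplete == s1$total))
})
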