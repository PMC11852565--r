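test_that("translate_and_frame picks the designed frame and shifts with prefixes", {
  nt <- germline_concat("IGHV3S66", "IGHJ4")
  tr0 <- translate_and_frame(nt)
  expect_equal(tr0$frame_offset, 0)
  expect_false(grepl("*", tr0$aa_seq, fixed = TRUE))
  expect_equal(nchar(tr0$aa_seq), nchar(nt) / 3)

  tr1 <- translate_and_frame(paste0("G", nt))
  expect_equal(tr1$frame_offset, 1)
  expect_equal(tr1$aa_seq, tr0$aa_seq)

  # stop codons early in every one of the three frames
  expect_error(translate_and_frame(strrep("TAGTTAGTTAGT", 10)), "untranslatable")
  expect_error(translate_and_frame("ACGT"), "shorter")
  expect_error(translate_and_frame(strrep("ACGB", 30)), "alphabet")
})

test_that("deduplicate partitions identical sequences and is idempotent", {
  base <- germline_concat("IGHV3S66", "IGHJ4")
  alt <- germline_concat("IGHV3S53", "IGHJ6")
  recs <- list(nanobody_record("a", base), nanobody_record("b", base),
               nanobody_record("c", alt), nanobody_record("d", alt),
               nanobody_record("e", germline_concat("IGHV3S65", "IGHJ7")))
  dd <- deduplicate(recs, "nt")
  expect_equal(dd$n_groups, 3)
  expect_setequal(dd$groups[["a"]], c("a", "b"))

  expect_equal(deduplicate(list(recs[[1]]), "aa")$n_groups, 1)

  # synonymous variants merge at aa level but not nt level
  syn <- sub("^CAG", "CAA", base)   # Q codon swap at position 1
  recs2 <- c(recs, list(nanobody_record("f", syn)))
  expect_equal(deduplicate(recs2, "nt")$n_groups, 4)
  expect_lte(deduplicate(recs2, "aa")$n_groups, deduplicate(recs2, "nt")$n_groups)
  expect_equal(deduplicate(recs2, "aa")$n_groups, 3)
})

test_that("germline assignment recovers the noiseless limit exactly", {
  rep0 <- gen_repertoire(gs_fix, 4, mutation_rate = 0, seed = 7)
  for (i in seq_along(rep0$records)) {
    r <- assign_germline(rep0$records[[i]], gs_fix)
    tr <- rep0$truth[[i]]
    expect_equal(r$germline$v_gene, tr$v_gene)
    expect_equal(r$germline$j_gene, tr$j_gene)
    expect_equal(r$germline$v_identity, 100)
    expect_equal(r$germline$v_nt_mutations, 0L)
    expect_equal(r$germline$aa_changes, 0L)
  }
})

test_that("planted substitutions are counted exactly (position-wise oracle)", {
  repm <- gen_repertoire(gs_fix, 8, mutation_rate = 0.06, seed = 21)
  for (i in seq_along(repm$records)) {
    r <- assign_germline(repm$records[[i]], gs_fix)
    tr <- repm$truth[[i]]
    expect_equal(r$germline$v_gene, tr$v_gene)
    expect_equal(r$germline$v_nt_mutations, tr$n_mutations)
    # independent oracle: compare the mutated V to its source germline,
    # base by base and residue by residue
    v_len <- nchar(gs_fix$v[[tr$v_gene]])
    got_v <- substr(r$nt_seq, 1, v_len)
    germ_v <- gs_fix$v[[tr$v_gene]]
    nt_diff <- sum(strsplit(got_v, "")[[1]] != strsplit(germ_v, "")[[1]])
    expect_equal(r$germline$v_nt_mutations, nt_diff)
    aa_got <- strsplit(translate_and_frame(paste0(got_v, "GGG"))$aa_seq, "")[[1]][1:(v_len / 3)]
    aa_germ <- strsplit(translate_and_frame(paste0(germ_v, "GGG"))$aa_seq, "")[[1]][1:(v_len / 3)]
    expect_equal(r$germline$aa_changes, sum(aa_got != aa_germ))
  }
})

test_that("a pure V+J concatenation gets a perfect call with no D", {
  r <- assign_germline(nanobody_record("vj", germline_concat("IGHV3S53", "IGHJ6")), gs_fix)
  expect_equal(r$germline$v_gene, "IGHV3S53")
  expect_equal(r$germline$j_gene, "IGHJ6")
  expect_equal(r$germline$v_nt_mutations, 0L)
  expect_equal(r$germline$aa_changes, 0L)
  expect_true(is.na(r$germline$d_gene))
})

test_that("clones without a planted D are reported D-absent, with a D when planted", {
  rep_d <- gen_repertoire(gs_fix, 10, mutation_rate = 0.02, seed = 31, d_prob = 0.5)
  for (i in seq_along(rep_d$records)) {
    r <- assign_germline(rep_d$records[[i]], gs_fix)
    tr <- rep_d$truth[[i]]
    if (is.na(tr$d_gene)) {
      expect_true(is.na(r$germline$d_gene))
    } else {
      expect_equal(r$germline$d_gene, tr$d_gene)
    }
  }
})

test_that("unalignable input raises an unassignable error", {
  junk <- nanobody_record("junk", strrep("GCA", 60))
  expect_error(assign_germline(junk, gs_fix), "unassignable")
})

test_that("lysine census splits CDR3 from the rest of the domain", {
  # framework K content is fixed by construction: IGHV3S66 carries 4 Ks
  # outside CDR3 with IGHJ4 (1 in FR2, 3 in FR3, none in J4)
  r <- assign_germline(nanobody_record("x", germline_concat("IGHV3S66", "IGHJ4")), gs_fix)
  lys <- count_lysines(r)
  expect_equal(lys$cdr3_lysines, 0)
  expect_equal(lys$non_cdr3_lysines, 4)
  expect_equal(lys$cdr3_lysines + lys$non_cdr3_lysines,
               sum(strsplit(r$aa_seq, "")[[1]] == "K"))

  # plant two K codons in the junction -> they land inside CDR3
  ntk <- paste0(gs_fix$v[["IGHV3S66"]], "AAAAAA", gs_fix$j[["IGHJ4"]])
  rk <- assign_germline(nanobody_record("k2", ntk), gs_fix)
  lysk <- count_lysines(rk)
  expect_equal(lysk$cdr3_lysines, 2)
  expect_equal(lysk$non_cdr3_lysines, 4)

  r_bare <- nanobody_record("bare", germline_concat("IGHV3S66", "IGHJ4"))
  expect_error(count_lysines(r_bare), "annotation")
})

test_that("candidate selection honours the lysine criteria and comparator", {
  # knock the FR2 lysine out of IGHV3S66 -> exactly 3 non-CDR3 lysines
  v <- gs_fix$v[["IGHV3S66"]]
  k_codon_start <- 3 * 42 + 1   # aa position 42 (0-based) is the FR2 K
  substr(v, k_codon_start, k_codon_start + 2) <- "CGT"
  r3 <- assign_germline(nanobody_record("three", paste0(v, gs_fix$j[["IGHJ4"]])), gs_fix)
  expect_equal(count_lysines(r3)$non_cdr3_lysines, 3)
  r4 <- assign_germline(nanobody_record("four", germline_concat("IGHV3S66", "IGHJ4")), gs_fix)
  rk <- assign_germline(nanobody_record("cdr3k",
          paste0(gs_fix$v[["IGHV3S66"]], "AAAAAA", gs_fix$j[["IGHJ4"]])), gs_fix)

  recs <- list(r3, r4, rk)
  sel <- select_candidates(recs, selection_criteria())  # at_least 3
  expect_setequal(vapply(sel, function(r) r$clone_id, character(1)),
                  c("three", "four"))
  sel_strict <- select_candidates(recs, selection_criteria(comparator = "strict_greater"))
  expect_setequal(vapply(sel_strict, function(r) r$clone_id, character(1)), "four")
})

test_that("gene usage tallies per segment class and percents sum to 100", {
  draws <- c(rep("IGHV3S66", 14), rep("IGHV3S53", 6))
  recs <- mapply(function(id, v) fake_called_record(id, v),
                 sprintf("c%02d", 1:20), draws, SIMPLIFY = FALSE)
  gu <- gene_usage(recs)
  vu <- gu[gu$segment == "V", ]
  expect_equal(vu$count[vu$gene == "IGHV3S66"], 14L)
  expect_equal(vu$percent[vu$gene == "IGHV3S66"], 70)
  expect_equal(vu$percent[vu$gene == "IGHV3S53"], 30)
  for (seg in unique(gu$segment)) {
    expect_lt(abs(sum(gu$percent[gu$segment == seg]) - 100), 0.2)
  }
  one <- gene_usage(list(fake_called_record("solo", "IGHV3S1")))
  expect_equal(one$percent[one$segment == "V"], 100)
})

test_that("mutation summary reports mean to one decimal with exact range", {
  r <- list(fake_called_record("a", "IGHV3S66", v_nt_mutations = 10, aa_changes = 4))
  ms <- mutation_summary(r)
  expect_equal(ms$mean, c(10.0, 4.0))
  expect_equal(ms$min, c(10L, 4L))
  expect_equal(ms$max, c(10L, 4L))
  expect_error(mutation_summary(list()), "no records")
})

test_that("identity matrix is symmetric with an exact diagonal", {
  base <- germline_concat("IGHV3S66", "IGHJ4")
  recs <- list(nanobody_record("a", base), nanobody_record("b", base),
               nanobody_record("c", germline_concat("IGHV3S53", "IGHJ6")))
  m <- identity_matrix(recs)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["a", "b"], 100)
  expect_true(all(m >= 0 & m <= 100))
})

test_that("neighbor-joining reproduces additive distances and sibling pairs", {
  # 4-leaf additive matrix built from known branch lengths
  # ((A:3,B:5):2,(C:4,D:6))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 8
  D["C", "D"] <- D["D", "C"] <- 10
  D["A", "C"] <- D["C", "A"] <- 9
  D["A", "D"] <- D["D", "A"] <- 11
  D["B", "C"] <- D["C", "B"] <- 11
  D["B", "D"] <- D["D", "B"] <- 13
  tree <- build_cladogram(100 - D)
  cd <- ape::cophenetic.phylo(tree)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-10)

  # identical sequences sit as a zero-distance sibling pair
  base <- germline_concat("IGHV3S66", "IGHJ4")
  recs <- list(nanobody_record("d9", base), nanobody_record("g7", base),
               nanobody_record("c1", germline_concat("IGHV3S53", "IGHJ6")),
               nanobody_record("f9", germline_concat("IGHV3S65", "IGHJ7")))
  tr2 <- build_cladogram(identity_matrix(recs))
  cd2 <- ape::cophenetic.phylo(tr2)
  expect_equal(cd2["d9", "g7"], 0, tolerance = 1e-10)
  expect_error(build_cladogram(matrix(100, 2, 2)), ">= 3")
})

test_that("census table integrates calls, lysines and selection", {
  repm <- gen_repertoire(gs_fix, 3, mutation_rate = 0.04, seed = 5)
  recs <- lapply(repm$records, assign_germline, germline_set = gs_fix)
  ct <- census_table(recs)
  expect_equal(nrow(ct), 3)
  expect_named(ct, c("clone", "v_gene", "d_gene", "j_gene", "v_identity",
                     "v_nt_mutations", "aa_changes", "cdr3_lysines",
                     "non_cdr3_lysines", "selected"))
  expect_equal(ct$v_nt_mutations,
               vapply(repm$truth, `[[`, integer(1), "n_mutations"),
               ignore_attr = TRUE)
})
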