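test_that("triplet extraction with one gap matches the worked example", {
  occ <- extract_motifs("CASSLGQAYEQYF", model_config(3, 1))
  expect_equal(nrow(occ), 13)
  expect_setequal(
    occ$residues,
    c("SLG", "LGQ", "GQA", "QAY", "AYE",
      "SGQ", "SLQ", "LQA", "LGA", "GAY", "GQY", "QYE", "QAE"))
  expect_setequal(occ$gap_pattern[occ$residues == "SGQ"], "2")
  expect_setequal(occ$gap_pattern[occ$residues == "SLQ"], "3")
})

test_that("short CDR3s degrade gracefully", {
  cfg <- model_config(3, 1)
  expect_equal(nrow(extract_motifs(random_cdr3(9), cfg)), 1)  # m = 3
  expect_equal(nrow(extract_motifs(random_cdr3(8), cfg)), 0)  # m = 2
  expect_error(extract_motifs("CASS*QYF", cfg), "non-canonical")
})

test_that("extraction equals the brute-force tuple oracle on random strings", {
  set.seed(11)
  for (i in 1:120) {
    cdr3 <- random_cdr3(sample(6:25, 1))
    for (case in list(c(3, 0), c(3, 1), c(3, 2), c(4, 0), c(4, 1))) {
      got <- extract_motifs(cdr3, model_config(case[1], case[2]))$residues
      expect_equal(sort(got), sort(naive_motifs(cdr3, case[1], case[2])),
                   info = paste(cdr3, case[1], case[2]))
    }
  }
})

test_that("occurrence count for size 3 / gap 1 follows the closed form", {
  set.seed(12)
  for (len in 6:25) {
    m <- len - 6
    expected <- max(0, m - 2) + 2 * max(0, m - 3)
    expect_equal(nrow(extract_motifs(random_cdr3(len), model_config(3, 1))),
                 expected)
  }
})

test_that("restricting the gap position filters gapped motifs only", {
  cfg <- model_config(3, 1, restrict_gap_to_position = 2)
  occ <- extract_motifs("CASSLGQAYEQYF", cfg)
  gapped <- occ[occ$gap_pattern != "", ]
  expect_true(all(gapped$gap_pattern == "2"))
  # contiguous motifs are always emitted
  expect_equal(sum(occ$gap_pattern == ""), 5)
})

test_that("motif counting is boolean per sequence with template weights", {
  cfg <- model_config(3, 1)
  rep <- repertoire("s", 1, c("CASSLGQAYEQYF", "CAPPSLGTTEQYF"), c(3, 1))
  tab <- build_motif_table(rep, cfg)
  expect_equal(tab$motifs$count[tab$motifs$key == "SLG"], 4)
  # a CDR3 containing the same triplet twice contributes its count once
  cdr3 <- "CASSLGQLGQQYF"  # trimmed "SLGQLGQ": LGQ occurs twice
  tab2 <- build_motif_table(repertoire("s2", 1, cdr3, 5), cfg)
  expect_equal(tab2$motifs$count[tab2$motifs$key == "LGQ"], 5)
})

test_that("relative abundances sum to one before truncation", {
  cfg <- model_config(3, 1)
  tab <- build_motif_table(repertoire("s", 1, "CASSLGQAYEQYF", 5), cfg,
                           apply_top_k = FALSE)
  expect_equal(nrow(tab$motifs), 13)
  expect_equal(tab$motifs$rel_abundance, rep(5 / 65, 13))
  expect_equal(sum(tab$motifs$rel_abundance), 1, tolerance = 1e-9)
  expect_true(all(tab$motifs$count <= tab$total))
})

test_that("motif tables are invariant to record order", {
  set.seed(13)
  seqs <- unique(replicate(15, random_cdr3(sample(10:16, 1))))
  counts <- sample(1:6, length(seqs), replace = TRUE)
  cfg <- model_config(3, 1)
  t1 <- build_motif_table(repertoire("s", 1, seqs, counts), cfg)
  ord <- sample(length(seqs))
  t2 <- build_motif_table(repertoire("s", 1, seqs[ord], counts[ord]), cfg)
  expect_identical(t1, t2)
})

test_that("keying by gap pattern splits triplets reachable both ways", {
  cdr3 <- "CASSLGLGAAQYF"  # trimmed "SLGLGA": LGA contiguous and gapped
  plain <- build_motif_table(repertoire("s", 1, cdr3, 2),
                             model_config(3, 1))
  keyed <- build_motif_table(repertoire("s", 1, cdr3, 2),
                             model_config(3, 1, key_includes_gap = TRUE))
  expect_equal(sum(plain$motifs$residues == "LGA"), 1)
  expect_gt(sum(keyed$motifs$residues == "LGA"), 1)
})

test_that("top-k truncation keeps largest counts with lexicographic ties", {
  tab <- build_motif_table(repertoire("s", 1, "CASSLGQAYEQYF", 1),
                           model_config(3, 1))
  expect_identical(truncate_top_k(tab, 65536), tab)
  # hand-built table: counts 5, 3, 1
  tab$motifs <- data.frame(key = c("AAA", "CCC", "BBB"),
                           residues = c("AAA", "CCC", "BBB"),
                           gap_pattern = "", count = c(5L, 1L, 3L),
                           rel_abundance = c(5, 1, 3) / 9,
                           stringsAsFactors = FALSE)
  tab$total <- 9L
  kept <- truncate_top_k(tab, 2)
  expect_setequal(kept$motifs$key, c("AAA", "BBB"))
  # abundances are not recomputed and total is unchanged
  expect_equal(sum(kept$motifs$rel_abundance), 8 / 9)
  expect_equal(kept$total, 9L)
  # tie at count 3: lexicographically smaller key survives
  tab$motifs$count <- c(3L, 3L, 3L)
  expect_equal(truncate_top_k(tab, 1)$motifs$key, "AAA")
})

test_that("unimplemented configuration flags are rejected at use", {
  cfg <- model_config(use_blood_frequency = TRUE)
  rep <- repertoire("s", 1, "CASSLGQAYEQYF", 1)
  expect_error(build_motif_table(rep, cfg), "not implemented")
  expect_error(build_motif_table(rep, model_config(batch_norm = TRUE)),
               "not implemented")
})
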