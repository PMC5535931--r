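test_that("a study-design manifest (7 baits, 5 IgG, 1 pan-methyl) validates", {
  man <- as_manifest(data.frame(
    sample_id = c(sprintf("ezh2_%d", 1:7), sprintf("igg_%d", 1:5), "panme"),
    antibody = c(rep("bait", 7), rep("isotype_control", 5), "pan_methyl"),
    condition = c(rep("untreated", 4), rep("treated", 3), rep("untreated", 5), "untreated"),
    pair_id = c("p1", "p2", NA, NA, "p1", "p2", NA, rep(NA, 6)),
    run_id = sprintf("r%d", c(1, 2, 3, 4, 1, 2, 5, 1:5, 5))))
  expect_s3_class(man, "apms_manifest")
  expect_equal(nrow(man), 13)
  expect_equal(sum(man$antibody == "bait"), 7)
})

test_that("manifest validation rejects malformed designs", {
  base <- data.frame(sample_id = c("a", "b"), antibody = c("bait", "isotype_control"),
                     condition = c("untreated", "untreated"), pair_id = NA,
                     run_id = "r1", stringsAsFactors = FALSE)
  expect_error(as_manifest(base[0, ]), "no samples")
  dup <- base; dup$sample_id <- c("a", "a")
  expect_error(as_manifest(dup), "duplicate sample_id: a")
  bad <- base; bad$antibody[1] <- "nanobody"
  expect_error(as_manifest(bad), "unknown antibody")
  tri <- data.frame(sample_id = c("a", "b", "c"), antibody = "bait",
                    condition = c("untreated", "treated", "untreated"),
                    pair_id = "p1", run_id = "r1")
  expect_error(as_manifest(tri), "exactly 2")
  same_cond <- tri[1:2, ]; same_cond$condition <- "untreated"
  expect_error(as_manifest(same_cond), "same condition")
  f <- tempfile(); writeLines("sample_id\tantibody\tcondition\tpair_id\trun_id", f)
  expect_error(read_manifest(f), "no samples")
})

test_that("count matrices read back in manifest order with blanks as zero", {
  man <- toy_manifest(n_u = 1, n_t = 1, n_c = 1)
  f <- tempfile(fileext = ".tsv")
  # file columns deliberately shuffled relative to manifest order (u1 t1 c1)
  writeLines(c("protein_id\tc1\tu1\tt1", "P1\t1\t5\t2", "P2\t\t0\t3"), f)
  cm <- read_count_matrix(f, man)
  expect_equal(colnames(cm), c("u1", "t1", "c1"))
  expect_equal(unname(cm["P2", ]), c(0, 3, 0))  # blank cell -> 0

  writeLines(c("protein_id\tu1", "P1\t2.5"), f)
  expect_error(read_count_matrix(f, man), "non-integer")
  writeLines(c("protein_id\tu1", "P1\t-1"), f)
  expect_error(read_count_matrix(f, man), "negative")
  writeLines(c("protein_id\tu1\tmystery", "P1\t1\t2"), f)
  expect_error(read_count_matrix(f, man), "absent from manifest: mystery")
})

test_that("peptide evidence is normalized, validated and flagged, not dropped", {
  rows <- rbind(
    ev_record("EEF1A1", "GSFKYAWVLDK", 52, "K4:me2"),
    ev_record("SUZ12", "APQKHGG-GSGK", 2, "K4:me1"),      # line-break hyphen
    ev_record("H31", "KSAPATGGVKPHR", 28, "K10:me1", stop = 41))  # span 14 vs length 13
  f <- tempfile(fileext = ".tsv")
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- read_peptide_evidence(f)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peptide_seq[2], "APQKHGGGSGK")
  expect_equal(ev$coord_consistent, c(TRUE, TRUE, FALSE))

  bad <- ev_record("X", "AKAA", 1, "K2:wobble")
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_evidence(f), "methyl state")
  off <- ev_record("X", "AKAA", 1, "K9:me1")
  write.table(off, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_evidence(f), "offset outside")
  mismatch <- ev_record("X", "AKAA", 1, "K3:me1")
  write.table(mismatch, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_evidence(f), "does not match")
})

test_that("mod annotations accept published spellings and canonicalize", {
  m <- parse_mods(c("K4: Dimethyl", "K2:me1;K5:Trimethyl", ""))
  expect_equal(m[[1]]$state, "me2")
  expect_equal(m[[2]]$state, c("me1", "me3"))
  expect_equal(nrow(m[[3]]), 0)
  expect_error(parse_mods("K4-me2"), "unparsable")
})

test_that("write_table round-trips records and orders rows deterministically", {
  set.seed(11)
  f <- tempfile(fileext = ".tsv")
  # empty result -> header-only file
  empty <- data.frame(protein_id = character(0), fold_change = numeric(0))
  write_table(empty, f)
  expect_length(readLines(f), 1)

  man <- toy_manifest(n_u = 3, n_t = 2, n_c = 2, n_pairs = 2)
  write_table(as.data.frame(man), f)
  back <- read_manifest(f)
  reord <- man[order(man$sample_id, method = "radix"), ]
  rownames(reord) <- NULL
  expect_equal(as.data.frame(back), as.data.frame(reord))

  cm <- toy_counts(man, sample.int(20, 7 * 5, replace = TRUE) - 1)
  write_table(cm, f)
  back_cm <- read_count_matrix(f, man)
  expect_equal(back_cm[rownames(cm), colnames(cm)], cm[, ], ignore_attr = TRUE)

  recs <- data.frame(protein_id = sample(LETTERS[1:6]),
                     fold_change = round(runif(6), 3),
                     verdict = sample(c("high_confidence", "rejected"), 6, TRUE))
  write_table(recs, f)
  again <- read.delim(f, colClasses = c("character", "numeric", "character"))
  expect_equal(again, recs[order(recs$protein_id), ], ignore_attr = TRUE)
})

test_that("GMT and edge-list readers validate structure", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tribosome\tP1\tP2\tP3", "T2\tsplicing\tP2\tP4"), f)
  g <- read_gmt(f)
  expect_named(g, c("T1", "T2"))
  expect_equal(g$T2, c("P2", "P4"))
  writeLines("T1\tonly-description", f)
  expect_error(read_gmt(f), "fewer than 3")

  e <- tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tweight", "P1\tP2\t1.5"), e)
  expect_equal(read_edge_list(e)$weight, 1.5)
  writeLines(c("node_a\tnode_b\tweight", "P1\tP2\t0"), e)
  expect_error(read_edge_list(e), "positive")
})
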