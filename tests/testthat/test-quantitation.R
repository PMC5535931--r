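test_that("shared peptides are excluded and identical peptide sets merge", {
  ev <- as_evidence(rbind(
    ev_record("A", "PEPTIDEK", 1, "", sample_id = "s1", n_total = 5L, n_mod = 0L),
    ev_record("A", "AAKAA", 1, "", sample_id = "s1", n_total = 3L, n_mod = 0L),
    ev_record("B", "PEPTIDEK", 1, "", sample_id = "s1", n_total = 5L, n_mod = 0L),
    ev_record("B", "CCKCC", 1, "", sample_id = "s1", n_total = 2L, n_mod = 0L)))
  grouping <- list(PEPTIDEK = c("A", "B"), AAKAA = "A", CCKCC = "B")
  ex <- compute_exclusive_counts(ev, grouping)
  # PEPTIDEK maps to two distinct groups -> contributes nowhere
  expect_equal(unname(ex["A", "s1"]), 3)
  expect_equal(unname(ex["B", "s1"]), 2)

  # identical peptide sets -> single merged group, both peptides now exclusive
  ev2 <- ev[ev$peptide_seq != "CCKCC", ]
  grouping2 <- list(PEPTIDEK = c("A", "B"), AAKAA = c("A", "B"))
  ex2 <- compute_exclusive_counts(ev2, grouping2)
  expect_equal(rownames(ex2), "A+B")
  expect_equal(unname(ex2["A+B", "s1"]), 13)

  expect_error(compute_exclusive_counts(ev, list(PEPTIDEK = "A")), "absent from grouping")
})

test_that("subsumed proteins merge into their superset group", {
  g <- group_proteins(list(p1 = c("A", "B"), p2 = "A", p3 = "A"))
  # B's peptide set {p1} is strictly inside A's {p1,p2,p3}
  expect_equal(g$A, "A+B")
  expect_equal(g$B, "A+B")
})

test_that("exclusive counts equal a brute-force recount on random instances", {
  set.seed(31)
  for (rep in 1:3) {
    proteins <- sprintf("P%02d", 1:10)
    peptides <- sprintf("PEP%02dK", 1:30)
    grouping <- lapply(stats::setNames(peptides, peptides), function(p) {
      sample(proteins, sample(1:3, 1))
    })
    ev <- do.call(rbind, lapply(seq_along(peptides), function(i) {
      ev_record(grouping[[i]][1], peptides[i], 1, "",
                sample_id = sample(c("s1", "s2"), 1),
                n_total = sample.int(10, 1), n_mod = 0L)
    }))
    ev <- as_evidence(ev)
    ex <- compute_exclusive_counts(ev, grouping)
    group_of <- group_proteins(grouping)
    # brute force: enumerate every (peptide record, group) pair
    brute <- matrix(0, nrow(ex), ncol(ex), dimnames = dimnames(ex))
    for (i in seq_len(nrow(ev))) {
      gs <- unique(unlist(group_of[grouping[[ev$peptide_seq[i]]]]))
      if (length(gs) == 1) brute[gs, ev$sample_id[i]] <- brute[gs, ev$sample_id[i]] + ev$n_total_spectra[i]
    }
    expect_equal(ex[, ], brute, ignore_attr = TRUE)
  }
})

test_that("fold change applies the 0.1 floor to group means", {
  man <- toy_manifest(n_u = 1, n_t = 1, n_c = 2)
  cm <- toy_counts(man, c(10, 10, 0, 0,
                          4, 4, 2, 2,
                          0, 0, 0, 0))
  fc <- fold_change_over_control(cm, c("u1", "t1"), c("c1", "c2"))
  expect_equal(fc$fold_change, c(100, 2, 1))
  expect_error(fold_change_over_control(cm, character(0), "c1"), "non-empty")
  expect_error(fold_change_over_control(cm, c("u1", "c1"), "c1"), "overlap")
})

test_that("fold change is monotone in bait and antitone in control counts", {
  set.seed(5)
  man <- toy_manifest(n_u = 2, n_t = 1, n_c = 2)
  for (i in 1:20) {
    vals <- sample.int(12, 5, replace = TRUE) - 1
    cm <- toy_counts(man, vals)
    base <- fold_change_over_control(cm, c("u1", "u2", "t1"), c("c1", "c2"))$fold_change
    up <- vals; up[1] <- up[1] + 1
    fc_up <- fold_change_over_control(toy_counts(man, up), c("u1", "u2", "t1"), c("c1", "c2"))$fold_change
    expect_gte(fc_up, base)
    dn <- vals; dn[4] <- dn[4] + 1
    fc_dn <- fold_change_over_control(toy_counts(man, dn), c("u1", "u2", "t1"), c("c1", "c2"))$fold_change
    expect_lte(fc_dn, base)
  }
})

test_that("exact-test p-values match the spec's worked tables", {
  man <- toy_manifest(n_u = 1, n_t = 0, n_c = 1)
  # x_bait = 5 of 100, x_ctrl = 0 of 100
  cm <- toy_counts(man, c(5, 0, 95, 100), proteins = c("hit", "rest"))
  ft <- fisher_enrichment(cm, "u1", "c1")
  expect_equal(ft$p_value[ft$protein_id == "hit"], enum_tail_p(5, 100, 0, 100))
  # no evidence at all for a protein -> p = 1
  cm0 <- toy_counts(man, c(0, 0, 10, 10), proteins = c("none", "rest"))
  expect_equal(fisher_enrichment(cm0, "u1", "c1")$p_value[1], 1)
  # identical proportions on a 20-spectrum toy: no enrichment signal
  cm_eq <- toy_counts(man, c(3, 3, 7, 7), proteins = c("even", "rest"))
  p_eq <- fisher_enrichment(cm_eq, "u1", "c1")$p_value[1]
  expect_equal(p_eq, enum_tail_p(3, 10, 3, 10))
  expect_gt(p_eq, 0.5)
  # degenerate inputs
  cm_zero <- toy_counts(man, c(0, 0, 0, 0))
  expect_error(fisher_enrichment(cm_zero, "u1", "c1"), "no spectra")
})

test_that("exact-test p-values agree with enumeration on random tables", {
  set.seed(13)
  man <- toy_manifest(n_u = 1, n_t = 0, n_c = 1)
  for (i in 1:50) {
    n_b <- sample.int(30, 1); n_c <- sample.int(30, 1)
    x_b <- sample.int(n_b + 1, 1) - 1; x_c <- sample.int(n_c + 1, 1) - 1
    if (x_b + x_c == 0 || (n_b - x_b) + (n_c - x_c) == 0) next
    cm <- toy_counts(man, c(x_b, x_c, n_b - x_b, n_c - x_c), proteins = c("P", "rest"))
    ft <- fisher_enrichment(cm, "u1", "c1")
    expect_equal(ft$p_value[ft$protein_id == "P"], enum_tail_p(x_b, n_b, x_c, n_c),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  # hand step-up: sorted p * n / rank, cumulative min from the largest
  p <- c(0.04, 0.001, 0.3, 0.02)
  expect_equal(bh_adjust(p), c(0.0533333333, 0.004, 0.3, 0.04), tolerance = 1e-9)
  # adjusted values are valid probabilities, never below the raw p, and
  # tied step-up results are fixed points
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
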