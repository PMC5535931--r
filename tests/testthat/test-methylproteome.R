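test_that("occupancy percentages and labels follow the reporting convention", {
  expect_equal(site_occupancy(7, 59), 11.9)
  expect_equal(site_occupancy(1, 8), 12.5)
  expect_true(is.na(site_occupancy(0, 0)))
  expect_equal(site_occupancy(5, 5), 100)
  # ties round half away from zero (7/32 = 21.875)
  expect_equal(site_occupancy(7, 32), 21.9)
  # integer-valued percents print without a decimal
  expect_equal(occupancy_label(c(1, 3, 0, 7), c(20, 6, 0, 59)),
               c("5% (1/20)", "50% (3/6)", "ND (0/0)", "11.9% (7/59)"))
  expect_error(site_occupancy(3, 2), "exceeds")
  expect_error(site_occupancy(-1, 2), "nonnegative")
})

test_that("absolute positions are start + offset - 1 on consistent records", {
  ev <- as_evidence(rbind(
    ev_record("eEF1A1", "GSFKYAWVLDK", 52, "K4:me2"),
    ev_record("eEF1A1", "MDSTEPPYSQKR", 155, "K11:me2"),
    ev_record("X", "KAAA", 1, "K1:me1")))
  pos <- map_absolute_position(ev)
  expect_equal(pos$position, c(55, 165, 1))
  bad <- as_evidence(ev_record("H31", "KSAPATGGVKPHR", 28, "K10:me1", stop = 41))
  expect_error(map_absolute_position(bad), "coord_consistent")
})

test_that("positions round-trip for synthetically planted sites", {
  set.seed(17)
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  for (i in 1:25) {
    len <- sample(6:25, 1)
    off <- sample.int(len, 1)
    p_abs <- sample.int(400, 1)          # plant the site at absolute position p_abs
    start <- p_abs - off + 1L
    if (start < 1) next
    seq <- paste(replace(sample(aa, len, TRUE), off, "K"), collapse = "")
    ev <- as_evidence(ev_record("P", seq, start, sprintf("K%d:me%d", off, sample(1:3, 1))))
    expect_equal(map_absolute_position(ev)$position, p_abs)
  }
})

test_that("site calling gates on probabilities inclusively and drops all-ND sites", {
  ev <- rbind(
    ev_record("A", "AKAA", 10, "K2:me1", sample_id = "s_u", n_mod = 3L, n_total = 10L),
    ev_record("A", "AKAA", 10, "K2:me1", sample_id = "s_t", n_mod = 1L, n_total = 4L),
    # exactly at the peptide gate: retained
    ev_record("B", "CKCC", 5, "K2:me2", sample_id = "s_u", n_mod = 2L, n_total = 8L,
              peptide_prob = 0.80),
    # below the peptide gate: dropped
    ev_record("C", "DKDD", 7, "K2:me3", sample_id = "s_u", n_mod = 1L, n_total = 2L,
              peptide_prob = 0.50),
    # below the protein gate: dropped
    ev_record("D", "EKEE", 9, "K2:me1", sample_id = "s_u", n_mod = 1L, n_total = 2L,
              protein_prob = 0.99),
    # no covering spectra anywhere: all-ND, dropped
    ev_record("E", "FKFF", 11, "K2:me1", sample_id = "s_u", n_mod = 0L, n_total = 0L))
  ev <- as_evidence(ev)
  conditions <- c(s_u = "untreated", s_t = "treated")
  sites <- call_methyl_sites(ev, conditions)
  expect_setequal(unique(sites$protein_id), c("A", "B"))
  a <- sites[sites$protein_id == "A", ]
  expect_equal(a$position, c(11, 11))
  expect_equal(a$occupancy_label[a$condition == "untreated"], "30% (3/10)")
  # condition with no record is completed as ND
  b <- sites[sites$protein_id == "B", ]
  expect_equal(b$occupancy_label[b$condition == "treated"], "ND (0/0)")
  expect_equal(b$position, rep(6, 2))
})

test_that("coordinate-inconsistent records never contribute to site calling", {
  ev <- as_evidence(rbind(
    ev_record("H31", "KSAPATGGVKPHR", 28, "K10:me1", stop = 41, n_mod = 1L, n_total = 6L),
    ev_record("OK", "AKAA", 1, "K2:me1", n_mod = 1L, n_total = 2L)))
  sites <- call_methyl_sites(ev)
  expect_equal(unique(sites$protein_id), "OK")
})

test_that("raising a probability gate never adds a site", {
  set.seed(23)
  st <- generate_study(simulation_config(seed = 23, n_methyl_sites = 25))
  ev <- st$evidence
  ev$peptide_prob <- round(runif(nrow(ev), 0.5, 1), 3)
  ev$protein_prob <- round(runif(nrow(ev), 0.99, 1), 5)
  key <- function(s) paste(s$protein_id, s$position, s$state)
  base <- call_methyl_sites(ev, st$manifest, protein_prob_min = 0.99, peptide_prob_min = 0.5)
  for (pp in c(0.7, 0.9)) {
    s <- call_methyl_sites(ev, st$manifest, protein_prob_min = 0.99, peptide_prob_min = pp)
    expect_true(all(key(s) %in% key(base)))
  }
  for (prp in c(0.995, 0.999)) {
    s <- call_methyl_sites(ev, st$manifest, protein_prob_min = prp, peptide_prob_min = 0.5)
    expect_true(all(key(s) %in% key(base)))
  }
})

test_that("pan-methyl enrichment is inclusive at the ratio threshold", {
  man <- toy_manifest(n_u = 1, n_t = 0, n_c = 2, n_pan = 1)
  cm <- toy_counts(man, c(0, 2, 2, 3,    # pan 3 vs IgG mean 2 -> 1.5, kept
                          0, 2, 2, 2,    # ratio 1.0, dropped
                          0, 0, 0, 1),   # 1 vs floored 0.1 -> 10, kept
                   proteins = c("edge", "flat", "rare"))
  hits <- panmethyl_enrichment(cm, man)
  expect_setequal(hits, c("edge", "rare"))
  no_pan <- toy_manifest(n_u = 1, n_t = 0, n_c = 1)
  expect_error(panmethyl_enrichment(toy_counts(no_pan, c(1, 1)), no_pan), "pan_methyl")
})

test_that("direct-substrate candidates require all three evidence streams", {
  man <- toy_manifest(n_u = 2, n_t = 2, n_c = 1, n_pan = 1)
  # runs: u1->r1, u2->r2, t1->r1, t2->r2 (helper reuses run ids across conditions)
  cm <- toy_counts(man, c(5, 4, 3, 2, 0, 8,   # detected in runs r1 and r2
                          6, 0, 0, 0, 0, 7,   # detected in run r1 only
                          0, 0, 0, 0, 0, 0),
                   proteins = c("multi", "single", "ghost"))
  sites <- data.frame(protein_id = c("multi", "single"), position = c(10, 20))
  pan <- c("multi", "single")
  out <- triangulate_targets(sites, pan, cm, man)
  expect_true(out$is_direct_candidate[out$protein_id == "multi"])
  expect_equal(out$coip_in_n_experiments[out$protein_id == "multi"], 2)
  # a called site plus pan-methyl evidence but one co-IP run is not enough
  expect_false(out$is_direct_candidate[out$protein_id == "single"])
  expect_equal(out$coip_in_n_experiments[out$protein_id == "single"], 1)
})

test_that("candidate flags equal brute-force evaluation on randomized evidence", {
  set.seed(41)
  man <- toy_manifest(n_u = 3, n_t = 2, n_c = 2, n_pan = 1)
  ids <- sprintf("P%02d", 1:30)
  cm <- count_matrix(matrix(rpois(30 * 8, 1.2), nrow = 30,
                            dimnames = list(ids, man$sample_id)))
  sites <- data.frame(protein_id = sample(ids, 12), position = 1:12)
  pan <- sample(ids, 14)
  out <- triangulate_targets(sites, pan, cm, man)
  baits <- man$sample_id[man$antibody == "bait"]
  runs <- setNames(man$run_id, man$sample_id)
  brute <- vapply(out$protein_id, function(p) {
    n_runs <- length(unique(runs[baits[cm[p, baits] > 0]]))
    n_runs >= 2 && p %in% pan && p %in% sites$protein_id
  }, TRUE)
  expect_equal(out$is_direct_candidate, unname(brute))
})
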