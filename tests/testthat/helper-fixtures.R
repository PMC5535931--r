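# Small in-code fixtures and independent oracles shared across tests.

# Manifest with n_u untreated baits, n_t treated baits, n_c IgG controls,
# optional pan-methyl sample and matched pairs (pair i = u_i with t_i).
toy_manifest <- function(n_u = 2, n_t = 2, n_c = 2, n_pan = 0, n_pairs = 0) {
  bait_u <- sprintf("u%d", seq_len(n_u))
  bait_t <- sprintf("t%d", seq_len(n_t))
  ctrl <- sprintf("c%d", seq_len(n_c))
  pan <- if (n_pan > 0) sprintf("pm%d", seq_len(n_pan)) else character(0)
  pair <- function(ids) ifelse(seq_along(ids) <= n_pairs,
                               sprintf("p%d", seq_along(ids)), NA_character_)
  as_manifest(data.frame(
    sample_id = c(bait_u, bait_t, ctrl, pan),
    antibody = c(rep("bait", n_u + n_t), rep("isotype_control", n_c),
                 rep("pan_methyl", length(pan))),
    condition = c(rep("untreated", n_u), rep("treated", n_t),
                  rep("untreated", n_c), rep("untreated", length(pan))),
    pair_id = c(pair(bait_u), pair(bait_t), rep(NA, n_c + length(pan))),
    run_id = c(sprintf("r%d", seq_len(n_u)), sprintf("r%d", seq_len(n_t)),
               sprintf("rc%d", seq_len(n_c)), rep("rp", length(pan))),
    stringsAsFactors = FALSE))
}

toy_counts <- function(manifest, values, proteins = NULL) {
  m <- matrix(values, ncol = nrow(manifest), byrow = TRUE)
  rownames(m) <- proteins %||% sprintf("P%d", seq_len(nrow(m)))
  colnames(m) <- manifest$sample_id
  count_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

ev_record <- function(protein_id, peptide_seq, start, mods, sample_id = "s1",
                      n_mod = 1L, n_total = 1L, protein_prob = 0.999,
                      peptide_prob = 0.95, stop = NULL) {
  data.frame(protein_id = protein_id, protein_prob = protein_prob,
             peptide_seq = peptide_seq, peptide_prob = peptide_prob,
             start_index = start,
             stop_index = stop %||% (start + nchar(gsub("[-*]", "", peptide_seq)) - 1L),
             mods = mods, sample_id = sample_id,
             n_mod_spectra = n_mod, n_total_spectra = n_total,
             stringsAsFactors = FALSE)
}

clique_edges <- function(ids, weight = 1) {
  pairs <- t(utils::combn(ids, 2))
  data.frame(node_a = pairs[, 1], node_b = pairs[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

# Exact upper-tail probability of a 2x2 table by explicit enumeration of the
# hypergeometric support (independent of stats::phyper / dhyper).
enum_tail_p <- function(x_bait, n_bait, x_ctrl, n_ctrl) {
  t <- x_bait + x_ctrl
  N <- n_bait + n_ctrl
  a_vals <- max(0, t - n_ctrl):min(t, n_bait)
  probs <- choose(t, a_vals) * choose(N - t, n_bait - a_vals) / choose(N, n_bait)
  sum(probs[a_vals >= x_bait])
}

# Independent Markov-clustering oracle: literal expansion/inflation iteration
# without pruning, clusters read as connected components of the limit
# matrix's support. Deliberately simpler than the package implementation.
mcl_oracle <- function(edges, inflation = 2, nodes = NULL) {
  ids <- sort(unique(c(edges$node_a, edges$node_b, nodes)))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    A[edges$node_a[i], edges$node_b[i]] <- A[edges$node_a[i], edges$node_b[i]] + edges$weight[i]
    A[edges$node_b[i], edges$node_a[i]] <- A[edges$node_b[i], edges$node_a[i]] + edges$weight[i]
  }
  loop <- apply(A, 1, max); loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:200) {
    M2 <- (M %*% M)^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  support <- (M > 1e-7) | t(M > 1e-7)
  comp <- rep(NA_integer_, length(ids))
  cur <- 0L
  for (s in seq_along(ids)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier) > 0) {
      comp[frontier] <- cur
      frontier <- setdiff(which(rowSums(support[, frontier, drop = FALSE]) > 0), which(!is.na(comp)))
    }
  }
  clusters <- lapply(seq_len(cur), function(k) sort(ids[comp == k]))
  canon_partition(clusters)
}

canon_partition <- function(clusters) {
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, "", 1L))]
}

# Random planted two-community graph on <= 12 nodes.
planted_graph <- function(seed, n1 = 5, n2 = 5, p_in = 0.9, p_out = 0.08) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n1 + n2))
  grp <- rep(1:2, c(n1, n2))
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    p <- if (grp[i] == grp[j]) p_in else p_out
    if (stats::runif(1) < p) {
      rows[[length(rows) + 1]] <- data.frame(node_a = ids[i], node_b = ids[j],
                                             weight = 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
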