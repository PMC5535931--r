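#' Spectral-count quantitation primitives
#'
#' Relative quantitation in AP-MS screens uses total spectra per protein as
#' a semi-quantitative abundance proxy; shared peptides are removed by
#' exclusive spectrum counting, fold changes over pooled IgG controls are
#' stabilised with a count floor, and candidate enrichment is screened with
#' a one-sided Fisher exact test under Benjamini-Hochberg correction.
#'
#' @name quantitation
NULL

#' Merge proteins into inference groups
#'
#' Minimal parsimony grouping needed to define exclusive counts: proteins
#' with identical peptide sets are merged into one group (id = member ids
#' joined with `+` in sorted order) and proteins whose peptide set is
#' strictly contained in another protein's set are merged into that
#' superset's group (largest superset wins; ties broken lexicographically).
#'
#' @param grouping named list: peptide sequence -> character vector of
#'   protein ids carrying that peptide.
#' @return Named list mapping each input protein id to its group id.
#' @export
group_proteins <- function(grouping) {
  proteins <- sort(unique(unlist(grouping, use.names = FALSE)))
  pep_sets <- lapply(stats::setNames(proteins, proteins), function(p) {
    sort(names(grouping)[vapply(grouping, function(ids) p %in% ids, TRUE)])
  })
  # identical peptide sets -> one group
  set_key <- vapply(pep_sets, paste, "", collapse = "\r")
  ident_group <- split(proteins, set_key)
  rep_of <- stats::setNames(rep(NA_character_, length(proteins)), proteins)
  for (members in ident_group) rep_of[members] <- members[1]
  reps <- unique(unname(rep_of))
  # strict-subset representatives absorbed into their largest superset
  absorbed_into <- stats::setNames(reps, reps)
  for (r in reps) {
    sup <- reps[vapply(reps, function(s) {
      s != r && length(pep_sets[[r]]) < length(pep_sets[[s]]) &&
        all(pep_sets[[r]] %in% pep_sets[[s]])
    }, TRUE)]
    if (length(sup) > 0) {
      sizes <- vapply(sup, function(s) length(pep_sets[[s]]), 1L)
      absorbed_into[r] <- sort(sup[sizes == max(sizes)])[1]
    }
  }
  # follow absorption chains (subset of a subset)
  resolve <- function(r) {
    seen <- character(0)
    while (absorbed_into[[r]] != r) {
      seen <- c(seen, r)
      r <- absorbed_into[[r]]
      if (r %in% seen) break
    }
    r
  }
  final_rep <- vapply(reps, resolve, "")
  members_of <- split(proteins, final_rep[rep_of[proteins]])
  group_id <- vapply(members_of, function(m) paste(sort(m), collapse = "+"), "")
  out <- stats::setNames(rep(NA_character_, length(proteins)), proteins)
  for (i in seq_along(members_of)) out[members_of[[i]]] <- group_id[i]
  as.list(out)
}

#' Exclusive spectrum counts per protein group
#'
#' Sums `n_total_spectra` over the peptides that map to exactly one protein
#' group, eliminating spectra that could belong to more than one protein.
#' Shared peptides contribute to no group.
#'
#' @param evidence `apms_evidence` records (one row per peptide per sample).
#' @param grouping named list: peptide sequence -> protein ids. Must cover
#'   every peptide in `evidence`.
#' @return An `apms_counts` matrix of kind `exclusive_spectra`, protein
#'   groups by samples.
#' @export
compute_exclusive_counts <- function(evidence, grouping) {
  peps <- unique(evidence$peptide_seq)
  absent <- setdiff(peps, names(grouping))
  if (length(absent) > 0) {
    stop_apmsq("peptide(s) absent from grouping: ", paste(utils::head(absent, 3), collapse = ", "))
  }
  group_of_protein <- group_proteins(grouping)
  groups <- sort(unique(unlist(group_of_protein, use.names = FALSE)))
  samples <- sort(unique(evidence$sample_id))
  mat <- matrix(0, nrow = length(groups), ncol = length(samples),
                dimnames = list(groups, samples))
  for (i in seq_len(nrow(evidence))) {
    pep_groups <- unique(unlist(group_of_protein[grouping[[evidence$peptide_seq[i]]]]))
    if (length(pep_groups) == 1L) {
      mat[pep_groups, evidence$sample_id[i]] <-
        mat[pep_groups, evidence$sample_id[i]] + evidence$n_total_spectra[i]
    }
  }
  count_matrix(mat, "exclusive_spectra")
}

check_sample_subsets <- function(counts, bait_samples, control_samples) {
  if (length(bait_samples) == 0 || length(control_samples) == 0) {
    stop_apmsq("bait and control sample subsets must be non-empty")
  }
  if (length(intersect(bait_samples, control_samples)) > 0) {
    stop_apmsq("bait and control sample subsets overlap")
  }
  absent <- setdiff(c(bait_samples, control_samples), colnames(counts))
  if (length(absent) > 0) {
    stop_apmsq("sample(s) absent from count matrix: ", paste(absent, collapse = ", "))
  }
}

#' Floored fold change of bait over control group means
#'
#' Per protein, the mean spectral count over the bait samples and over the
#' control samples are each floored at `floor` (default 0.1, so proteins
#' absent from the IgG controls get a finite ratio) and their ratio is the
#' fold change. Means, not sums, so unequal group sizes do not bias the
#' ratio.
#'
#' @param counts `apms_counts` matrix.
#' @param bait_samples,control_samples disjoint non-empty character vectors
#'   of column names.
#' @param floor positive detection floor applied to each group mean.
#' @return Data frame `protein_id`, `bait_mean`, `control_mean`,
#'   `fold_change`.
#' @export
fold_change_over_control <- function(counts, bait_samples, control_samples, floor = 0.1) {
  check_sample_subsets(counts, bait_samples, control_samples)
  if (!is.numeric(floor) || floor <= 0) stop_apmsq("floor must be positive")
  bait_mean <- rowMeans(counts[, bait_samples, drop = FALSE])
  control_mean <- rowMeans(counts[, control_samples, drop = FALSE])
  data.frame(protein_id = rownames(counts),
             bait_mean = bait_mean,
             control_mean = control_mean,
             fold_change = pmax(bait_mean, floor) / pmax(control_mean, floor),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided Fisher exact enrichment test per protein
#'
#' For each protein the 2x2 table contrasts its summed spectra against the
#' summed spectra of all other proteins, in the bait group versus the
#' control group. The p-value is the upper hypergeometric tail (enrichment
#' in bait); q-values are Benjamini-Hochberg adjusted across all tested
#' proteins.
#'
#' @inheritParams fold_change_over_control
#' @return Data frame `protein_id`, `x_bait`, `n_bait`, `x_control`,
#'   `n_control`, `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(counts, bait_samples, control_samples) {
  check_sample_subsets(counts, bait_samples, control_samples)
  x_bait <- rowSums(counts[, bait_samples, drop = FALSE])
  x_ctrl <- rowSums(counts[, control_samples, drop = FALSE])
  n_bait <- sum(x_bait)
  n_ctrl <- sum(x_ctrl)
  if (n_bait + n_ctrl == 0) stop_apmsq("no spectra in either group")
  if (n_bait == 0 || n_ctrl == 0) stop_apmsq("no spectra in one group")
  # P(X >= x_bait), X ~ Hypergeom drawing n_bait spectra from the pooled margin
  p <- stats::phyper(x_bait - 1, m = x_bait + x_ctrl,
                     n = (n_bait + n_ctrl) - (x_bait + x_ctrl),
                     k = n_bait, lower.tail = FALSE)
  p <- pmin(pmax(p, 0), 1)
  data.frame(protein_id = rownames(counts),
             x_bait = x_bait, n_bait = n_bait,
             x_control = x_ctrl, n_control = n_ctrl,
             p_value = p, q_value = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  assert_prob(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}
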