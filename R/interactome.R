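#' High-confidence interactome construction
#'
#' Combines floored fold change over IgG, exact-test enrichment, a
#' Poisson-mixture confidence score for the bait-prey interaction, and
#' contaminant-frequency filtering into a single verdict per protein.
#'
#' @name interactome_filter
NULL

#' Poisson-mixture confidence score for bait-prey interactions
#'
#' A self-contained probabilistic score in the spirit of SAINT-style
#' analysis. Per protein, the background rate is
#' `lambda0 = max(mean control count, floor)` and the interaction rate is
#' `lambda1 = max(mean bait count, lambda0)` (clamped so the interaction
#' component never sits below background). Each bait replicate count `x_j`
#' yields a posterior probability that it was drawn from the interaction
#' component,
#' `r_j = pi * Pois(x_j; lambda1) / (pi * Pois(x_j; lambda1) + (1 - pi) * Pois(x_j; lambda0))`,
#' and the confidence score is the mean of `r_j` over bait replicates.
#' When bait and control means agree the likelihood ratio is 1 and the
#' score equals the prior `pi`.
#'
#' @param counts `apms_counts` matrix.
#' @param manifest `apms_manifest`; bait and isotype-control samples present
#'   in `counts` are used unless subsets are given.
#' @param prior_true prior probability `pi` of a true interaction (default 0.5).
#' @param floor detection floor for the rate estimates (default 0.1).
#' @param bait_samples,control_samples optional explicit sample subsets.
#' @param lambda0,lambda1 optional fixed background/interaction rates
#'   (recycled across proteins), overriding the estimates from the count
#'   means. At fixed rates the per-replicate posterior is monotone in the
#'   count (monotone likelihood ratio); with estimated rates a changed
#'   count also moves `lambda1`.
#' @return Data frame `protein_id`, `lambda0`, `lambda1`, `confidence_score`.
#' @export
score_interactions <- function(counts, manifest, prior_true = 0.5, floor = 0.1,
                               bait_samples = NULL, control_samples = NULL,
                               lambda0 = NULL, lambda1 = NULL) {
  bait_samples <- bait_samples %||%
    intersect(manifest_samples(manifest, "bait"), colnames(counts))
  control_samples <- control_samples %||%
    intersect(manifest_samples(manifest, "isotype_control"), colnames(counts))
  if (length(bait_samples) == 0) stop_apmsq("no bait replicates to score")
  check_sample_subsets(counts, bait_samples, control_samples)
  assert_prob(prior_true, "prior_true")
  lambda0 <- rep(lambda0 %||% pmax(rowMeans(counts[, control_samples, drop = FALSE]), floor),
                 length.out = nrow(counts))
  lambda1 <- pmax(rep(lambda1 %||% pmax(rowMeans(counts[, bait_samples, drop = FALSE]), lambda0),
                      length.out = nrow(counts)), lambda0)
  xs <- counts[, bait_samples, drop = FALSE]
  num <- prior_true * stats::dpois(xs, lambda1)
  den <- num + (1 - prior_true) * stats::dpois(xs, lambda0)
  score <- rowMeans(num / den)
  data.frame(protein_id = rownames(counts),
             lambda0 = lambda0, lambda1 = lambda1,
             confidence_score = score,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag frequent contaminants
#'
#' Two-clause rule against a reference profile of control AP-MS runs: a
#' protein is flagged as a contaminant iff it is detected in more than
#' `max_frequency` of the reference control experiments AND its bait
#' abundance is not differentially enriched over the profile's expected
#' background level (floored bait mean over floored profile `mean_count`
#' below `fc_threshold`). Genuinely enriched frequent fliers therefore
#' survive; proteins absent from the profile are never flagged.
#'
#' @param records data frame with `protein_id` and `bait_mean` (e.g. the
#'   output of [fold_change_over_control()]).
#' @param profile contaminant profile data frame (see
#'   [read_contaminant_profile()]).
#' @param max_frequency detection-frequency threshold (default 0.5).
#' @param fc_threshold enrichment threshold rescuing enriched proteins
#'   (default 2).
#' @param floor detection floor (default 0.1).
#' @return `records` with a logical `contaminant_flag` column appended.
#' @export
filter_contaminants <- function(records, profile, max_frequency = 0.5,
                                fc_threshold = 2, floor = 0.1) {
  flag <- rep(FALSE, nrow(records))
  if (!is.null(profile) && nrow(profile) > 0) {
    idx <- match(records$protein_id, profile$protein_id)
    hit <- !is.na(idx)
    freq <- profile$n_detected[idx[hit]] / profile$n_experiments[idx[hit]]
    expect <- pmax(profile$mean_count[idx[hit]], floor)
    fc_vs_profile <- pmax(records$bait_mean[hit], floor) / expect
    flag[hit] <- freq > max_frequency & fc_vs_profile < fc_threshold
  }
  records$contaminant_flag <- flag
  records
}

#' Build the high-confidence bait interactome
#'
#' Composes [fold_change_over_control()], [fisher_enrichment()],
#' [score_interactions()] and [filter_contaminants()] over all bait IPs
#' versus all isotype controls, then applies the verdict rule: a protein is
#' `high_confidence` iff `fold_change >= fc_threshold` and
#' `confidence_score >= score_threshold` and it is not flagged as a
#' contaminant. Membership in an optional published-interactor reference
#' list is annotated but never gates the verdict.
#'
#' @param counts `apms_counts` matrix.
#' @param manifest `apms_manifest` with at least one bait and one
#'   isotype-control sample present in `counts`.
#' @param profile optional contaminant profile.
#' @param reference optional character vector of published interactor ids.
#' @param fc_threshold fold-change gate (default 2, the stringent
#'   interactome cut-off).
#' @param score_threshold confidence-score gate (default 0.8).
#' @param prior_true,floor passed to the component steps.
#' @param contaminant_max_frequency passed to [filter_contaminants()].
#' @return Data frame of enrichment records: `protein_id`, `bait_mean`,
#'   `control_mean`, `fold_change`, `p_value`, `q_value`,
#'   `confidence_score`, `contaminant_flag`, `n_bait_detected`,
#'   `in_reference`, `verdict`.
#' @export
build_interactome <- function(counts, manifest, profile = NULL, reference = NULL,
                              fc_threshold = 2, score_threshold = 0.8,
                              prior_true = 0.5, floor = 0.1,
                              contaminant_max_frequency = 0.5) {
  bait_samples <- intersect(manifest_samples(manifest, "bait"), colnames(counts))
  control_samples <- intersect(manifest_samples(manifest, "isotype_control"), colnames(counts))
  if (length(bait_samples) == 0 || length(control_samples) == 0) {
    stop_apmsq("interactome analysis needs >=1 bait and >=1 isotype_control sample")
  }
  fc <- fold_change_over_control(counts, bait_samples, control_samples, floor = floor)
  ft <- fisher_enrichment(counts, bait_samples, control_samples)
  sc <- score_interactions(counts, manifest, prior_true = prior_true, floor = floor,
                           bait_samples = bait_samples, control_samples = control_samples)
  rec <- fc
  rec$p_value <- ft$p_value[match(rec$protein_id, ft$protein_id)]
  rec$q_value <- ft$q_value[match(rec$protein_id, ft$protein_id)]
  rec$confidence_score <- sc$confidence_score[match(rec$protein_id, sc$protein_id)]
  rec <- filter_contaminants(rec, profile, max_frequency = contaminant_max_frequency,
                             fc_threshold = fc_threshold, floor = floor)
  rec$n_bait_detected <- rowSums(counts[, bait_samples, drop = FALSE] > 0)[match(rec$protein_id, rownames(counts))]
  rec$in_reference <- rec$protein_id %in% (reference %||% character(0))
  pass <- rec$fold_change >= fc_threshold &
    rec$confidence_score >= score_threshold &
    !rec$contaminant_flag
  rec$verdict <- ifelse(pass, "high_confidence", "rejected")
  rec
}
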