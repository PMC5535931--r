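#' Synthetic AP-MS studies with known ground truth
#'
#' Generates a complete study - manifest, spectral-count matrix, methyl
#' peptide evidence, contaminant profile and the ground truth behind them -
#' mirroring a bait-IP design with isotype controls and one pan-methyl IP,
#' so that every pipeline stage can be validated end to end without
#' external data.
#'
#' @name synthetic_data
NULL

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 4 untreated + 3 treated bait
#' IPs (2 matched biological pairs), 5 IgG controls and 1 pan-methyl IP.
#' Background counts are negative-binomial with mean `background_mean` and
#' size `dispersion` (larger size = closer to Poisson); true interactors
#' have their bait counts scaled by `interaction_effect`, condition-specific
#' interactors additionally by `condition_effect` in one condition, and
#' contaminants by `contaminant_effect` in every sample including controls.
#' Methyl-site occupancies are drawn from
#' `Beta(occupancy_alpha, occupancy_beta)` and modified spectra binomially.
#'
#' @param seed integer RNG seed.
#' @param n_proteins number of proteins.
#' @param n_true_interactors proteins truly enriched in bait IPs.
#' @param n_condition_specific subset of true interactors whose interaction
#'   changes with treatment.
#' @param n_bait_untreated,n_bait_treated,n_controls,n_pan_methyl sample
#'   counts per group.
#' @param n_pairs matched biological pairs (pair i = i-th untreated with
#'   i-th treated bait).
#' @param background_mean mean background spectral count.
#' @param dispersion negative-binomial size parameter.
#' @param interaction_effect fold elevation of true interactors in bait IPs
#'   (>= 1).
#' @param condition_effect additional fold elevation in the favoured
#'   condition (>= 1).
#' @param contaminant_fraction fraction of proteins that are frequent
#'   contaminants.
#' @param contaminant_effect fold elevation of contaminants in all samples.
#' @param n_methyl_sites number of planted methyl sites.
#' @param methyl_total_mean mean covering-spectrum count per site and
#'   condition.
#' @param occupancy_alpha,occupancy_beta Beta shape parameters for true
#'   occupancies.
#' @return Validated config list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 500L,
                              n_true_interactors = 20L,
                              n_condition_specific = 10L,
                              n_bait_untreated = 4L,
                              n_bait_treated = 3L,
                              n_controls = 5L,
                              n_pan_methyl = 1L,
                              n_pairs = 2L,
                              background_mean = 2,
                              dispersion = 8,
                              interaction_effect = 8,
                              condition_effect = 4,
                              contaminant_fraction = 0.05,
                              contaminant_effect = 5,
                              n_methyl_sites = 30L,
                              methyl_total_mean = 60,
                              occupancy_alpha = 2,
                              occupancy_beta = 8) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              n_true_interactors = as.integer(n_true_interactors),
              n_condition_specific = as.integer(n_condition_specific),
              n_bait_untreated = as.integer(n_bait_untreated),
              n_bait_treated = as.integer(n_bait_treated),
              n_controls = as.integer(n_controls),
              n_pan_methyl = as.integer(n_pan_methyl),
              n_pairs = as.integer(n_pairs),
              background_mean = background_mean, dispersion = dispersion,
              interaction_effect = interaction_effect,
              condition_effect = condition_effect,
              contaminant_fraction = contaminant_fraction,
              contaminant_effect = contaminant_effect,
              n_methyl_sites = as.integer(n_methyl_sites),
              methyl_total_mean = methyl_total_mean,
              occupancy_alpha = occupancy_alpha, occupancy_beta = occupancy_beta)
  n_contaminants <- round(cfg$contaminant_fraction * cfg$n_proteins)
  if (cfg$n_true_interactors + n_contaminants > cfg$n_proteins) {
    stop_apmsq("n_true_interactors plus contaminants exceeds n_proteins")
  }
  if (cfg$n_condition_specific > cfg$n_true_interactors) {
    stop_apmsq("n_condition_specific exceeds n_true_interactors")
  }
  if (cfg$n_pairs > min(cfg$n_bait_untreated, cfg$n_bait_treated)) {
    stop_apmsq("n_pairs exceeds the smaller bait group")
  }
  if (cfg$background_mean <= 0 || cfg$dispersion <= 0) {
    stop_apmsq("background_mean and dispersion must be positive")
  }
  if (cfg$interaction_effect < 1 || cfg$condition_effect < 1) {
    stop_apmsq("effects are fold multipliers and must be >= 1")
  }
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction > 1) {
    stop_apmsq("contaminant_fraction must be a fraction")
  }
  if (cfg$occupancy_alpha <= 0 || cfg$occupancy_beta <= 0) {
    stop_apmsq("occupancy shape parameters must be positive")
  }
  class(cfg) <- "simulation_config"
  cfg
}

random_peptide <- function(len, k_at) {
  aa <- c("A","C","D","E","F","G","H","I","L","M","N","P","Q","S","T","V","W","Y")
  s <- sample(aa, len, replace = TRUE)
  s[k_at] <- "K"
  paste(s, collapse = "")
}

#' Generate a synthetic AP-MS study
#'
#' @param config a [simulation_config()].
#' @return List with elements `manifest` (`apms_manifest`), `counts`
#'   (`apms_counts`, total spectra), `evidence` (`apms_evidence` methyl
#'   peptide records), `profile` (contaminant profile) and `truth`
#'   (`true_interactors`, `condition_specific` named direction vector,
#'   `contaminants`, `methyl_sites` with per-condition true occupancies).
#'   Identical config (including seed) gives identical output.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_apmsq("config must come from simulation_config()")
  }
  with_seed(config$seed, {
    proteins <- sprintf("PROT%04d", seq_len(config$n_proteins))
    bait_u <- sprintf("bait_untreated_%d", seq_len(config$n_bait_untreated))
    bait_t <- sprintf("bait_treated_%d", seq_len(config$n_bait_treated))
    iggs <- sprintf("igg_%d", seq_len(config$n_controls))
    pans <- if (config$n_pan_methyl > 0) sprintf("pan_methyl_%d", seq_len(config$n_pan_methyl)) else character(0)
    pair_of <- function(ids) {
      idx <- seq_along(ids)
      ifelse(idx <= config$n_pairs, sprintf("pair_%d", idx), NA_character_)
    }
    # matched pairs share an MS run; everything else gets its own run
    run_u <- ifelse(seq_along(bait_u) <= config$n_pairs,
                    sprintf("run_%d", seq_along(bait_u)),
                    sprintf("run_u%d", seq_along(bait_u)))
    run_t <- ifelse(seq_along(bait_t) <= config$n_pairs,
                    sprintf("run_%d", seq_along(bait_t)),
                    sprintf("run_t%d", seq_along(bait_t)))
    manifest <- as_manifest(data.frame(
      sample_id = c(bait_u, bait_t, iggs, pans),
      antibody = c(rep("bait", length(bait_u) + length(bait_t)),
                   rep("isotype_control", length(iggs)),
                   rep("pan_methyl", length(pans))),
      condition = c(rep("untreated", length(bait_u)), rep("treated", length(bait_t)),
                    rep(c("untreated", "treated"), length.out = length(iggs)),
                    rep("untreated", length(pans))),
      pair_id = c(pair_of(bait_u), pair_of(bait_t), rep(NA, length(iggs) + length(pans))),
      run_id = c(run_u, run_t,
                 sprintf("run_g%d", seq_along(iggs)),
                 rep("run_pan", length(pans))),
      stringsAsFactors = FALSE))

    true_ids <- sample(proteins, config$n_true_interactors)
    cond_ids <- sample(true_ids, config$n_condition_specific)
    cond_dir <- stats::setNames(sample(c("up_in_untreated", "up_in_treated"),
                                       length(cond_ids), replace = TRUE), cond_ids)
    n_contaminants <- round(config$contaminant_fraction * config$n_proteins)
    contam_ids <- sample(setdiff(proteins, true_ids), n_contaminants)

    # planted methyl sites sit on true interactors
    site_proteins <- sample(true_ids, config$n_methyl_sites, replace = TRUE)

    samples <- manifest$sample_id
    mu <- matrix(config$background_mean, nrow = length(proteins), ncol = length(samples),
                 dimnames = list(proteins, samples))
    baits <- c(bait_u, bait_t)
    mu[true_ids, baits] <- mu[true_ids, baits] * config$interaction_effect
    for (p in cond_ids) {
      up_cols <- if (cond_dir[p] == "up_in_untreated") bait_u else bait_t
      mu[p, up_cols] <- mu[p, up_cols] * config$condition_effect
    }
    mu[contam_ids, ] <- mu[contam_ids, ] * config$contaminant_effect
    if (length(pans) > 0) {
      methyl_prot <- unique(site_proteins)
      mu[methyl_prot, pans] <- config$background_mean * config$interaction_effect
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = config$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    counts <- count_matrix(counts, "total_spectra")

    # contaminant-frequency profile covering every protein
    n_ref <- 20L
    freq <- ifelse(proteins %in% contam_ids, stats::runif(length(proteins), 0.6, 1),
                   stats::runif(length(proteins), 0, 0.3))
    profile <- data.frame(
      protein_id = proteins,
      n_detected = as.integer(round(freq * n_ref)),
      n_experiments = n_ref,
      mean_count = ifelse(proteins %in% contam_ids,
                          config$background_mean * config$contaminant_effect,
                          config$background_mean),
      stringsAsFactors = FALSE)

    # methyl-peptide evidence, one record per site and condition
    ev <- NULL
    truth_sites <- NULL
    if (config$n_methyl_sites > 0) {
      len <- sample(8:20, config$n_methyl_sites, replace = TRUE)
      offset <- vapply(len, function(l) sample.int(l, 1), 1L)
      start <- sample.int(300L, config$n_methyl_sites, replace = TRUE)
      state <- sample(METHYL_STATES, config$n_methyl_sites, replace = TRUE)
      # planted (protein, position, state) keys must be distinct
      for (tries in 1:100) {
        key <- paste(site_proteins, start + offset - 1L, state)
        dup <- duplicated(key)
        if (!any(dup)) break
        start[dup] <- sample.int(300L, sum(dup), replace = TRUE)
      }
      pep <- vapply(seq_len(config$n_methyl_sites),
                    function(i) random_peptide(len[i], offset[i]), "")
      occ_u <- stats::rbeta(config$n_methyl_sites, config$occupancy_alpha, config$occupancy_beta)
      occ_t <- stats::rbeta(config$n_methyl_sites, config$occupancy_alpha, config$occupancy_beta)
      rows <- list()
      for (i in seq_len(config$n_methyl_sites)) {
        for (cond in CONDITIONS) {
          n_total <- stats::rpois(1, config$methyl_total_mean)
          occ <- if (cond == "untreated") occ_u[i] else occ_t[i]
          n_mod <- stats::rbinom(1, n_total, occ)
          sample_id <- if (cond == "untreated") bait_u[1] else bait_t[1]
          rows[[length(rows) + 1]] <- data.frame(
            protein_id = site_proteins[i], protein_prob = 0.999,
            peptide_seq = pep[i], peptide_prob = 0.95,
            start_index = start[i], stop_index = start[i] + len[i] - 1L,
            mods = paste0("K", offset[i], ":", state[i]),
            sample_id = sample_id, n_mod_spectra = n_mod,
            n_total_spectra = n_total, stringsAsFactors = FALSE)
        }
      }
      ev <- as_evidence(do.call(rbind, rows), source = "synthetic evidence")
      truth_sites <- data.frame(protein_id = site_proteins,
                                position = start + offset - 1L,
                                state = state,
                                occupancy_untreated = occ_u,
                                occupancy_treated = occ_t,
                                stringsAsFactors = FALSE)
    }

    list(manifest = manifest, counts = counts, evidence = ev, profile = profile,
         truth = list(true_interactors = sort(true_ids),
                      condition_specific = cond_dir,
                      contaminants = sort(contam_ids),
                      methyl_sites = truth_sites),
         config = config)
  })
}

#' Bundled methyl-peptide evidence example
#'
#' A small packaged evidence table from an EZH2 AP-MS study of AML cells:
#' 19 methyl-peptide observations (21 distinct sites; one multiply
#' methylated metallothionein peptide carries three) with per-condition
#' modified/total spectrum counts, transcribed with the original formatting
#' quirks (bolding asterisks removed, line-break hyphens stripped by the
#' reader, one coordinate-inconsistent histone H3.1 row retained with
#' `coord_consistent = FALSE`). Where the source named a site, that name is
#' preserved in `author_label`; computed positions are authoritative.
#'
#' @return An `apms_evidence` data frame with pooled per-condition records
#'   (`sample_id` values `pooled_untreated`, `pooled_treated`).
#' @export
methyl_evidence_example <- function() {
  path <- system.file("extdata", "methyl_evidence_example.tsv", package = "apmsq")
  read_peptide_evidence(path)
}

#' Condition mapping for [methyl_evidence_example()]
#'
#' @return Named character vector mapping the example's pooled sample ids
#'   to their conditions.
#' @export
methyl_evidence_conditions <- function() {
  c(pooled_untreated = "untreated", pooled_treated = "treated")
}
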