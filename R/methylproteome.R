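#' Methyl-site calling, occupancy and substrate triangulation
#'
#' Methylated residues are called from peptide evidence passing protein- and
#' peptide-probability gates; occupancy per condition is the fraction of
#' spectra covering the site that carry the modification; candidate direct
#' methyltransferase substrates are triangulated from three independent
#' evidence streams (co-IP with the bait in at least two experiments,
#' enrichment in a pan-methyl-lysine IP, and an identified methyl site).
#'
#' @name methylproteome
NULL

#' Site occupancy in percent
#'
#' `100 * n_mod / n_total`, rounded half away from zero to one decimal.
#' Returns `NA` (not detected) when `n_total` is zero.
#'
#' @param n_mod,n_total nonnegative integer vectors, `n_mod <= n_total`.
#' @return Numeric percentage vector (`NA` where not detected).
#' @export
site_occupancy <- function(n_mod, n_total) {
  if (any(n_mod < 0) || any(n_total < 0)) stop_apmsq("spectrum counts must be nonnegative")
  if (any(n_mod > n_total)) stop_apmsq("n_mod exceeds n_total")
  ifelse(n_total == 0, NA_real_, round_half_up(100 * n_mod / pmax(n_total, 1), 1))
}

#' Printed occupancy label
#'
#' Formats occupancy the way site tables print it: one decimal with the
#' trailing `.0` trimmed (`"50\% (3/6)"`, `"11.9\% (7/59)"`) and
#' `"ND (0/0)"` when no covering spectra were observed.
#'
#' @inheritParams site_occupancy
#' @param counts logical; append the `(n_mod/n_total)` parenthetical.
#' @return Character vector of labels.
#' @export
occupancy_label <- function(n_mod, n_total, counts = TRUE) {
  pct <- site_occupancy(n_mod, n_total)
  lab <- ifelse(is.na(pct), "ND",
                ifelse(pct == floor(pct),
                       paste0(format(floor(pct), trim = TRUE, scientific = FALSE), "%"),
                       paste0(formatC(pct, format = "f", digits = 1), "%")))
  if (counts) lab <- paste0(lab, " (", n_mod, "/", n_total, ")")
  lab
}

#' Absolute residue positions of a record's modifications
#'
#' Peptide coordinates are 1-based and inclusive with the initiator
#' methionine counted, so a modification at `offset_in_peptide` sits at
#' absolute residue `start_index + offset - 1` of the full protein.
#' Records flagged coordinate-inconsistent are refused: inspect
#' `coord_consistent` and exclude them before mapping.
#'
#' @param evidence `apms_evidence` records.
#' @return Data frame with one row per modification: `protein_id`,
#'   `peptide_seq`, `residue`, `offset`, `position`, `state`.
#' @export
map_absolute_position <- function(evidence) {
  if (any(!evidence$coord_consistent)) {
    stop_apmsq("coordinate-inconsistent evidence record(s); ",
               "filter on the coord_consistent flag before mapping positions")
  }
  mods <- parse_mods(evidence$mods)
  n <- vapply(mods, nrow, 1L)
  idx <- rep(seq_len(nrow(evidence)), n)
  m <- do.call(rbind, mods)
  data.frame(protein_id = evidence$protein_id[idx],
             peptide_seq = evidence$peptide_seq[idx],
             residue = m$residue,
             offset = m$offset,
             position = evidence$start_index[idx] + m$offset - 1L,
             state = m$state,
             stringsAsFactors = FALSE)
}

#' Call methylated residues with per-condition occupancy
#'
#' Evidence records must pass `protein_prob >= protein_prob_min` and
#' `peptide_prob >= peptide_prob_min` (both inclusive) and be
#' coordinate-consistent. Modified and total spectra are then summed per
#' (protein, position, state, condition); a site is reported with one row
#' per condition, `ND` where no covering spectra were seen, and dropped
#' entirely only if it is `ND` in every condition.
#'
#' @param evidence `apms_evidence` records.
#' @param conditions named character vector mapping `sample_id` to a
#'   condition label, or an `apms_manifest` (its `condition` column is
#'   used). Defaults to treating each distinct `sample_id` as its own
#'   condition.
#' @param protein_prob_min protein identification probability gate
#'   (default 0.999).
#' @param peptide_prob_min peptide identification probability gate
#'   (default 0.80, the permissive end of the usual 80-95\% range).
#' @param by_sample logical; additionally aggregate per sample instead of
#'   per condition (transparency view).
#' @return Data frame: `protein_id`, `residue`, `position`, `state`,
#'   `condition`, `n_mod`, `n_total`, `occupancy_percent`,
#'   `occupancy_label`.
#' @export
call_methyl_sites <- function(evidence, conditions = NULL,
                              protein_prob_min = 0.999, peptide_prob_min = 0.80,
                              by_sample = FALSE) {
  if (protein_prob_min <= 0 || protein_prob_min > 1 ||
      peptide_prob_min <= 0 || peptide_prob_min > 1) {
    stop_apmsq("probability thresholds must lie in (0, 1]")
  }
  if (inherits(conditions, "apms_manifest")) {
    conditions <- stats::setNames(conditions$condition, conditions$sample_id)
  }
  if (is.null(conditions)) {
    ids <- unique(evidence$sample_id)
    conditions <- stats::setNames(ids, ids)
  }
  unknown <- setdiff(unique(evidence$sample_id), names(conditions))
  if (length(unknown) > 0) {
    stop_apmsq("sample(s) without a condition mapping: ", paste(unknown, collapse = ", "))
  }
  keep <- evidence$coord_consistent &
    evidence$protein_prob >= protein_prob_min &
    evidence$peptide_prob >= peptide_prob_min
  ev <- evidence[keep, , drop = FALSE]
  cond_levels <- unique(unname(conditions))
  empty <- data.frame(protein_id = character(0), residue = character(0),
                      position = integer(0), state = character(0),
                      condition = character(0), n_mod = integer(0),
                      n_total = integer(0), occupancy_percent = numeric(0),
                      occupancy_label = character(0), stringsAsFactors = FALSE)
  if (nrow(ev) == 0) return(empty)

  mods <- parse_mods(ev$mods)
  n <- vapply(mods, nrow, 1L)
  idx <- rep(seq_len(nrow(ev)), n)
  if (length(idx) == 0) return(empty)
  m <- do.call(rbind, mods)
  grp_by <- if (by_sample) ev$sample_id[idx] else unname(conditions[ev$sample_id[idx]])
  long <- data.frame(protein_id = ev$protein_id[idx],
                     residue = m$residue,
                     position = ev$start_index[idx] + m$offset - 1L,
                     state = m$state,
                     condition = grp_by,
                     n_mod = ev$n_mod_spectra[idx],
                     n_total = ev$n_total_spectra[idx],
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_mod, n_total) ~ protein_id + residue + position + state + condition,
                          data = long, FUN = sum)
  # complete missing (site x condition) combinations as ND
  if (!by_sample) {
    sites <- unique(agg[, c("protein_id", "residue", "position", "state")])
    full <- merge(sites, data.frame(condition = cond_levels, stringsAsFactors = FALSE))
    agg <- merge(full, agg, all.x = TRUE,
                 by = c("protein_id", "residue", "position", "state", "condition"))
    agg$n_mod[is.na(agg$n_mod)] <- 0L
    agg$n_total[is.na(agg$n_total)] <- 0L
  }
  agg$occupancy_percent <- site_occupancy(agg$n_mod, agg$n_total)
  agg$occupancy_label <- occupancy_label(agg$n_mod, agg$n_total)
  # a site ND in every condition carries no occupancy information
  key <- paste(agg$protein_id, agg$position, agg$state)
  informative <- vapply(split(agg$n_total, key), function(x) any(x > 0), TRUE)
  agg <- agg[informative[key], , drop = FALSE]
  agg <- agg[canonical_row_order(agg[, c("protein_id", "position", "state", "condition")]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Proteins enriched in the pan-methyl IP
#'
#' Proteins with at least `ratio_min` times more counts (mean over
#' pan-methyl samples) than the floored pooled IgG-control mean. The
#' comparison is inclusive, so a ratio of exactly `ratio_min` is kept.
#'
#' @param counts `apms_counts` matrix (conventionally of kind
#'   `total_peptides`).
#' @param manifest `apms_manifest` with at least one `pan_methyl` sample.
#' @param ratio_min enrichment threshold (default 1.5).
#' @param floor detection floor applied to the IgG mean (default 0.1).
#' @return Character vector of enriched protein ids.
#' @export
panmethyl_enrichment <- function(counts, manifest, ratio_min = 1.5, floor = 0.1) {
  pan <- intersect(manifest_samples(manifest, "pan_methyl"), colnames(counts))
  controls <- intersect(manifest_samples(manifest, "isotype_control"), colnames(counts))
  if (length(pan) == 0) stop_apmsq("no pan_methyl sample in manifest/counts")
  if (length(controls) == 0) stop_apmsq("no isotype_control samples for pan-methyl comparison")
  pan_mean <- rowMeans(counts[, pan, drop = FALSE])
  igg_mean <- pmax(rowMeans(counts[, controls, drop = FALSE]), floor)
  rownames(counts)[pan_mean / igg_mean >= ratio_min]
}

#' Triangulate candidate direct methylation substrates
#'
#' A protein is a direct-substrate candidate iff all three clauses hold:
#' it co-IPs with the bait in at least two distinct MS experiments
#' (distinct `run_id`s of bait samples with count > 0), it is enriched in
#' the pan-methyl IP, and a methyl site was called for it.
#'
#' @param sites site table from [call_methyl_sites()].
#' @param panmethyl_set character vector from [panmethyl_enrichment()].
#' @param counts `apms_counts` matrix.
#' @param manifest `apms_manifest`.
#' @return Data frame: `protein_id`, `coip_in_n_experiments`,
#'   `panmethyl_enriched`, `has_called_site`, `is_direct_candidate`, one
#'   row per protein seen in any evidence stream.
#' @export
triangulate_targets <- function(sites, panmethyl_set, counts, manifest) {
  baits <- intersect(manifest_samples(manifest, "bait"), colnames(counts))
  runs <- stats::setNames(manifest$run_id, manifest$sample_id)
  universe <- sort(unique(c(rownames(counts), sites$protein_id, panmethyl_set)))
  coip <- vapply(universe, function(p) {
    if (!p %in% rownames(counts)) return(0L)
    detected <- baits[counts[p, baits] > 0]
    length(unique(runs[detected]))
  }, 1L)
  out <- data.frame(protein_id = universe,
                    coip_in_n_experiments = unname(coip),
                    panmethyl_enriched = universe %in% panmethyl_set,
                    has_called_site = universe %in% unique(sites$protein_id),
                    stringsAsFactors = FALSE)
  out$is_direct_candidate <- out$coip_in_n_experiments >= 2L &
    out$panmethyl_enriched & out$has_called_site
  out
}
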