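#' Differential-interaction cascade across a treatment condition
#'
#' Four gates applied in a fixed order to every protein, recording the
#' first failed stage:
#' \enumerate{
#'   \item \strong{igg_gate} - floored mean over all bait IPs at least
#'     `igg_fc` times the floored mean over the IgG controls (the less
#'     stringent 1.5-fold screen).
#'   \item \strong{ratio_gate} - the floored untreated-bait mean over the
#'     floored treated-bait mean changes by at least `ratio_fc` in either
#'     direction (ratio \eqn{\ge} `ratio_fc` or \eqn{\le} 1/`ratio_fc`).
#'   \item \strong{consistency_gate} - every matched biological pair with a
#'     detected direction agrees with the global direction, guarding
#'     against hits that pass the ratio gate but move oppositely in the
#'     matched runs. A pair whose floored ratio falls inside the dead zone
#'     counts as `not_detected` and does not vote.
#'   \item \strong{presence_gate} - detection (count > 0) in more than one
#'     bait sample.
#' }
#'
#' @param counts `apms_counts` matrix.
#' @param manifest `apms_manifest` with bait samples in both conditions.
#'   If it contains no matched pairs the consistency gate is skipped with a
#'   warning.
#' @param floor detection floor for all ratios (default 0.1).
#' @param igg_fc IgG-enrichment gate (default 1.5).
#' @param ratio_fc condition-change gate (default 2).
#' @param dead_zone length-2 numeric; per-pair ratios strictly inside
#'   `(dead_zone[1], dead_zone[2])` count as `not_detected`
#'   (default c(0.83, 1.2)).
#' @return Data frame with one row per protein: `protein_id`,
#'   `igg_fold_change`, `condition_ratio`, `direction`, `pair_directions`
#'   (semicolon-joined `pair:direction` labels), `consistent`,
#'   `n_samples_detected`, `verdict` (`selective`/`rejected`) and
#'   `rejection_stage` (`igg_gate`, `ratio_gate`, `consistency_gate`,
#'   `presence_gate` or `none`).
#' @export
differential_cascade <- function(counts, manifest, floor = 0.1,
                                 igg_fc = 1.5, ratio_fc = 2,
                                 dead_zone = c(0.83, 1.2)) {
  bait_u <- intersect(manifest_samples(manifest, "bait", "untreated"), colnames(counts))
  bait_t <- intersect(manifest_samples(manifest, "bait", "treated"), colnames(counts))
  controls <- intersect(manifest_samples(manifest, "isotype_control"), colnames(counts))
  if (length(bait_u) == 0 || length(bait_t) == 0) {
    stop_apmsq("differential analysis needs bait samples in both conditions")
  }
  if (length(controls) == 0) stop_apmsq("differential analysis needs isotype controls")
  baits <- c(bait_u, bait_t)

  pair_ids <- unique(stats::na.omit(manifest$pair_id[manifest$sample_id %in% baits]))
  pairs <- lapply(stats::setNames(pair_ids, pair_ids), function(pid) {
    members <- manifest[!is.na(manifest$pair_id) & manifest$pair_id == pid, ]
    list(untreated = members$sample_id[members$condition == "untreated"],
         treated = members$sample_id[members$condition == "treated"])
  })
  pairs <- pairs[vapply(pairs, function(p) {
    length(p$untreated) == 1 && length(p$treated) == 1 &&
      all(c(p$untreated, p$treated) %in% baits)
  }, TRUE)]
  if (length(pairs) == 0) {
    warning("no matched pairs among bait samples; consistency gate skipped",
            call. = FALSE)
  }

  mean_u <- apply(counts[, bait_u, drop = FALSE], 1, floored_mean, floor = floor)
  mean_t <- apply(counts[, bait_t, drop = FALSE], 1, floored_mean, floor = floor)
  mean_all <- apply(counts[, baits, drop = FALSE], 1, floored_mean, floor = floor)
  mean_igg <- apply(counts[, controls, drop = FALSE], 1, floored_mean, floor = floor)

  igg_fold_change <- mean_all / mean_igg
  condition_ratio <- mean_u / mean_t
  direction <- ifelse(condition_ratio >= ratio_fc, "up_in_untreated",
                      ifelse(condition_ratio <= 1 / ratio_fc, "up_in_treated", NA))

  pair_dir_one <- function(protein, pair) {
    xu <- max(counts[protein, pair$untreated], floor)
    xt <- max(counts[protein, pair$treated], floor)
    r <- xu / xt
    if (r > dead_zone[1] && r < dead_zone[2]) "not_detected"
    else if (r >= dead_zone[2]) "up_in_untreated"
    else "up_in_treated"
  }

  proteins <- rownames(counts)
  n_detected <- rowSums(counts[, baits, drop = FALSE] > 0)
  out <- data.frame(protein_id = proteins,
                    igg_fold_change = unname(igg_fold_change),
                    condition_ratio = unname(condition_ratio),
                    direction = unname(direction),
                    pair_directions = "",
                    consistent = NA,
                    n_samples_detected = unname(n_detected),
                    verdict = "rejected",
                    rejection_stage = "none",
                    stringsAsFactors = FALSE)

  for (i in seq_along(proteins)) {
    pdirs <- vapply(pairs, pair_dir_one, "", protein = proteins[i])
    out$pair_directions[i] <- paste(names(pdirs), pdirs, sep = ":", collapse = ";")
    voting <- pdirs[pdirs != "not_detected"]
    consistent <- if (is.na(direction[i])) NA else all(voting == direction[i])
    out$consistent[i] <- consistent
    stage <- "none"
    if (igg_fold_change[i] < igg_fc) {
      stage <- "igg_gate"
    } else if (is.na(direction[i])) {
      stage <- "ratio_gate"
    } else if (length(pairs) > 0 && !consistent) {
      stage <- "consistency_gate"
    } else if (n_detected[i] <= 1) {
      stage <- "presence_gate"
    }
    out$rejection_stage[i] <- stage
    out$verdict[i] <- if (stage == "none") "selective" else "rejected"
  }
  out
}
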