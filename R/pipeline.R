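#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place. Defaults
#' are the screen's published operating points: a 0.1 count floor, a
#' stringent 2-fold IgG gate for the interactome, a permissive 1.5-fold IgG
#' gate plus a 2-fold condition gate for the differential cascade, a 0.8
#' confidence-score cut-off, 99.9\%/80\% protein/peptide identification
#' gates for site calling, a 1.5-fold pan-methyl enrichment ratio and MCL
#' inflation 2.
#'
#' @param floor detection floor for all floored means.
#' @param interactome_fc interactome fold-change gate.
#' @param differential_igg_fc IgG gate of the differential cascade.
#' @param condition_fc condition-change gate.
#' @param score_threshold confidence-score gate.
#' @param prior_true prior for the confidence score.
#' @param protein_prob_min,peptide_prob_min identification gates for site
#'   calling.
#' @param panmethyl_ratio pan-methyl enrichment ratio.
#' @param mcl_inflation MCL inflation exponent.
#' @param contaminant_max_frequency contaminant-frequency gate.
#' @param dead_zone matched-pair direction dead zone.
#' @param seed optional integer seed recorded in the run report.
#' @return Config list of class `pipeline_config`.
#' @export
pipeline_config <- function(floor = 0.1, interactome_fc = 2,
                            differential_igg_fc = 1.5, condition_fc = 2,
                            score_threshold = 0.8, prior_true = 0.5,
                            protein_prob_min = 0.999, peptide_prob_min = 0.80,
                            panmethyl_ratio = 1.5, mcl_inflation = 2,
                            contaminant_max_frequency = 0.5,
                            dead_zone = c(0.83, 1.2), seed = NULL) {
  cfg <- list(floor = floor, interactome_fc = interactome_fc,
              differential_igg_fc = differential_igg_fc,
              condition_fc = condition_fc, score_threshold = score_threshold,
              prior_true = prior_true, protein_prob_min = protein_prob_min,
              peptide_prob_min = peptide_prob_min,
              panmethyl_ratio = panmethyl_ratio, mcl_inflation = mcl_inflation,
              contaminant_max_frequency = contaminant_max_frequency,
              dead_zone = dead_zone, seed = seed)
  thresholds <- c("floor", "interactome_fc", "differential_igg_fc", "condition_fc",
                  "score_threshold", "panmethyl_ratio", "mcl_inflation")
  for (k in thresholds) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) stop_apmsq(k, " must be positive")
  }
  for (k in c("prior_true", "protein_prob_min", "peptide_prob_min")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] > 1) {
      stop_apmsq(k, " must lie in (0, 1]")
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML with overrides
#'
#' Precedence: built-in defaults < config file < explicit overrides. The
#' resolved configuration is echoed into every run report.
#'
#' @param path optional YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @param overrides optional named list applied last.
#' @return `pipeline_config` list.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_apmsq("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(file_cfg), known)
    if (length(unknown) > 0) {
      stop_apmsq("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    args[names(file_cfg)] <- file_cfg
  }
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - interactome, differential cascade,
#' methylproteome, network clustering/enrichment - on the supplied input
#' files, writing one TSV per result plus a YAML run report carrying the
#' resolved configuration, input checksums and per-stage status. Stages
#' whose optional inputs are absent are skipped with a logged notice;
#' identical inputs and configuration produce identical outputs. A stage
#' error aborts the run, names the stage and removes partial outputs.
#'
#' @param manifest_path,counts_path required TSV inputs.
#' @param out_dir output directory (created if needed).
#' @param evidence_path optional methyl peptide evidence TSV.
#' @param profile_path optional contaminant-profile TSV.
#' @param peptide_counts_path optional total-peptide count matrix used for
#'   the pan-methyl comparison (defaults to the spectral counts).
#' @param edges_path optional interaction edge list for clustering.
#' @param gmt_path optional GMT annotation file for term enrichment.
#' @param reference_path optional file with one published interactor id per
#'   line.
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the written file paths and the run
#'   report.
#' @export
run_full_pipeline <- function(manifest_path, counts_path, out_dir,
                              evidence_path = NULL, profile_path = NULL,
                              peptide_counts_path = NULL, edges_path = NULL,
                              gmt_path = NULL, reference_path = NULL,
                              config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) stop_apmsq("config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(stage, msg) if (!quiet) message("[", stage, "] ", msg)
  fail <- function(stage, e) {
    unlink(written)
    stop_apmsq("stage '", stage, "' failed: ", conditionMessage(e))
  }
  emit <- function(records, name) {
    path <- file.path(out_dir, name)
    write_table(records, path)
    written <<- c(written, path)
    path
  }

  inputs <- c(manifest = manifest_path, counts = counts_path,
              evidence = evidence_path, profile = profile_path,
              peptide_counts = peptide_counts_path, edges = edges_path,
              gmt = gmt_path, reference = reference_path)
  stages <- list()

  manifest <- tryCatch(read_manifest(manifest_path), error = function(e) fail("input", e))
  counts <- tryCatch(read_count_matrix(counts_path, manifest), error = function(e) fail("input", e))
  profile <- if (!is.null(profile_path)) {
    tryCatch(read_contaminant_profile(profile_path), error = function(e) fail("input", e))
  }
  reference <- if (!is.null(reference_path)) {
    tryCatch(readLines(reference_path, warn = FALSE), error = function(e) fail("input", e))
  }

  # interactome
  interactome <- tryCatch(
    build_interactome(counts, manifest, profile = profile, reference = reference,
                      fc_threshold = config$interactome_fc,
                      score_threshold = config$score_threshold,
                      prior_true = config$prior_true, floor = config$floor,
                      contaminant_max_frequency = config$contaminant_max_frequency),
    error = function(e) fail("interactome", e))
  emit(interactome, "interactome.tsv")
  hc <- interactome$protein_id[interactome$verdict == "high_confidence"]
  say("interactome", paste0(length(hc), " high-confidence proteins of ", nrow(interactome)))
  stages$interactome <- "completed"

  # differential cascade
  has_both <- length(manifest_samples(manifest, "bait", "untreated")) > 0 &&
    length(manifest_samples(manifest, "bait", "treated")) > 0
  if (has_both) {
    differential <- tryCatch(
      differential_cascade(counts, manifest, floor = config$floor,
                           igg_fc = config$differential_igg_fc,
                           ratio_fc = config$condition_fc,
                           dead_zone = config$dead_zone),
      error = function(e) fail("differential", e))
    emit(differential, "differential.tsv")
    say("differential", paste0(sum(differential$verdict == "selective"), " selective proteins"))
    stages$differential <- "completed"
  } else {
    say("differential", "skipped: bait samples not present in both conditions")
    stages$differential <- "skipped"
  }

  # methylproteome
  if (!is.null(evidence_path)) {
    res <- tryCatch({
      evidence <- read_peptide_evidence(evidence_path)
      sites <- call_methyl_sites(evidence, manifest,
                                 protein_prob_min = config$protein_prob_min,
                                 peptide_prob_min = config$peptide_prob_min)
      pep_counts <- if (!is.null(peptide_counts_path)) {
        read_count_matrix(peptide_counts_path, manifest, "total_peptides")
      } else counts
      have_pan <- length(intersect(manifest_samples(manifest, "pan_methyl"),
                                   colnames(pep_counts))) > 0
      pan_set <- if (have_pan) {
        panmethyl_enrichment(pep_counts, manifest,
                             ratio_min = config$panmethyl_ratio, floor = config$floor)
      } else character(0)
      targets <- triangulate_targets(sites, pan_set, counts, manifest)
      list(sites = sites, targets = targets, have_pan = have_pan)
    }, error = function(e) fail("methylproteome", e))
    emit(res$sites, "methyl_sites.tsv")
    emit(res$targets, "candidate_targets.tsv")
    if (!res$have_pan) say("methylproteome", "no pan-methyl sample: enrichment clause empty")
    say("methylproteome", paste0(length(unique(res$sites$protein_id)), " proteins with called sites; ",
                                 sum(res$targets$is_direct_candidate), " direct candidates"))
    stages$methylproteome <- "completed"
  } else {
    say("methylproteome", "skipped: no evidence table supplied")
    stages$methylproteome <- "skipped"
  }

  # network
  if (!is.null(edges_path)) {
    res <- tryCatch({
      edges <- read_edge_list(edges_path)
      keep <- edges$node_a %in% hc & edges$node_b %in% hc
      clusters <- mcl_cluster(edges[keep, , drop = FALSE], inflation = config$mcl_inflation,
                              nodes = hc)
      cluster_df <- data.frame(
        cluster = rep(sprintf("cluster_%03d", seq_along(clusters)), lengths(clusters)),
        protein_id = unlist(clusters), stringsAsFactors = FALSE)
      enr <- NULL
      if (!is.null(gmt_path)) {
        annotations <- read_gmt(gmt_path)
        universe <- hc
        enr <- do.call(rbind, lapply(seq_along(clusters), function(i) {
          te <- term_enrichment(clusters[[i]], annotations, universe)
          cbind(cluster = sprintf("cluster_%03d", i), te, stringsAsFactors = FALSE)
        }))
      }
      list(cluster_df = cluster_df, enr = enr)
    }, error = function(e) fail("network", e))
    emit(res$cluster_df, "clusters.tsv")
    if (!is.null(res$enr)) emit(res$enr, "term_enrichment.tsv")
    say("network", paste0(length(unique(res$cluster_df$cluster)), " clusters"))
    stages$network <- "completed"
  } else {
    say("network", "skipped: no edge list supplied")
    stages$network <- "skipped"
  }

  report <- list(
    package_version = as.character(utils::packageVersion("apmsq")),
    config = unclass(config),
    inputs = lapply(as.list(inputs), function(p) unname(tools::md5sum(p))),
    stages = stages,
    outputs = basename(written))
  report_path <- file.path(out_dir, "run_report.yaml")
  yaml::write_yaml(report, report_path)
  written <- c(written, report_path)
  invisible(list(outputs = written, report = report))
}
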