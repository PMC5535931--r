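#' Sample manifests, count matrices and peptide evidence
#'
#' The pipeline starts from three post-database-search tables: a sample
#' manifest describing the immunoprecipitation (IP) design, a protein-group
#' by sample spectral-count matrix, and a peptide-evidence table carrying
#' modification annotations. All are plain UTF-8 tab-delimited files with a
#' header row.
#'
#' @name design_io
NULL

ANTIBODIES <- c("bait", "isotype_control", "pan_methyl")
CONDITIONS <- c("untreated", "treated")
METHYL_STATES <- c("me1", "me2", "me3")
COUNT_KINDS <- c("total_spectra", "exclusive_spectra", "total_peptides")

#' Construct and validate a sample manifest
#'
#' A manifest has one row per IP sample with columns `sample_id` (unique),
#' `antibody` (one of `bait`, `isotype_control`, `pan_methyl`), `condition`
#' (`untreated` or `treated`), `pair_id` (optional; a matched biological
#' pair must consist of exactly two samples with differing condition) and
#' `run_id` (the MS experiment the sample belongs to).
#'
#' @param df data frame with the columns above (`pair_id` may be `NA`).
#' @return The validated manifest, classed `apms_manifest`.
#' @export
as_manifest <- function(df) {
  req <- c("sample_id", "antibody", "condition", "run_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_apmsq("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_apmsq("manifest has no samples")
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  df$pair_id[!is.na(df$pair_id) & df$pair_id == ""] <- NA_character_
  for (col in c("sample_id", "antibody", "condition", "pair_id", "run_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop_apmsq("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  bad_ab <- setdiff(unique(df$antibody), ANTIBODIES)
  if (length(bad_ab) > 0) {
    stop_apmsq("unknown antibody value(s): ", paste(bad_ab, collapse = ", "),
               " (expected ", paste(ANTIBODIES, collapse = "/"), ")")
  }
  bad_cond <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad_cond) > 0) {
    stop_apmsq("unknown condition value(s): ", paste(bad_cond, collapse = ", "))
  }
  pairs <- split(df$condition, df$pair_id)
  for (pid in names(pairs)) {
    if (length(pairs[[pid]]) != 2L) {
      stop_apmsq("pair_id '", pid, "' occurs on ", length(pairs[[pid]]),
                 " samples; a matched pair must have exactly 2")
    }
    if (pairs[[pid]][1] == pairs[[pid]][2]) {
      stop_apmsq("pair_id '", pid, "' members share the same condition")
    }
  }
  df <- df[, c("sample_id", "antibody", "condition", "pair_id", "run_id")]
  rownames(df) <- NULL
  class(df) <- c("apms_manifest", "data.frame")
  df
}

#' Read a sample manifest from a TSV file
#'
#' @param path path to a tab-delimited file with header
#'   `sample_id, antibody, condition, pair_id, run_id`.
#' @return An `apms_manifest` data frame (see [as_manifest()]).
#' @export
read_manifest <- function(path) {
  df <- read_tsv_checked(path)
  if (nrow(df) == 0L) stop_apmsq("manifest '", path, "' contains no samples")
  as_manifest(df)
}

# Convenience selectors used across the analysis modules.
manifest_samples <- function(manifest, antibody, condition = NULL) {
  keep <- manifest$antibody %in% antibody
  if (!is.null(condition)) keep <- keep & manifest$condition %in% condition
  manifest$sample_id[keep]
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_apmsq("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "",
                    na.strings = NULL, stringsAsFactors = FALSE)
}

#' Construct a spectral-count matrix
#'
#' @param counts nonnegative integer matrix, proteins in rows (rownames set
#'   to protein-group ids), samples in columns (colnames set to sample ids).
#' @param count_kind one of `total_spectra`, `exclusive_spectra`,
#'   `total_peptides`.
#' @return The matrix with a `count_kind` attribute, classed `apms_counts`.
#' @export
count_matrix <- function(counts, count_kind = "total_spectra") {
  count_kind <- match.arg(count_kind, COUNT_KINDS)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_apmsq("count matrix needs protein rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop_apmsq("duplicate protein ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop_apmsq("duplicate sample ids in count matrix")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop_apmsq("non-numeric count value")
  if (any(storage < 0)) stop_apmsq("negative count value")
  if (any(storage != floor(storage))) stop_apmsq("non-integer count value")
  mode(counts) <- "numeric"
  attr(counts, "count_kind") <- count_kind
  class(counts) <- c("apms_counts", class(matrix()))
  counts
}

count_kind <- function(counts) attr(counts, "count_kind") %||% "total_spectra"

#' Read a protein-by-sample count matrix
#'
#' The file's first column holds protein-group ids; every remaining column
#' must be a `sample_id` present in the manifest. Columns are reordered to
#' manifest order; blank cells are read as 0 (absence of spectra, not
#' missing data).
#'
#' @param path TSV path.
#' @param manifest an `apms_manifest`.
#' @param count_kind the quantitation the file holds (see [count_matrix()]).
#' @return An `apms_counts` matrix.
#' @export
read_count_matrix <- function(path, manifest, count_kind = "total_spectra") {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop_apmsq("count matrix '", path, "' needs a protein column and >=1 sample column")
  proteins <- df[[1]]
  if (anyDuplicated(proteins)) stop_apmsq("duplicate protein id in '", path, "'")
  sample_cols <- names(df)[-1]
  unknown <- setdiff(sample_cols, manifest$sample_id)
  if (length(unknown) > 0) {
    stop_apmsq("sample column(s) absent from manifest: ", paste(unknown, collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  mat[mat == ""] <- "0"
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  num <- matrix(num, nrow = nrow(df), dimnames = list(proteins, sample_cols))
  if (anyNA(num)) stop_apmsq("non-numeric count cell in '", path, "'")
  if (any(num != floor(num))) stop_apmsq("non-integer count cell in '", path, "'")
  if (any(num < 0)) stop_apmsq("negative count cell in '", path, "'")
  ordered_cols <- intersect(manifest$sample_id, sample_cols)
  count_matrix(num[, ordered_cols, drop = FALSE], count_kind)
}

#' Normalize a peptide sequence string
#'
#' Strips the formatting characters that appear in published site tables
#' (bolding asterisks, line-break hyphens, whitespace) so that length and
#' residue checks operate on the amino-acid string itself.
#'
#' @param seq character vector of peptide sequences.
#' @return Uppercase sequences with `*`, `-` and whitespace removed.
#' @export
normalize_peptide <- function(seq) {
  toupper(gsub("[*[:space:]-]", "", seq))
}

#' Parse a modification annotation string
#'
#' Modifications are encoded `"K4:me2;K11:me1"`: residue letter, 1-based
#' offset within the peptide, and methyl state. The state may also be
#' written `Methyl`/`Dimethyl`/`Trimethyl` (case-insensitive), as in
#' published tables.
#'
#' @param mods character vector of annotation strings ("" = unmodified).
#' @return A list of data frames with columns `offset`, `residue`, `state`.
#' @export
parse_mods <- function(mods) {
  state_map <- c(me1 = "me1", me2 = "me2", me3 = "me3",
                 methyl = "me1", dimethyl = "me2", trimethyl = "me3")
  lapply(as.character(mods), function(m) {
    if (is.na(m) || !nzchar(trimws(m))) {
      return(data.frame(offset = integer(0), residue = character(0),
                        state = character(0), stringsAsFactors = FALSE))
    }
    tokens <- trimws(strsplit(m, ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    parts <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+):[[:space:]]*([A-Za-z0-9]+)$", tokens))
    bad <- vapply(parts, length, 1L) != 4L
    if (any(bad)) stop_apmsq("unparsable mod token: '", tokens[which(bad)[1]], "'")
    residue <- toupper(vapply(parts, `[`, "", 2L))
    offset <- as.integer(vapply(parts, `[`, "", 3L))
    state_raw <- tolower(vapply(parts, `[`, "", 4L))
    if (any(!state_raw %in% names(state_map))) {
      stop_apmsq("unknown methyl state in mod token: '", tokens[which(!state_raw %in% names(state_map))[1]], "'")
    }
    data.frame(offset = offset, residue = residue,
               state = unname(state_map[state_raw]), stringsAsFactors = FALSE)
  })
}

format_mods <- function(mod_list) {
  vapply(mod_list, function(m) {
    if (nrow(m) == 0L) "" else paste0(m$residue, m$offset, ":", m$state, collapse = ";")
  }, "")
}

#' Read a peptide-evidence table
#'
#' Expected columns: `protein_id`, `protein_prob`, `peptide_seq`,
#' `peptide_prob`, `start_index`, `stop_index`, `mods`, `sample_id`,
#' `n_mod_spectra`, `n_total_spectra`. Sequences are normalized with
#' [normalize_peptide()]; modification tokens are validated against the
#' normalized sequence. Records whose stated coordinates do not span the
#' sequence length (`stop - start + 1 != nchar(seq)`) are retained with
#' `coord_consistent = FALSE` rather than dropped; downstream site calling
#' excludes them.
#'
#' @param path TSV path.
#' @return A data frame of evidence records, classed `apms_evidence`.
#' @export
read_peptide_evidence <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("protein_id", "protein_prob", "peptide_seq", "peptide_prob",
           "start_index", "stop_index", "mods", "sample_id",
           "n_mod_spectra", "n_total_spectra")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_apmsq("evidence table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("protein_prob", "peptide_prob")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("start_index", "stop_index", "n_mod_spectra", "n_total_spectra")) {
    df[[col]] <- as.integer(df[[col]])
  }
  as_evidence(df, source = path)
}

#' Validate a peptide-evidence data frame
#'
#' @param df evidence records (see [read_peptide_evidence()] for columns).
#' @param source label used in error messages.
#' @return The normalized records, classed `apms_evidence`.
#' @export
as_evidence <- function(df, source = "evidence") {
  df$peptide_seq <- normalize_peptide(df$peptide_seq)
  assert_prob(df$protein_prob, "protein_prob")
  assert_prob(df$peptide_prob, "peptide_prob")
  if (any(df$n_mod_spectra < 0) || any(df$n_total_spectra < 0)) {
    stop_apmsq("negative spectrum count in ", source)
  }
  if (any(df$n_mod_spectra > df$n_total_spectra)) {
    stop_apmsq("n_mod_spectra exceeds n_total_spectra in ", source)
  }
  mod_list <- tryCatch(parse_mods(df$mods), error = function(e) {
    stop_apmsq(conditionMessage(e), " (", source, ")")
  })
  for (i in seq_len(nrow(df))) {
    m <- mod_list[[i]]
    if (nrow(m) == 0L) next
    plen <- nchar(df$peptide_seq[i])
    if (any(m$offset < 1L | m$offset > plen)) {
      stop_apmsq("row ", i, ": mod offset outside peptide in ", source)
    }
    at <- substring(df$peptide_seq[i], m$offset, m$offset)
    if (any(at != m$residue)) {
      stop_apmsq("row ", i, ": mod residue does not match peptide sequence in ", source)
    }
  }
  df$mods <- format_mods(mod_list)
  df$coord_consistent <- (df$stop_index - df$start_index + 1L) == nchar(df$peptide_seq)
  rownames(df) <- NULL
  class(df) <- c("apms_evidence", "data.frame")
  df
}

#' Read a contaminant-frequency profile
#'
#' Reference table of how often each protein appears in control AP-MS runs
#' (a CRAPome-style export): columns `protein_id`, `n_detected`,
#' `n_experiments`, `mean_count`.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_contaminant_profile <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("protein_id", "n_detected", "n_experiments", "mean_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_apmsq("contaminant profile missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$n_detected <- as.integer(df$n_detected)
  df$n_experiments <- as.integer(df$n_experiments)
  df$mean_count <- as.numeric(df$mean_count)
  if (any(df$n_experiments <= 0)) stop_apmsq("n_experiments must be positive")
  if (any(df$n_detected < 0 | df$n_detected > df$n_experiments)) {
    stop_apmsq("n_detected must lie in [0, n_experiments]")
  }
  if (any(df$mean_count < 0)) stop_apmsq("mean_count must be nonnegative")
  df
}

#' Read a GMT term-annotation file
#'
#' One term per line: term id, description, then member ids, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of member-id character vectors; term descriptions are
#'   attached as the `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_apmsq("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 3L)) {
    stop_apmsq("GMT line with fewer than 3 fields in '", path, "'")
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(terms))) stop_apmsq("duplicate term id in '", path, "'")
  attr(terms, "description") <- stats::setNames(vapply(fields, `[`, "", 2L), names(terms))
  terms
}

#' Read a weighted edge list
#'
#' @param path TSV with header `node_a`, `node_b`, `weight`.
#' @return Data frame with character node columns and numeric positive weights.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("node_a", "node_b", "weight")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_apmsq("edge list missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight) || any(df$weight <= 0)) stop_apmsq("edge weights must be positive numbers")
  df[, req]
}

#' Write a result table as TSV
#'
#' Writes any of the pipeline's tabular results (or a count matrix, which is
#' widened with a leading `protein_id` column) as a UTF-8 tab-delimited file
#' with a deterministic layout: columns in their defined order, rows sorted
#' lexicographically over all columns left to right. Re-reading the file
#' reproduces the records.
#'
#' @param records data frame or `apms_counts` matrix; an empty data frame
#'   yields a header-only file.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (inherits(records, "apms_counts") || is.matrix(records)) {
    records <- data.frame(protein_id = rownames(records),
                          as.data.frame(unclass(records), check.names = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(records)) stop_apmsq("write_table expects a data frame or count matrix")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records <- records[canonical_row_order(records), , drop = FALSE]
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_apmsq("directory does not exist: ", dir)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
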