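#' Abundance matrix container
#'
#' Wraps a proteins-or-peptides x samples matrix of non-negative reporter-ion
#' intensities, together with the quantification level and the normalization
#' state. Stage functions enforce the state machine
#' `raw -> within_plex_normalized -> bridge_scaled`.
#'
#' @param values Numeric matrix with row names (protein/peptide ids) and
#'   column names (sample ids). `NA` marks a missing value.
#' @param level `"protein"` or `"peptide"`.
#' @param state One of `"raw"`, `"within_plex_normalized"`, `"bridge_scaled"`.
#' @return An `AbundanceMatrix` object.
#' @export
abundance_matrix <- function(values, level = c("protein", "peptide"),
                             state = "raw") {
  level <- match.arg(level)
  if (!state %in% MATRIX_STATES) {
    ro_validation_error(sprintf("unknown matrix state '%s'", state))
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    ro_validation_error("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ro_validation_error("values must have row and column names")
  }
  if (anyDuplicated(rownames(values))) ro_validation_error("duplicate row ids")
  if (anyDuplicated(colnames(values))) ro_validation_error("duplicate sample ids")
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    ro_validation_error(sprintf(
      "negative abundance for '%s' in sample '%s'",
      rownames(values)[bad[1L]], colnames(values)[bad[2L]]
    ))
  }
  structure(list(values = values, level = level, state = state),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("<AbundanceMatrix> %d %ss x %d samples [%s], %d missing\n",
              nrow(x$values), x$level, ncol(x$values), x$state,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

assert_state <- function(am, state, op) {
  if (!inherits(am, "AbundanceMatrix")) {
    ro_validation_error(sprintf("%s() expects an AbundanceMatrix", op))
  }
  if (am$state != state) {
    ro_state_error(sprintf("%s() requires state '%s' but matrix is '%s'",
                           op, state, am$state))
  }
  invisible(am)
}

#' Validate a sample sheet
#'
#' A sample sheet maps TMT channels to samples: columns `sample_id`, `group`,
#' `replicate`, `plex_id`, `channel_label`, `is_pool`. Groups are restricted
#' to the five study groups (`WT`, `mdx_saline`, `uDys`, `midiDys`,
#' `fullDys`) plus `POOL`; each plex must carry exactly one pooled bridge
#' channel.
#'
#' @param sheet A data frame.
#' @return The validated sheet (invisibly usable as-is).
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "replicate", "plex_id", "channel_label", "is_pool")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    ro_schema_error(sprintf("sample sheet is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$group <- as.character(sheet$group)
  sheet$plex_id <- as.character(sheet$plex_id)
  sheet$channel_label <- as.character(sheet$channel_label)
  sheet$is_pool <- as.logical(sheet$is_pool)
  sheet$replicate <- as.integer(sheet$replicate)
  bad <- setdiff(unique(sheet$group), ALL_GROUPS)
  if (length(bad)) {
    ro_validation_error(sprintf("unknown group label(s): %s",
                                paste(bad, collapse = ", ")))
  }
  if (any(duplicated(sheet$sample_id))) ro_validation_error("duplicate sample_id in sheet")
  key <- paste(sheet$plex_id, sheet$channel_label, sep = "\r")
  if (any(duplicated(key))) {
    ro_validation_error("duplicate (plex_id, channel_label) in sheet")
  }
  if (any(xor(sheet$is_pool, sheet$group == POOL_GROUP))) {
    ro_validation_error("is_pool must be TRUE exactly for group == 'POOL'")
  }
  pools <- tapply(sheet$is_pool, sheet$plex_id, sum)
  if (any(pools != 1L)) {
    ro_validation_error(sprintf(
      "each plex must contain exactly one POOL sample (got: %s)",
      paste(sprintf("%s=%d", names(pools), pools), collapse = ", ")
    ))
  }
  if (any(!sheet$is_pool & (is.na(sheet$replicate) | sheet$replicate < 1L))) {
    ro_validation_error("replicate must be an integer >= 1 for study samples")
  }
  sheet
}

#' Read a sample sheet from TSV
#'
#' @param path Path to a tab-separated sheet with columns `sample_id`,
#'   `group`, `replicate`, `plex_id`, `channel_label`, `is_pool`.
#' @return Validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) ro_io_error(sprintf("sample sheet not found: %s", path))
  sheet <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = "")
  validate_sample_sheet(sheet)
}

#' Read a wide abundance table plus its sample sheet
#'
#' Ingests Proteome-Discoverer-style wide exports: first column is the row
#' identifier, remaining columns are one TMT channel each. Columns are
#' reordered to sheet order; empty cells become missing values.
#'
#' @param table_path Path to the wide TSV abundance table.
#' @param sheet_path Path to the sample sheet TSV.
#' @param level `"protein"` or `"peptide"`.
#' @return A list with elements `matrix` (an [abundance_matrix()], state
#'   `"raw"`) and `sheet` (validated sample sheet).
#' @export
read_abundance <- function(table_path, sheet_path, level = "protein") {
  sheet <- read_sample_sheet(sheet_path)
  if (!file.exists(table_path)) ro_io_error(sprintf("table not found: %s", table_path))
  tab <- read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "",
                    colClasses = "character")
  if (ncol(tab) < 2L) ro_schema_error("abundance table needs an id column plus samples")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) ro_validation_error("duplicate row ids in abundance table")
  sample_cols <- names(tab)[-1L]
  extra <- setdiff(sample_cols, sheet$sample_id)
  missing_cols <- setdiff(sheet$sample_id, sample_cols)
  if (length(extra) || length(missing_cols)) {
    ro_schema_error(sprintf(
      "table/sheet sample mismatch%s%s",
      if (length(extra)) sprintf("; in table only: %s", paste(extra, collapse = ", ")) else "",
      if (length(missing_cols)) sprintf("; in sheet only: %s", paste(missing_cols, collapse = ", ")) else ""
    ))
  }
  vals <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals),
                                     dimnames = list(ids, sheet$sample_id)))
  bad <- is.na(storage) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    ro_validation_error(sprintf("non-numeric value '%s' for '%s' in sample '%s'",
                                vals[idx[1L], idx[2L]], ids[idx[1L]],
                                sheet$sample_id[idx[2L]]))
  }
  list(matrix = abundance_matrix(storage, level = level, state = "raw"),
       sheet = sheet)
}

#' Write a data frame (or AbundanceMatrix) as TSV
#'
#' Missing values are rendered as empty strings; output is UTF-8 with a
#' header row and no quoting, so `read(write(x))` round-trips.
#'
#' @param rows A data frame, or an `AbundanceMatrix` (written with an `id`
#'   first column).
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  if (inherits(rows, "AbundanceMatrix")) {
    rows <- data.frame(id = rownames(rows$values), rows$values,
                       check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(rows)) ro_validation_error("write_table() expects a data frame")
  # render doubles at full precision so read(write(x)) is bit-for-bit
  for (j in seq_along(rows)) {
    if (is.double(rows[[j]])) {
      col <- rows[[j]]
      rows[[j]] <- ifelse(is.na(col), NA_character_, sprintf("%.17g", col))
    }
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) ro_io_error(sprintf("directory does not exist: %s", dirname(path)))
  tryCatch(
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8"),
    error = function(e) ro_io_error(sprintf("cannot write %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read a generic TSV written by [write_table()]
#'
#' @param path Input path.
#' @return A data frame; empty cells are `NA`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) ro_io_error(sprintf("file not found: %s", path))
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = "")
}

#' Run configuration
#'
#' Bundles the analysis cutoffs: the DEP thresholds (minimum corrected
#' p-value 0.05, minimum absolute log2 fold change 1, i.e. two-fold), the
#' Grubbs outlier level, the minimum peptides per protein, and the pairwise
#' contrasts to test (defaults to the ten group pairs of the study design).
#'
#' @param fc_cutoff_log2 Minimum absolute log2 fold change for a DEP call.
#' @param q_cutoff Maximum BH-adjusted p-value for a DEP call.
#' @param grubbs_alpha Significance level of the Grubbs single-outlier test.
#' @param min_peptides Minimum number of peptides for a protein to be kept.
#' @param contrasts List of length-2 character vectors `c(A, B)`; fold
#'   changes are reported as A over B.
#' @param seed Integer seed recorded in output manifests.
#' @return A `RunConfig` list.
#' @export
run_config <- function(fc_cutoff_log2 = 1, q_cutoff = 0.05,
                       grubbs_alpha = 0.05, min_peptides = 2L,
                       contrasts = default_contrasts(), seed = 1L) {
  if (!is.numeric(fc_cutoff_log2) || fc_cutoff_log2 <= 0) {
    ro_config_error("fc_cutoff_log2 must be > 0")
  }
  if (!is.numeric(q_cutoff) || q_cutoff <= 0 || q_cutoff >= 1) {
    ro_config_error("q_cutoff must be in (0, 1)")
  }
  if (!is.numeric(grubbs_alpha) || grubbs_alpha <= 0 || grubbs_alpha >= 1) {
    ro_config_error("grubbs_alpha must be in (0, 1)")
  }
  if (!is.numeric(min_peptides) || min_peptides < 0) {
    ro_config_error("min_peptides must be >= 0")
  }
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% STUDY_GROUPS)) {
      ro_config_error(sprintf("invalid contrast: %s", paste(ct, collapse = ":")))
    }
  }
  structure(list(
    fc_cutoff_log2 = as.numeric(fc_cutoff_log2),
    q_cutoff = as.numeric(q_cutoff),
    grubbs_alpha = as.numeric(grubbs_alpha),
    min_peptides = as.integer(min_peptides),
    contrasts = contrasts,
    seed = as.integer(seed)
  ), class = "RunConfig")
}

#' The ten pairwise contrasts of the study design
#'
#' Disease effect (mdx vs WT), each treatment vs WT, each treatment vs
#' untreated mdx, and treatment-vs-treatment comparisons.
#'
#' @return List of length-2 character vectors.
#' @export
default_contrasts <- function() {
  list(
    c("mdx_saline", "WT"),
    c("uDys", "WT"), c("midiDys", "WT"), c("fullDys", "WT"),
    c("mdx_saline", "uDys"), c("mdx_saline", "midiDys"), c("mdx_saline", "fullDys"),
    c("uDys", "midiDys"), c("uDys", "fullDys"), c("midiDys", "fullDys")
  )
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; contrasts are given as `"A:B"` strings.
#'
#' @param path Path to a JSON file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ro_io_error(sprintf("config not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("fc_cutoff_log2", "q_cutoff", "grubbs_alpha", "min_peptides",
             "contrasts", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    ro_config_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$contrasts)) {
    raw$contrasts <- lapply(raw$contrasts, function(s) strsplit(s, ":", fixed = TRUE)[[1L]])
  }
  do.call(run_config, raw)
}
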