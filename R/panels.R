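#' Classify construct peptides into discrimination panels
#'
#' Digests every construct under identical settings and assigns each peptide
#' to one named panel by set predicates over its construct membership:
#' \describe{
#'   \item{PAN}{in the digest of every construct.}
#'   \item{FULL_ONLY}{in at least one full-size construct, in no micro or
#'     midi construct — the "full-length only" peptides.}
#'   \item{TRANSGENIC_SHARED}{in every transgenic construct and in no
#'     endogenous construct — reports transgene expression regardless of
#'     construct size.}
#'   \item{LARGE_ONLY}{in at least one midi or full construct and in no
#'     micro construct — excludes the micro-dystrophin.}
#'   \item{OTHER}{everything else.}
#' }
#' Precedence PAN > FULL_ONLY > TRANSGENIC_SHARED > LARGE_ONLY > OTHER makes
#' the panels pairwise disjoint and exhaustive. Membership is digest-based:
#' a peptide belongs to a construct iff it appears in that construct's
#' tryptic digest at these settings, so peptides spanning a deletion
#' junction are specific to the shortened construct.
#'
#' @param constructs Named list of [construct_sequence()] objects; at least
#'   one must have `size_class == "full"`.
#' @param settings A [digest_settings()] object.
#' @return A `PeptideClassMap`: list with `membership` (named list, peptide
#'   -> character vector of construct ids), `panels` (named list of peptide
#'   character vectors), `panel_of` (named character vector), `settings`.
#' @export
classify_peptides <- function(constructs, settings = digest_settings()) {
  constructs <- validate_construct_set(constructs)
  size_class <- vapply(constructs, `[[`, character(1L), "size_class")
  origin <- vapply(constructs, `[[`, character(1L), "origin")
  if (!any(size_class == "full")) {
    ro_config_error("construct set must include at least one full-size construct")
  }
  digests <- lapply(constructs, function(cs) digest_peptides(cs$sequence, settings))
  peptides <- sort(unique(unlist(digests, use.names = FALSE)))
  member <- vapply(digests, function(d) peptides %in% d, logical(length(peptides)))
  if (length(peptides) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(digests)))
  full_ids <- size_class == "full"
  small_ids <- size_class %in% c("micro", "midi")
  micro_ids <- size_class == "micro"
  large_ids <- size_class %in% c("midi", "full")
  transgenic_ids <- origin == "transgenic"
  endogenous_ids <- origin == "endogenous"

  in_any <- function(sel) if (any(sel)) rowSums(member[, sel, drop = FALSE]) > 0 else rep(FALSE, length(peptides))
  in_all <- function(sel) if (any(sel)) rowSums(member[, sel, drop = FALSE]) == sum(sel) else rep(TRUE, length(peptides))

  pan <- in_all(rep(TRUE, length(constructs)))
  full_only <- in_any(full_ids) & !in_any(small_ids)
  transgenic_shared <- in_all(transgenic_ids) & any(transgenic_ids) & !in_any(endogenous_ids)
  large_only <- in_any(large_ids) & !in_any(micro_ids)

  panel_of <- rep("OTHER", length(peptides))
  panel_of[large_only] <- "LARGE_ONLY"
  panel_of[transgenic_shared] <- "TRANSGENIC_SHARED"
  panel_of[full_only] <- "FULL_ONLY"
  panel_of[pan] <- "PAN"
  names(panel_of) <- peptides

  membership <- lapply(seq_along(peptides), function(i) names(constructs)[member[i, ]])
  names(membership) <- peptides
  panel_names <- c("PAN", "FULL_ONLY", "TRANSGENIC_SHARED", "LARGE_ONLY", "OTHER")
  panels <- lapply(panel_names, function(p) peptides[panel_of == p])
  names(panels) <- panel_names
  structure(list(membership = membership, panels = panels,
                 panel_of = panel_of, settings = settings),
            class = "PeptideClassMap")
}

#' @export
print.PeptideClassMap <- function(x, ...) {
  sizes <- vapply(x$panels, length, integer(1L))
  cat("<PeptideClassMap>", sum(sizes), "peptides:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Panel-level quantification
#'
#' Per sample, the panel abundance is the arithmetic mean of the panel's
#' peptide abundances, skipping missing values (all-missing gives a missing
#' panel value). With a sample sheet, group mean and SEM over study samples
#' are also reported. Panel peptides absent from the matrix are reported,
#' never silently dropped.
#'
#' @param matrix A peptide-level [abundance_matrix()].
#' @param class_map A [classify_peptides()] result.
#' @param panel Panel name, e.g. `"TRANSGENIC_SHARED"`.
#' @param sheet Optional sample sheet for per-group summaries.
#' @return List with `sample_abundance` (named numeric vector),
#'   `group_summary` (data frame `group`, `mean`, `sem`, `n` or `NULL`),
#'   and `absent` (panel peptides missing from the matrix).
#' @export
quantify_panel <- function(matrix, class_map, panel, sheet = NULL) {
  if (!inherits(matrix, "AbundanceMatrix") || matrix$level != "peptide") {
    ro_validation_error("quantify_panel() expects a peptide-level AbundanceMatrix")
  }
  if (!panel %in% names(class_map$panels)) {
    ro_config_error(sprintf("unknown panel '%s'", panel))
  }
  peptides <- class_map$panels[[panel]]
  if (!length(peptides)) ro_validation_error(sprintf("panel '%s' is empty", panel))
  present <- intersect(peptides, rownames(matrix$values))
  absent <- setdiff(peptides, present)
  if (!length(present)) {
    ro_validation_error(sprintf("no '%s' panel peptides present in the matrix", panel))
  }
  sub <- matrix$values[present, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  sample_abundance <- colSums(sub, na.rm = TRUE) / n_obs
  sample_abundance[n_obs == 0] <- NA_real_
  group_summary <- NULL
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    study <- sheet[!sheet$is_pool, , drop = FALSE]
    vals <- sample_abundance[study$sample_id]
    group_summary <- do.call(rbind, lapply(split(vals, study$group), function(v) {
      v <- v[!is.na(v)]
      data.frame(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
    }))
    group_summary <- data.frame(group = rownames(group_summary), group_summary,
                                row.names = NULL, stringsAsFactors = FALSE)
    group_summary <- group_summary[order(match(group_summary$group, STUDY_GROUPS)), ]
    rownames(group_summary) <- NULL
  }
  list(sample_abundance = sample_abundance, group_summary = group_summary,
       absent = absent)
}
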