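with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    ro_stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
            "restoromics_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: within-plex normalization, pooled-
#' missing exclusion, bridge scaling, Grubbs outlier exclusion, optional
#' minimum-peptide filtering, differential expression for every configured
#' contrast, and restoration classification for the three treatments. All
#' tables are written as TSV under `out_dir` together with a JSON manifest
#' (package version, seed, parameters, exclusion counts). Output is
#' deterministic given inputs and configuration — reruns are byte
#' identical.
#'
#' @param matrix A protein-level [abundance_matrix()] in state `"raw"`, or
#'   a path to a wide TSV.
#' @param sheet A sample sheet data frame, or a path to a sheet TSV.
#' @param cfg A [run_config()].
#' @param peptide_counts Optional named vector of peptides per protein for
#'   the minimum-peptide filter; `NULL` skips the filter.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and returns the results only.
#' @return Invisibly, a list: `matrix` (processed), `exclusions`,
#'   `dep` (named list of DEP tables), `restoration` (calls), `summary`
#'   (restoration summary), `manifest`.
#' @export
run_pipeline <- function(matrix, sheet, cfg = run_config(),
                         peptide_counts = NULL, out_dir = NULL) {
  if (is.character(matrix)) {
    loaded <- with_stage("read", read_abundance(matrix, sheet))
    matrix <- loaded$matrix
    sheet <- loaded$sheet
  } else if (is.character(sheet)) {
    sheet <- with_stage("read", read_sample_sheet(sheet))
  }
  sheet <- with_stage("read", validate_sample_sheet(sheet))

  exclusions <- list()
  am <- with_stage("normalize_within_plex", normalize_within_plex(matrix, sheet))
  fp <- with_stage("filter_pooled_missing", filter_pooled_missing(am, sheet))
  am <- fp$matrix
  exclusions$pooled_missing <- fp$excluded
  am <- with_stage("bridge_scale", bridge_scale(am, sheet))
  gr <- with_stage("grubbs", apply_grubbs(am, sheet, cfg$grubbs_alpha))
  am <- gr$matrix
  exclusions$grubbs <- gr$ledger
  if (!is.null(peptide_counts)) {
    mp <- with_stage("filter_min_peptides",
                     filter_min_peptides(am, peptide_counts, cfg$min_peptides))
    am <- mp$matrix
    exclusions$min_peptides <- mp$excluded
  }

  deps <- with_stage("differential_stats", {
    out <- lapply(cfg$contrasts, function(ct) dep_table(am, sheet, ct, cfg))
    names(out) <- vapply(cfg$contrasts, paste, character(1L), collapse = "_vs_")
    out
  })

  restoration <- with_stage("restoration", {
    need <- function(a, b) {
      key <- sprintf("%s_vs_%s", a, b)
      if (!is.null(deps[[key]])) return(deps[[key]])
      rkey <- sprintf("%s_vs_%s", b, a)
      if (!is.null(deps[[rkey]])) return(dep_reverse(deps[[rkey]]))
      dep_table(am, sheet, c(a, b), cfg)
    }
    base <- need("mdx_saline", "WT")
    calls <- lapply(TREATMENT_GROUPS, function(trt) {
      classify_restoration(base, need(trt, "WT"), need(trt, "mdx_saline"), trt)
    })
    do.call(rbind, calls)
  })
  summary_tab <- restoration_summary(restoration)
  summary_strict <- restoration_summary(restoration, strict = TRUE)

  manifest <- list(
    package = "restoromics",
    version = as.character(packageVersion("restoromics")),
    seed = cfg$seed,
    parameters = list(
      fc_cutoff_log2 = cfg$fc_cutoff_log2, q_cutoff = cfg$q_cutoff,
      grubbs_alpha = cfg$grubbs_alpha, min_peptides = cfg$min_peptides,
      contrasts = vapply(cfg$contrasts, paste, character(1L), collapse = ":")
    ),
    n_proteins_in = nrow(matrix$values),
    n_proteins_analyzed = nrow(am$values),
    exclusions = list(
      pooled_missing = length(exclusions$pooled_missing),
      grubbs_cells = nrow(exclusions$grubbs),
      min_peptides = length(exclusions$min_peptides %||% character(0L))
    )
  )

  result <- list(matrix = am, exclusions = exclusions, dep = deps,
                 restoration = restoration, summary = summary_tab,
                 summary_strict = summary_strict, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(am, file.path(out_dir, "normalized_matrix.tsv"))
    write_table(data.frame(protein = exclusions$pooled_missing),
                file.path(out_dir, "excluded_pooled_missing.tsv"))
    write_table(exclusions$grubbs, file.path(out_dir, "grubbs_ledger.tsv"))
    if (!is.null(peptide_counts)) {
      write_table(data.frame(protein = exclusions$min_peptides),
                  file.path(out_dir, "excluded_min_peptides.tsv"))
    }
    for (key in names(deps)) {
      write_table(deps[[key]], file.path(out_dir, sprintf("dep_%s.tsv", key)))
    }
    write_table(restoration, file.path(out_dir, "restoration.tsv"))
    jsonlite::write_json(
      list(inclusive = summary_tab, strict = summary_strict),
      file.path(out_dir, "summary.json"), dataframe = "rows", digits = NA
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
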