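#' Venn partition of DEP lists
#'
#' Assigns every protein in the union of the input sets to exactly one
#' region of the power-set partition (e.g. `A`, `B`, `A&B` for two lists).
#'
#' @param sets Named list of character vectors (DEP lists by contrast).
#' @return Named list of character vectors, one per non-empty-label region;
#'   region sizes sum to the union size.
#' @export
#' @examples
#' venn_partition(list(A = c("p1", "p2"), B = c("p2", "p3")))
venn_partition <- function(sets) {
  if (!length(sets)) return(list())
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    ro_validation_error("sets must be named")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) {
    membership <- matrix(membership, nrow = 1L, dimnames = list(NULL, names(sets)))
  }
  k <- length(sets)
  regions <- list()
  for (mask in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    label <- paste(names(sets)[inset], collapse = "&")
    hit <- rowSums(membership[, inset, drop = FALSE]) == sum(inset) &
      rowSums(membership[, !inset, drop = FALSE]) == 0
    regions[[label]] <- universe[hit]
  }
  regions
}

is_dep_status <- function(status) status %in% c("up", "down")

#' Restoration classification
#'
#' Classifies every protein for one treatment from three DEP tables, via
#' the decision table:
#' \itemize{
#'   \item baseline DEP (mdx vs WT significant):
#'     treated-vs-WT ns -> `restored`;
#'     treated-vs-WT DEP and treated-vs-mdx DEP -> `partial`;
#'     treated-vs-WT DEP and treated-vs-mdx ns -> `unrestored`
#'     (significantly altered vs WT, yet not significantly different from
#'     untreated disease — therapy did not move it).
#'   \item baseline ns: treated-vs-WT DEP -> `treatment_induced`;
#'     otherwise -> `unchanged`.
#' }
#' Categories are mutually exclusive and exhaustive; untestable statuses
#' count as not-DEP.
#'
#' @param dep_mdx_vs_wt,dep_trt_vs_wt,dep_trt_vs_mdx [dep_table()] results
#'   over the same protein universe.
#' @param treatment Treatment group label (`uDys`, `midiDys`, `fullDys`).
#' @return A `RestorationCall` data frame: `protein`, `treatment`,
#'   `category`, `status_mdx_vs_wt`, `status_trt_vs_wt`,
#'   `status_trt_vs_mdx`.
#' @export
classify_restoration <- function(dep_mdx_vs_wt, dep_trt_vs_wt, dep_trt_vs_mdx,
                                 treatment) {
  if (!treatment %in% TREATMENT_GROUPS) {
    ro_config_error(sprintf("unknown treatment '%s'", treatment))
  }
  ids <- dep_mdx_vs_wt$protein
  for (dep in list(dep_trt_vs_wt, dep_trt_vs_mdx)) {
    missing <- c(setdiff(ids, dep$protein), setdiff(dep$protein, ids))
    if (length(missing)) {
      ro_validation_error(sprintf(
        "DEP tables cover different protein universes (e.g. %s)",
        paste(utils::head(missing, 3L), collapse = ", ")
      ))
    }
  }
  s_base <- setNames(dep_mdx_vs_wt$status, dep_mdx_vs_wt$protein)[ids]
  s_tw <- setNames(dep_trt_vs_wt$status, dep_trt_vs_wt$protein)[ids]
  s_tm <- setNames(dep_trt_vs_mdx$status, dep_trt_vs_mdx$protein)[ids]
  base_dep <- is_dep_status(s_base)
  tw_dep <- is_dep_status(s_tw)
  tm_dep <- is_dep_status(s_tm)
  category <- ifelse(base_dep,
    ifelse(!tw_dep, "restored", ifelse(tm_dep, "partial", "unrestored")),
    ifelse(tw_dep, "treatment_induced", "unchanged")
  )
  out <- data.frame(protein = ids, treatment = treatment, category = category,
                    status_mdx_vs_wt = unname(s_base),
                    status_trt_vs_wt = unname(s_tw),
                    status_trt_vs_mdx = unname(s_tm),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("RestorationCall", "data.frame")
  out
}

#' Restoration summary counts
#'
#' Counts restored / partial / unrestored proteins out of the N baseline
#' (mdx vs WT) DEPs for each treatment, plus the treatment-induced count.
#' The headline "restored X out of N" counts `restored + partial` by
#' default (proteins whose disease change was at least partly corrected);
#' `strict = TRUE` counts fully restored only. Both are reported.
#'
#' @param calls A `RestorationCall` data frame (one or more treatments,
#'   e.g. `rbind` of [classify_restoration()] results).
#' @param strict If `TRUE` the headline counts `restored` only.
#' @return Data frame per treatment: `treatment`, `n_baseline_dep`,
#'   `restored`, `partial`, `unrestored`, `treatment_induced`,
#'   `headline_restored`.
#' @export
restoration_summary <- function(calls, strict = FALSE) {
  out <- lapply(split(calls, calls$treatment), function(cc) {
    base <- cc[is_dep_status(cc$status_mdx_vs_wt), , drop = FALSE]
    counts <- table(factor(base$category,
                           levels = c("restored", "partial", "unrestored")))
    n <- nrow(base)
    stopifnot(sum(counts) == n)  # partition of the baseline DEP set
    data.frame(
      treatment = cc$treatment[1L],
      n_baseline_dep = n,
      restored = as.integer(counts[["restored"]]),
      partial = as.integer(counts[["partial"]]),
      unrestored = as.integer(counts[["unrestored"]]),
      treatment_induced = sum(cc$category == "treatment_induced"),
      headline_restored = if (strict) as.integer(counts[["restored"]]) else
        as.integer(counts[["restored"]] + counts[["partial"]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$treatment, TREATMENT_GROUPS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
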