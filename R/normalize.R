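#' Within-plex total-intensity normalization
#'
#' Within each plex, every channel is multiplied by the factor that makes
#' all channel totals — computed over the plex's shared rows (no missing
#' value in any channel of the plex) — equal to the plex's mean channel
#' total. Column scaling leaves within-channel ratios between proteins
#' unchanged.
#'
#' @param matrix An [abundance_matrix()] in state `"raw"`.
#' @param sheet Sample sheet.
#' @return The matrix with state `"within_plex_normalized"`.
#' @export
normalize_within_plex <- function(matrix, sheet) {
  assert_state(matrix, "raw", "normalize_within_plex")
  sheet <- validate_sample_sheet(sheet)
  x <- matrix$values
  for (plex in unique(sheet$plex_id)) {
    cols <- sheet$sample_id[sheet$plex_id == plex]
    block <- x[, cols, drop = FALSE]
    shared <- rowSums(is.na(block)) == 0L
    totals <- colSums(block[shared, , drop = FALSE])
    zero <- totals == 0
    if (any(zero)) {
      ro_validation_error(sprintf(
        "channel(s) with zero total in %s: %s", plex,
        paste(cols[zero], collapse = ", ")
      ))
    }
    factors <- mean(totals) / totals
    x[, cols] <- sweep(block, 2L, factors, `*`)
  }
  matrix$values <- x
  matrix$state <- "within_plex_normalized"
  matrix
}

#' Pooled bridge-channel scaling across plexes
#'
#' Per protein, each plex's columns are multiplied by the ratio of the
#' geometric mean of the protein's pooled-channel values across plexes to
#' its pooled value in that plex. Afterwards a protein's pooled values are
#' identical across plexes, removing inter-plex batch effects. Idempotent.
#'
#' @param matrix An [abundance_matrix()] in state
#'   `"within_plex_normalized"`.
#' @param sheet Sample sheet with one POOL channel per plex.
#' @return The matrix with state `"bridge_scaled"`.
#' @export
bridge_scale <- function(matrix, sheet) {
  assert_state(matrix, "within_plex_normalized", "bridge_scale")
  sheet <- validate_sample_sheet(sheet)
  x <- matrix$values
  plexes <- unique(sheet$plex_id)
  pool_cols <- vapply(plexes, function(p) {
    sheet$sample_id[sheet$plex_id == p & sheet$is_pool]
  }, character(1L))
  pools <- x[, pool_cols, drop = FALSE]
  bad <- rowSums(is.na(pools) | pools == 0) > 0L
  if (any(bad)) {
    ro_validation_error(sprintf(
      "%d protein(s) have missing or zero POOL values (e.g. %s); run filter_pooled_missing() first",
      sum(bad), paste(utils::head(rownames(x)[bad], 3L), collapse = ", ")
    ))
  }
  gm <- exp(rowMeans(log(pools)))
  for (k in seq_along(plexes)) {
    cols <- sheet$sample_id[sheet$plex_id == plexes[k]]
    x[, cols] <- x[, cols, drop = FALSE] * (gm / pools[, k])
  }
  matrix$values <- x
  matrix$state <- "bridge_scaled"
  matrix
}

#' Exclude proteins with missing pooled values
#'
#' Rows whose pooled bridge value is missing or zero in any plex are
#' removed and reported (they cannot be bridge-scaled; zero reporter
#' intensity is treated as non-detection).
#'
#' @param matrix An [abundance_matrix()].
#' @param sheet Sample sheet with one POOL channel per plex.
#' @return List with `matrix` (filtered) and `excluded` (row ids).
#' @export
filter_pooled_missing <- function(matrix, sheet) {
  sheet <- validate_sample_sheet(sheet)
  pool_cols <- sheet$sample_id[sheet$is_pool]
  pools <- matrix$values[, pool_cols, drop = FALSE]
  bad <- rowSums(is.na(pools) | pools == 0) > 0L
  excluded <- rownames(matrix$values)[bad]
  matrix$values <- matrix$values[!bad, , drop = FALSE]
  list(matrix = matrix, excluded = excluded)
}

#' Minimum-peptide filter
#'
#' Proteins quantified from fewer than `min_peptides` peptides are removed
#' and reported.
#'
#' @param matrix A protein-level [abundance_matrix()].
#' @param peptide_counts Named integer vector, protein id -> peptide count.
#' @param min_peptides Minimum count to retain (default 2).
#' @return List with `matrix` (filtered) and `excluded` (row ids).
#' @export
filter_min_peptides <- function(matrix, peptide_counts, min_peptides = 2L) {
  ids <- rownames(matrix$values)
  miss <- setdiff(ids, names(peptide_counts))
  if (length(miss)) {
    ro_validation_error(sprintf("no peptide count for protein(s): %s",
                                paste(utils::head(miss, 3L), collapse = ", ")))
  }
  counts <- peptide_counts[ids]
  if (any(counts < 0)) ro_validation_error("peptide counts must be >= 0")
  bad <- counts < min_peptides
  excluded <- ids[bad]
  matrix$values <- matrix$values[!bad, , drop = FALSE]
  list(matrix = matrix, excluded = excluded)
}

#' Peptide-to-protein roll-up with a razor rule
#'
#' Protein abundance per sample is the sum of its unique and razor peptide
#' intensities. A peptide mapping to several proteins (shared) is credited
#' entirely to the member protein with the most unique peptides, ties
#' broken by lexicographically smallest protein id.
#'
#' @param matrix A peptide-level [abundance_matrix()].
#' @param peptide_proteins Named list: peptide -> character vector of
#'   protein ids containing it (e.g. `classify_peptides()$membership`).
#' @return List with `matrix` (protein-level, same state), and
#'   `peptide_counts` (named vector of peptides credited per protein).
#' @export
rollup_proteins <- function(matrix, peptide_proteins) {
  if (!inherits(matrix, "AbundanceMatrix") || matrix$level != "peptide") {
    ro_validation_error("rollup_proteins() expects a peptide-level AbundanceMatrix")
  }
  peps <- rownames(matrix$values)
  miss <- setdiff(peps, names(peptide_proteins))
  if (length(miss)) {
    ro_validation_error(sprintf("no protein mapping for peptide(s): %s",
                                paste(utils::head(miss, 3L), collapse = ", ")))
  }
  maps <- peptide_proteins[peps]
  n_owners <- lengths(maps)
  if (any(n_owners == 0L)) ro_validation_error("peptides with empty protein mapping")
  unique_of <- unlist(maps[n_owners == 1L], use.names = FALSE)
  unique_counts <- table(unique_of)
  assign_to <- vapply(maps, function(prots) {
    if (length(prots) == 1L) return(prots)
    uc <- as.integer(unique_counts[prots])
    uc[is.na(uc)] <- 0L
    prots <- prots[order(-uc, prots)]
    prots[1L]
  }, character(1L))
  proteins <- sort(unique(assign_to))
  vals <- matrix$values
  out <- matrix(NA_real_, nrow = length(proteins), ncol = ncol(vals),
                dimnames = list(proteins, colnames(vals)))
  for (p in proteins) {
    sub <- vals[assign_to == p, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    s <- colSums(sub, na.rm = TRUE)
    s[n_obs == 0L] <- NA_real_
    out[p, ] <- s
  }
  list(
    matrix = abundance_matrix(out, level = "protein", state = matrix$state),
    peptide_counts = setNames(as.integer(table(assign_to)[proteins]), proteins)
  )
}
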