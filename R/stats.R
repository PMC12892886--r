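## Zero floor: half the smallest positive value in the matrix, applied once
## before log transforms so zero intensities do not map to -Inf.
zero_floor <- function(values) {
  pos <- values[!is.na(values) & values > 0]
  if (!length(pos)) ro_validation_error("matrix has no positive values")
  min(pos) / 2
}

log2_with_floor <- function(values, floor) {
  v <- pmax(values, floor)
  log2(v)
}

#' Geometric-mean log2 fold change
#'
#' `log2(geomean(a) / geomean(b))`, skipping missing values; zeros are
#' replaced by `floor` (by default half the smallest positive value seen in
#' the two groups) before the log.
#'
#' @param a,b Numeric vectors of replicate abundances for the two groups.
#' @param floor Positive replacement for zeros; `NULL` derives it from the
#'   data.
#' @return The log2 fold change of `a` over `b`, or `NA` if either group
#'   has no usable value.
#' @export
#' @examples
#' log2_fold_change(c(2, 8), c(1, 1)) # 2
log2_fold_change <- function(a, b, floor = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  if (is.null(floor)) floor <- zero_floor(c(a, b))
  mean(log2_with_floor(a, floor)) - mean(log2_with_floor(b, floor))
}

## Vectorised equal-variance two-sample t on log2 abundances.
## Returns p values; NA where either group has < 2 observed replicates.
## Zero pooled variance: p = 1 if the means are equal, else p = 0.
row_ttest <- function(xa, xb) {
  na <- row_n(xa); nb <- row_n(xb)
  ma <- row_mean(xa); mb <- row_mean(xb)
  va <- row_var(xa); vb <- row_var(xb)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.na(sp2) & sp2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  p[na < 2 | nb < 2] <- NA_real_
  p
}

group_cols <- function(sheet, group) {
  cols <- sheet$sample_id[!sheet$is_pool & sheet$group == group]
  if (!length(cols)) ro_config_error(sprintf("no samples for group '%s'", group))
  cols
}

#' Per-protein two-sample t-test for one contrast
#'
#' Two-tailed unpaired Student's (equal-variance) t-test on log2
#' abundances, vectorised over proteins. Proteins with fewer than 2
#' observed replicates in either group are untestable (`NA`).
#'
#' @param matrix An [abundance_matrix()].
#' @param sheet Sample sheet.
#' @param contrast Length-2 character vector `c(A, B)`.
#' @param welch If `TRUE` use Welch's unequal-variance t instead.
#' @return Named numeric vector of raw p-values.
#' @export
pairwise_ttest <- function(matrix, sheet, contrast, welch = FALSE) {
  sheet <- validate_sample_sheet(sheet)
  floor <- zero_floor(matrix$values)
  xa <- log2_with_floor(matrix$values[, group_cols(sheet, contrast[1L]), drop = FALSE], floor)
  xb <- log2_with_floor(matrix$values[, group_cols(sheet, contrast[2L]), drop = FALSE], floor)
  if (!welch) return(setNames(row_ttest(xa, xb), rownames(matrix$values)))
  na <- row_n(xa); nb <- row_n(xb)
  ma <- row_mean(xa); mb <- row_mean(xb)
  va <- row_var(xa); vb <- row_var(xb)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.na(se2) & se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  p[na < 2 | nb < 2] <- NA_real_
  setNames(p, rownames(matrix$values))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1
#' and mapped back to input order. `NA` entries (untestable hypotheses) are
#' excluded from `m` and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, same length and names as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  names(out) <- names(p)
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) ro_validation_error("p-values must be in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  out[ok] <- q
  out
}

#' DEP status calls
#'
#' `up` if `log2fc >= fc_cutoff_log2` and `q <= q_cutoff`; `down`
#' symmetrically; `ns` otherwise; `untestable` where the inputs are
#' missing. Boundary equalities are significant.
#'
#' @param log2fc,q Aligned numeric vectors.
#' @param cfg A [run_config()].
#' @return Character vector of statuses.
#' @export
call_deps <- function(log2fc, q, cfg = run_config()) {
  if (length(log2fc) != length(q)) ro_validation_error("log2fc and q must align")
  status <- rep("ns", length(log2fc))
  sig <- !is.na(q) & q <= cfg$q_cutoff
  status[sig & log2fc >= cfg$fc_cutoff_log2] <- "up"
  status[sig & log2fc <= -cfg$fc_cutoff_log2] <- "down"
  status[is.na(log2fc) | is.na(q)] <- "untestable"
  names(status) <- names(log2fc)
  status
}

#' Differential-expression table for one contrast
#'
#' Computes per-protein geometric-mean log2 fold changes, Student's t
#' p-values, BH-adjusted q-values and DEP status for the contrast
#' `c(A, B)` (fold change of A over B).
#'
#' @param matrix An [abundance_matrix()].
#' @param sheet Sample sheet.
#' @param contrast Length-2 character vector `c(A, B)`.
#' @param cfg A [run_config()].
#' @return A `DEPTable` data frame: `protein`, `log2fc`, `p_raw`, `q`,
#'   `status`, with the contrast in attribute `"contrast"`.
#' @export
dep_table <- function(matrix, sheet, contrast, cfg = run_config()) {
  sheet <- validate_sample_sheet(sheet)
  floor <- zero_floor(matrix$values)
  a <- log2_with_floor(matrix$values[, group_cols(sheet, contrast[1L]), drop = FALSE], floor)
  b <- log2_with_floor(matrix$values[, group_cols(sheet, contrast[2L]), drop = FALSE], floor)
  fc <- row_mean(a) - row_mean(b)
  fc[row_n(a) == 0 | row_n(b) == 0] <- NA_real_
  p <- row_ttest(a, b)
  q <- bh_adjust(p)
  fc_for_call <- fc
  fc_for_call[is.na(p)] <- NA_real_   # untestable dominates
  status <- call_deps(fc_for_call, q, cfg)
  out <- data.frame(protein = rownames(matrix$values), log2fc = fc,
                    p_raw = p, q = q, status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("DEPTable", "data.frame")
  out
}

#' Reverse a DEP table
#'
#' The table for contrast `(B, A)` from the table for `(A, B)`: negated
#' fold changes, identical p and q, swapped up/down.
#'
#' @param dep A [dep_table()] result.
#' @return The reversed `DEPTable`.
#' @export
dep_reverse <- function(dep) {
  out <- dep
  out$log2fc <- -dep$log2fc
  out$status <- c(up = "down", down = "up", ns = "ns",
                  untestable = "untestable")[dep$status]
  names(out$status) <- NULL
  attr(out, "contrast") <- rev(attr(dep, "contrast"))
  out
}

#' One-way ANOVA with Tukey pairwise comparisons
#'
#' Standard one-way ANOVA on log2 abundances across the study groups,
#' vectorised over proteins, plus Tukey HSD adjusted p-values for every
#' group pair from the studentized-range distribution with the ANOVA
#' residual degrees of freedom (Tukey-Kramer for unequal n).
#'
#' @param matrix An [abundance_matrix()].
#' @param sheet Sample sheet.
#' @param groups Groups to compare (default all five study groups).
#' @return Data frame: `protein`, `F`, `p_omnibus`, and one
#'   `tukey_<A>_vs_<B>` column per pair. Proteins with any group below 2
#'   observed replicates get `NA` rows.
#' @export
anova_tukey <- function(matrix, sheet, groups = STUDY_GROUPS) {
  sheet <- validate_sample_sheet(sheet)
  if (length(groups) < 2L) ro_config_error("need at least 2 groups")
  floor <- zero_floor(matrix$values)
  blocks <- lapply(groups, function(g) {
    log2_with_floor(matrix$values[, group_cols(sheet, g), drop = FALSE], floor)
  })
  names(blocks) <- groups
  ns <- vapply(blocks, row_n, numeric(nrow(matrix$values)))
  ms <- vapply(blocks, row_mean, numeric(nrow(matrix$values)))
  ssw <- Reduce(`+`, lapply(blocks, function(b) {
    rowSums((b - row_mean(b))^2, na.rm = TRUE)
  }))
  N <- rowSums(ns)
  k <- length(groups)
  grand <- rowSums(ns * ms) / N
  ssb <- rowSums(ns * (ms - grand)^2)
  df1 <- k - 1
  df2 <- N - k
  mse <- ssw / df2
  Fstat <- (ssb / df1) / mse
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  # all observations equal: F = 0, p = 1; zero within-variance with real
  # between-group differences: F = Inf, p = 0
  allzero <- ssw == 0 & ssb < 1e-12
  Fstat[allzero] <- 0
  p[allzero] <- 1
  sep <- ssw == 0 & ssb >= 1e-12
  Fstat[sep] <- Inf
  p[sep] <- 0
  untestable <- apply(ns, 1L, min) < 2
  out <- data.frame(protein = rownames(matrix$values), F = Fstat,
                    p_omnibus = p, row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  for (pr in pairs) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(mse / 2 * (1 / ns[, i] + 1 / ns[, j]))
    qstat <- abs(ms[, i] - ms[, j]) / se
    padj <- ptukey(qstat, nmeans = k, df = df2, lower.tail = FALSE)
    deg <- mse == 0
    padj[deg] <- ifelse(abs(ms[deg, i] - ms[deg, j]) < 1e-12, 1, 0)
    out[[sprintf("tukey_%s_vs_%s", i, j)]] <- padj
  }
  if (any(untestable)) out[untestable, -1L] <- NA_real_
  out
}

#' Volcano-plot table
#'
#' Plot-ready rows: log2 fold change against `-log10(q)` with DEP status.
#' Untestable proteins are dropped; `q = 0` is floored at the smallest
#' positive double.
#'
#' @param dep A [dep_table()] result.
#' @return Data frame: `protein`, `log2fc`, `neg_log10_q`, `status`.
#' @export
volcano_table <- function(dep) {
  keep <- dep$status != "untestable"
  q <- pmax(dep$q[keep], .Machine$double.xmin)
  data.frame(protein = dep$protein[keep], log2fc = dep$log2fc[keep],
             neg_log10_q = -log10(q), status = dep$status[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
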