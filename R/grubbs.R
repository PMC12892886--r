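#' Grubbs critical value
#'
#' Two-sided single-outlier critical value at level `alpha` for sample size
#' `n`: `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the
#' upper `alpha/(2n)` quantile of Student's t on `n-2` degrees of freedom.
#'
#' @param n Sample size(s), each >= 3.
#' @param alpha Significance level.
#' @return Numeric vector of critical values (vectorised over `n`).
#' @export
grubbs_crit <- function(n, alpha = 0.05) {
  if (any(n < 3)) ro_validation_error("Grubbs test requires n >= 3")
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs single-outlier test
#'
#' Tests for one outlier via the maximum absolute studentized deviation
#' `G = max |x - mean| / sd` (sample sd, n-1 denominator), two-sided. At
#' most one point is flagged; a zero-variance sample has undefined `G` and
#' no outlier.
#'
#' @param values Numeric vector, n >= 3, finite.
#' @param alpha Significance level (default 0.05).
#' @return A `GrubbsResult` list: `G`, `G_crit`, `outlier_index` (1-based
#'   index of the flagged point, or `NA`), `n`, `alpha`.
#' @export
#' @examples
#' grubbs_test(c(1, 1, 1, 1, 10))
grubbs_test <- function(values, alpha = 0.05) {
  if (any(!is.finite(values))) ro_validation_error("values must be finite")
  n <- length(values)
  if (n < 3L) ro_validation_error("Grubbs test requires n >= 3")
  s <- sd(values)
  gcrit <- grubbs_crit(n, alpha)
  if (s == 0) {
    res <- list(G = NA_real_, G_crit = gcrit, outlier_index = NA_integer_,
                n = n, alpha = alpha)
    return(structure(res, class = "GrubbsResult"))
  }
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  idx <- if (G > gcrit) which.max(dev) else NA_integer_
  structure(list(G = G, G_crit = gcrit, outlier_index = idx, n = n,
                 alpha = alpha), class = "GrubbsResult")
}

#' @export
print.GrubbsResult <- function(x, ...) {
  cat(sprintf("<GrubbsResult> n=%d G=%.4f G_crit(%.3g)=%.4f outlier=%s\n",
              x$n, x$G, x$alpha, x$G_crit,
              if (is.na(x$outlier_index)) "none" else x$outlier_index))
  invisible(x)
}

#' Apply Grubbs outlier exclusion per protein per group
#'
#' The test runs independently on each (protein, group) replicate set, on
#' log2 abundances (zeros and missing values are skipped; sets with fewer
#' than 3 observed values are skipped). At most one cell per set is flagged
#' and set to missing. Vectorised across proteins within each group.
#'
#' @param matrix An [abundance_matrix()] in state `"bridge_scaled"`.
#' @param sheet Sample sheet.
#' @param alpha Significance level (default 0.05).
#' @return List with `matrix` (flagged cells set missing) and `ledger`
#'   (data frame: `row_id`, `group`, `sample_id`, `value`, `G`, `G_crit`).
#' @export
apply_grubbs <- function(matrix, sheet, alpha = 0.05) {
  assert_state(matrix, "bridge_scaled", "apply_grubbs")
  sheet <- validate_sample_sheet(sheet)
  x <- matrix$values
  ledgers <- list()
  study <- sheet[!sheet$is_pool, , drop = FALSE]
  for (g in unique(study$group)) {
    cols <- study$sample_id[study$group == g]
    block <- x[, cols, drop = FALSE]
    lx <- log2(block)
    lx[!is.finite(lx)] <- NA_real_   # zeros treated as non-detection
    n <- row_n(lx)
    m <- row_mean(lx)
    s <- sqrt(row_var(lx))
    dev <- abs(lx - m)
    maxdev <- apply(dev, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    G <- maxdev / s
    testable <- n >= 3L & !is.na(s) & s > 0
    gcrit <- rep(NA_real_, nrow(x))
    gcrit[testable] <- grubbs_crit(n[testable], alpha)
    flag <- which(testable & G > gcrit)
    if (length(flag)) {
      which_col <- max.col(replace(dev[flag, , drop = FALSE],
                                   is.na(dev[flag, , drop = FALSE]), -Inf),
                           ties.method = "first")
      cells_col <- cols[which_col]
      ledgers[[g]] <- data.frame(
        row_id = rownames(x)[flag], group = g, sample_id = cells_col,
        value = x[cbind(flag, match(cells_col, colnames(x)))],
        G = G[flag], G_crit = gcrit[flag], stringsAsFactors = FALSE
      )
      x[cbind(flag, match(cells_col, colnames(x)))] <- NA_real_
    }
  }
  ledger <- if (length(ledgers)) do.call(rbind, ledgers) else
    data.frame(row_id = character(0L), group = character(0L),
               sample_id = character(0L), value = numeric(0L),
               G = numeric(0L), G_crit = numeric(0L))
  rownames(ledger) <- NULL
  matrix$values <- x
  list(matrix = matrix, ledger = ledger)
}
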