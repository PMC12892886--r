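# Independent reference oracles and fixture builders. Oracles deliberately
# use different algorithms from the package implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Regex-split digestion oracle: split at every tryptic bond, then join runs
# of up to max_missed + 1 adjacent fragments.
oracle_digest <- function(sequence, max_missed = 2L, min_len = 6L, max_len = 50L) {
  frags <- strsplit(sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1L]]
  res <- list()
  for (m in 0:max_missed) {
    k <- length(frags) - m
    if (k < 1L) break
    for (i in seq_len(k)) {
      pep <- paste(frags[i:(i + m)], collapse = "")
      if (nchar(pep) >= min_len && nchar(pep) <= max_len) {
        start <- if (i == 1L) 1L else sum(nchar(frags[seq_len(i - 1L)])) + 1L
        res[[length(res) + 1L]] <- data.frame(peptide = pep, missed = m,
                                              start = start,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(peptide = character(0L), missed = integer(0L), start = integer(0L))
  out <- out[order(out$start, nchar(out$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force substring digestion oracle: enumerate every substring and keep
# those whose boundaries are cleavage boundaries, counting internal missed
# sites. O(L^2); only for short sequences.
substring_digest_oracle <- function(sequence, max_missed = 2L, min_len = 6L,
                                    max_len = 50L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cuts <- integer(0L)
  for (i in seq_len(n - 1L)) {
    if ((chars[i] == "K" || chars[i] == "R") && chars[i + 1L] != "P") {
      cuts <- c(cuts, i)
    }
  }
  res <- list()
  for (i in seq_len(n)) {
    if (!(i == 1L || (i - 1L) %in% cuts)) next
    for (j in i:n) {
      if (!(j == n || j %in% cuts)) next
      len <- j - i + 1L
      missed <- sum(cuts >= i & cuts < j)
      if (missed <= max_missed && len >= min_len && len <= max_len) {
        res[[length(res) + 1L]] <- data.frame(
          peptide = substring(sequence, i, j), missed = missed, start = i,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(peptide = character(0L), missed = integer(0L), start = integer(0L))
  out <- out[order(out$start, nchar(out$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Literal step-up BH definition with explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0L)
    for (j in i:m) vals <- c(vals, sorted[j] * m / j)
    q[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# The two published filter criteria as raw set operations.
unrestored_oracle <- function(dep_mdx_vs_wt, dep_trt_vs_wt, dep_trt_vs_mdx) {
  dep_ids <- function(d) d$protein[d$status %in% c("up", "down")]
  baseline <- dep_ids(dep_mdx_vs_wt)
  crit_a <- dep_ids(dep_trt_vs_wt)
  crit_b <- setdiff(dep_trt_vs_mdx$protein, dep_ids(dep_trt_vs_mdx))
  intersect(baseline, intersect(crit_a, crit_b))
}

# Simulation config with every stochastic nuisance switched off (overridable).
quiet_cfg <- function(...) {
  args <- list(...)
  quiet <- list(noise_cv = 0, plex_shift_log2 = 0, coisolation_rho = 0,
                outlier_rate = 0, missing_rate = 0)
  do.call(sim_config, c(args, quiet[setdiff(names(quiet), names(args))]))
}

# Tiny 2-plex sheet: `per_group` replicates of each group per plex + pool.
tiny_sheet <- function(per_group = 1L) study_design(2L * per_group, 2L)

# Deterministic small matrix on a given sheet.
tiny_matrix <- function(sheet, n = 4L, seed = 1L, state = "raw") {
  set.seed(seed)
  vals <- matrix(rlnorm(n * nrow(sheet), log(100), 0.3), nrow = n,
                 dimnames = list(sprintf("P%02d", seq_len(n)), sheet$sample_id))
  abundance_matrix(vals, state = state)
}

write_fasta_fixture <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}
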