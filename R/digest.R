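#' Tryptic digestion settings
#'
#' Defaults mirror a standard database-search configuration: full trypsin
#' specificity, up to 2 missed cleavages, peptide length 6 to 50.
#'
#' @param protease Only `"trypsin_full"` is supported: cleavage C-terminal
#'   to K or R, except when the next residue is P.
#' @param max_missed Maximum internal missed cleavage sites per peptide.
#' @param min_len,max_len Inclusive peptide length bounds.
#' @return A `DigestSettings` list.
#' @export
digest_settings <- function(protease = "trypsin_full", max_missed = 2L,
                            min_len = 6L, max_len = 50L) {
  if (!identical(protease, "trypsin_full")) {
    ro_config_error(sprintf("unsupported protease '%s'", protease))
  }
  max_missed <- as.integer(max_missed)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (max_missed < 0L) ro_config_error("max_missed must be >= 0")
  if (min_len < 1L || min_len > max_len) {
    ro_config_error("need 1 <= min_len <= max_len")
  }
  structure(list(protease = protease, max_missed = max_missed,
                 min_len = min_len, max_len = max_len),
            class = "DigestSettings")
}

## 1-based positions i such that the bond after residue i is cleaved:
## residue i is K or R and residue i+1 is not P. The sequence end is not a
## cleavage site.
trypsin_cut_after <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(integer(0L))
  i <- seq_len(n - 1L)
  i[(chars[i] == "K" | chars[i] == "R") & chars[i + 1L] != "P"]
}

#' In-silico tryptic digestion
#'
#' Enumerates all tryptic peptides of a sequence with at most
#' `settings$max_missed` missed cleavages and length within the configured
#' bounds. Cleavage occurs after K or R unless followed by P.
#'
#' @param sequence Amino-acid sequence string.
#' @param settings A [digest_settings()] object.
#' @return A data frame with columns `peptide`, `missed` (missed cleavage
#'   count) and `start` (1-based position in the input), ordered by
#'   `(start, length)`.
#' @export
#' @examples
#' digest("MKRAT", digest_settings(max_missed = 0, min_len = 1))
digest <- function(sequence, settings = digest_settings()) {
  assert_aa_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  # fragment boundaries: 0, each cut position, n
  bounds <- c(0L, trypsin_cut_after(chars), n)
  nfrag <- length(bounds) - 1L
  out <- vector("list", settings$max_missed + 1L)
  for (m in 0:settings$max_missed) {
    k <- nfrag - m
    if (k < 1L) break
    i <- seq_len(k)
    start <- bounds[i] + 1L
    end <- bounds[i + 1L + m]
    len <- end - start + 1L
    keep <- len >= settings$min_len & len <= settings$max_len
    if (!any(keep)) next
    out[[m + 1L]] <- data.frame(
      peptide = substring(sequence, start[keep], end[keep]),
      missed = m,
      start = start[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peptide = character(0L), missed = integer(0L),
                      start = integer(0L), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, nchar(res$peptide)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Unique peptide set of a construct digest
#'
#' @param sequence Amino-acid sequence string.
#' @param settings A [digest_settings()] object.
#' @return Character vector of distinct peptides.
#' @export
digest_peptides <- function(sequence, settings = digest_settings()) {
  unique(digest(sequence, settings)$peptide)
}
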