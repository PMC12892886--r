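## Typed error conditions. Every validation failure raises one of these;
## nothing is silently coerced.

ro_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "restoromics_error"), call = call))
}

ro_format_error <- function(msg) ro_stop(msg, "restoromics_format_error", sys.call(-1))
ro_validation_error <- function(msg) ro_stop(msg, "restoromics_validation_error", sys.call(-1))
ro_schema_error <- function(msg) ro_stop(msg, "restoromics_schema_error", sys.call(-1))
ro_config_error <- function(msg) ro_stop(msg, "restoromics_config_error", sys.call(-1))
ro_io_error <- function(msg) ro_stop(msg, "restoromics_io_error", sys.call(-1))
ro_state_error <- function(msg) ro_stop(msg, "restoromics_state_error", sys.call(-1))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise moments on a numeric matrix, skipping NA. Used throughout the
## vectorised statistics; avoids per-protein apply() loops.
row_n <- function(x) rowSums(!is.na(x))

row_mean <- function(x) {
  n <- row_n(x)
  out <- rowSums(x, na.rm = TRUE) / n
  out[n == 0] <- NA_real_
  out
}

row_var <- function(x) {
  n <- row_n(x)
  m <- row_mean(x)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

assert_aa_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    ro_validation_error(sprintf("sequence for '%s' must be a non-empty string", id))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad)) {
    ro_validation_error(sprintf(
      "sequence for '%s' contains non-amino-acid character '%s' at position %d",
      id, chars[bad[1L]], bad[1L]
    ))
  }
  invisible(sequence)
}
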