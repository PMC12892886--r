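#' Construct sequences
#'
#' A `ConstructSequence` is a named amino-acid sequence carrying its origin
#' (endogenous vs transgenic) and size class (micro, midi, full). A set of
#' them describes the dystrophin constructs under comparison: the endogenous
#' full-length protein and the AAV-delivered micro-, midi- and full-length
#' transgenes.
#'
#' @param id Short unique identifier.
#' @param sequence Amino-acid sequence (uppercase, 20-letter alphabet).
#' @param origin `"endogenous"` or `"transgenic"`.
#' @param size_class `"micro"`, `"midi"` or `"full"`.
#' @return An object of class `ConstructSequence`.
#' @export
#' @examples
#' construct_sequence("dys1", "MKRAT", "endogenous", "full")
construct_sequence <- function(id, sequence,
                               origin = c("endogenous", "transgenic"),
                               size_class = c("micro", "midi", "full")) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    ro_validation_error("construct id must be a non-empty string")
  }
  origin <- match.arg(origin)
  size_class <- match.arg(size_class)
  assert_aa_sequence(sequence, id)
  structure(
    list(id = id, sequence = sequence, origin = origin, size_class = size_class),
    class = "ConstructSequence"
  )
}

#' @export
print.ConstructSequence <- function(x, ...) {
  cat(sprintf(
    "<ConstructSequence> %s (%s, %s), %d aa\n",
    x$id, x$origin, x$size_class, nchar(x$sequence)
  ))
  invisible(x)
}

validate_construct_set <- function(constructs) {
  if (!length(constructs)) ro_validation_error("construct set is empty")
  ok <- vapply(constructs, inherits, logical(1L), "ConstructSequence")
  if (!all(ok)) ro_validation_error("all elements must be ConstructSequence objects")
  ids <- vapply(constructs, `[[`, character(1L), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    ro_validation_error(sprintf("duplicate construct id(s): %s",
                                paste(unique(dup), collapse = ", ")))
  }
  names(constructs) <- ids
  constructs
}

parse_construct_header <- function(header) {
  parts <- strsplit(trimws(header), "\\s+")[[1L]]
  id <- parts[1L]
  tags <- parts[-1L]
  kv <- tags[grepl("=", tags, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  tag <- function(key) {
    hit <- which(keys == key)
    if (!length(hit)) {
      ro_format_error(sprintf(
        "FASTA record '%s': header is missing required tag '%s='", id, key
      ))
    }
    vals[hit[1L]]
  }
  list(id = id, origin = tag("origin"), size_class = tag("size_class"))
}

#' Read construct sequences from FASTA
#'
#' Headers must follow the dialect `>id origin=<endogenous|transgenic>
#' size_class=<micro|midi|full>` (whitespace-separated key=value tags after
#' the identifier). Record order is preserved.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A named list of [construct_sequence()] objects.
#' @export
read_constructs <- function(path) {
  if (!file.exists(path)) ro_io_error(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) ro_format_error(sprintf("no FASTA records in %s", path))
  constructs <- lapply(seq_along(seqs), function(i) {
    h <- parse_construct_header(names(seqs)[i])
    if (!h$origin %in% c("endogenous", "transgenic")) {
      ro_format_error(sprintf("FASTA record '%s': unknown origin '%s'", h$id, h$origin))
    }
    if (!h$size_class %in% c("micro", "midi", "full")) {
      ro_format_error(sprintf("FASTA record '%s': unknown size_class '%s'", h$id, h$size_class))
    }
    construct_sequence(h$id, as.character(seqs[[i]]), h$origin, h$size_class)
  })
  validate_construct_set(constructs)
}

#' Write construct sequences to FASTA
#'
#' Inverse of [read_constructs()]; emits the same header dialect.
#'
#' @param constructs Named list of [construct_sequence()] objects.
#' @param path Output path.
#' @export
write_constructs <- function(constructs, path) {
  constructs <- validate_construct_set(constructs)
  seqs <- Biostrings::AAStringSet(vapply(constructs, `[[`, character(1L), "sequence"))
  names(seqs) <- vapply(constructs, function(cs) {
    sprintf("%s origin=%s size_class=%s", cs$id, cs$origin, cs$size_class)
  }, character(1L))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
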