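#' Reverse complement of a nucleotide string
#'
#' @param x A single nucleotide string (IUPAC codes allowed).
#' @return A single string, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a random uniform-composition genome sequence
#'
#' Bases are drawn i.i.d. uniformly from A, C, G, T. Uses the current RNG
#' stream; call [set.seed()] for reproducibility.
#'
#' @param n Sequence length in bases.
#' @return A single string of length `n`.
#' @export
random_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Coerce the various genome carriers (string, genome_record, one-row tibble)
# to a list(id =, seq =). Internal.
as_genome <- function(x, default_id = "genome") {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = default_id, seq = toupper(x)))
  }
  if (is.list(x) && !is.null(x$seq)) {
    id <- if (!is.null(x$id)) as.character(x$id)[1] else default_id
    return(list(id = id, seq = toupper(as.character(x$seq)[1])))
  }
  abort("cannot interpret input as a genome (expected a string or a record with $seq)")
}

# Coerce a genome set (tibble with id/seq, named character vector, or
# DNAStringSet) to a tibble(id, seq). Internal.
as_genome_tbl <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(tibble::tibble(id = names(x), seq = toupper(as.character(x))))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    out <- tibble::as_tibble(x[c("id", "seq")])
    out$seq <- toupper(out$seq)
    return(out)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("G%02d", seq_along(x))
    return(tibble::tibble(id = ids, seq = toupper(unname(x))))
  }
  abort("cannot interpret input as a genome set")
}

# Strip directory and FASTA-ish extensions from labels so that tool outputs
# keyed by file path join against plain genome ids.
normalize_label <- function(x) {
  x <- basename(as.character(x))
  sub("\\.(fa|fasta|fna)(\\.gz)?$", "", x, ignore.case = TRUE)
}
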