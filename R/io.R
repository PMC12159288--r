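#' Read genomes from a (possibly gzipped) multi-FASTA file
#'
#' Sequences are folded to upper case; record ids are the first whitespace
#' token of each header. Empty files and duplicate ids are explicit errors.
#'
#' @param path Path to a `.fa`/`.fasta` file, optionally `.gz`-compressed.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) abort(paste("cannot read FASTA:",
                                                 conditionMessage(e))))
  if (length(ss) == 0) abort(paste("empty FASTA file:", path))
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(paste("duplicate FASTA ids:", paste(unique(dup), collapse = ", ")))
  }
  tibble::tibble(id = ids, seq = unname(toupper(as.character(ss))))
}

#' Write genomes to a multi-FASTA file
#'
#' @param genomes A genome set (tibble with `id`, `seq`, or named character
#'   vector).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  g <- as_genome_tbl(genomes)
  ss <- Biostrings::DNAStringSet(setNames(g$seq, g$id))
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write pair tables in long or square dialect
#'
#' Long dialect: TSV with header `query`, `reference`, then value columns.
#' Square dialect: labeled symmetric matrix (header row of labels, first
#' column of labels). The two dialects convert losslessly for complete
#' tables; missing pairs of a long table become `NA` cells in the square
#' form, never zeros.
#'
#' @param path File path.
#' @param dialect `"long"` or `"square"`.
#' @return `read_pair_table`: a tibble `query`, `reference`, value column(s)
#'   with query < reference.
#' @export
read_pair_table <- function(path, dialect = c("long", "square")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    x <- tibble::as_tibble(read.delim(path, check.names = FALSE))
    stopifnot(all(c("query", "reference") %in% names(x)))
    q <- pmin(x$query, x$reference)
    r <- pmax(x$query, x$reference)
    x$query <- q; x$reference <- r
    return(dplyr::arrange(dplyr::distinct(x, .data$query, .data$reference,
                                          .keep_all = TRUE),
                          .data$query, .data$reference))
  }
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m))) {
    abort("square pair table must be a labeled square matrix")
  }
  storage.mode(m) <- "double"
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-9) {
    abort(sprintf("square matrix is asymmetric (max |M - t(M)| = %g)", asym))
  }
  dist_long(m, value = "value")
}

#' @rdname read_pair_table
#' @param x A pair tibble (`query`, `reference`, one value column) for
#'   writing.
#' @return `write_pair_table`: `path`, invisibly.
#' @export
write_pair_table <- function(x, path, dialect = c("long", "square")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(x), all(c("query", "reference") %in% names(x)))
  x <- dplyr::arrange(tibble::as_tibble(x), .data$query, .data$reference)
  if (dialect == "long") {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  vcol <- setdiff(names(x), c("query", "reference"))[1]
  labs <- sort(union(x$query, x$reference))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  diag(m) <- 0
  m[cbind(x$query, x$reference)] <- x[[vcol]]
  m[cbind(x$reference, x$query)] <- x[[vcol]]
  write.table(cbind(data.frame(label = labs), as.data.frame(m)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse the output of an external distance tool
#'
#' Adapters for the file shapes emitted by commonly benchmarked tools, all
#' normalized to a pair tibble with an `orientation` attribute:
#' * `mash`: `mash dist -t` square matrix (row labels in the first column)
#'   or the 5-column long output (query, reference, distance, p, shared);
#'   values are distances; self pairs are dropped.
#' * `fastani`: 5-column output (query, reference, ANI, mapped, total);
#'   values are similarity percents; pairs the tool left unreported are
#'   flagged as missing when joined in [make_pair_table()].
#' * `pyani_matrix`: labeled square similarity matrix.
#'
#' @param path File path.
#' @param tool `"mash"`, `"fastani"` or `"pyani_matrix"`.
#' @return A tibble `query`, `reference`, `value` (query < reference,
#'   normalized labels) with attribute `orientation` set to `"distance"` or
#'   `"similarity"`.
#' @export
parse_external_tool_output <- function(path,
                                       tool = c("mash", "fastani",
                                                "pyani_matrix")) {
  tool <- match.arg(tool)
  finish <- function(q, r, v, orientation) {
    q <- normalize_label(q); r <- normalize_label(r)
    keep <- q != r
    out <- tibble::tibble(query = pmin(q[keep], r[keep]),
                          reference = pmax(q[keep], r[keep]),
                          value = v[keep])
    out <- dplyr::distinct(out, .data$query, .data$reference,
                           .keep_all = TRUE)
    out <- dplyr::arrange(out, .data$query, .data$reference)
    attr(out, "orientation") <- orientation
    out
  }
  first <- readLines(path, n = 1)
  if (tool == "mash") {
    nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    looks_square <- startsWith(first, "#") || nfield > 5
    if (looks_square) {
      m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
      storage.mode(m) <- "double"
      colnames(m) <- normalize_label(colnames(m))
      rownames(m) <- normalize_label(rownames(m))
      lg <- dist_long(m, value = "value")
      return(finish(lg$query, lg$reference, lg$value, "distance"))
    }
    x <- read.delim(path, header = FALSE)
    if (ncol(x) < 3) abort("mash long output needs >= 3 columns (query, reference, distance)")
    return(finish(x[[1]], x[[2]], as.numeric(x[[3]]), "distance"))
  }
  if (tool == "fastani") {
    x <- read.delim(path, header = FALSE)
    if (ncol(x) < 3) {
      abort("fastani output needs 5 columns (query, reference, ANI, mapped, total)")
    }
    return(finish(x[[1]], x[[2]], as.numeric(x[[3]]), "similarity"))
  }
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  colnames(m) <- normalize_label(colnames(m))
  rownames(m) <- normalize_label(rownames(m))
  lg <- dist_long(m, value = "value")
  finish(lg$query, lg$reference, lg$value, "similarity")
}

#' Serialize / read a MinHash sketch as TSV
#'
#' A stable plain-text dialect: a header line
#' `#anibench-sketch k=<k> s=<s> seed=<seed> canonical=<0/1> id=<genome_id>`
#' followed by one hash value per line.
#'
#' @param sketch A `kmer_sketch`.
#' @param path Output path.
#' @return `path` invisibly (`write_sketch`); a `kmer_sketch`
#'   (`read_sketch`).
#' @export
write_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  hdr <- sprintf("#anibench-sketch k=%d s=%d seed=%d canonical=%d id=%s",
                 sketch$config$k, sketch$s, sketch$config$hash_seed,
                 as.integer(sketch$config$canonical),
                 sketch$genome_id %||% "")
  writeLines(c(hdr, format(sketch$hashes, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#anibench-sketch")) {
    abort("not an anibench sketch file")
  }
  kv <- strsplit(sub("^#anibench-sketch ", "", lines[1]), " ")[[1]]
  vals <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  cfg <- kmer_config(k = as.integer(vals[["k"]]),
                     canonical = vals[["canonical"]] == "1",
                     hash_seed = as.integer(vals[["seed"]]))
  structure(
    list(config = cfg, s = as.integer(vals[["s"]]),
         genome_id = if (nzchar(vals[["id"]])) vals[["id"]] else NULL,
         hashes = as.numeric(lines[-1])),
    class = "kmer_sketch"
  )
}
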