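#' K-mer extraction configuration
#'
#' Settings shared by all k-mer set and sketch operations. Two k-mer sets or
#' sketches are only comparable when built under identical configurations.
#'
#' @param k K-mer length, an integer in 1..32 (Mash's default is 21).
#' @param canonical If `TRUE` (default, matching Mash) a k-mer and its reverse
#'   complement are collapsed to the lexicographically smaller 2-bit encoding,
#'   so strandedness of the assembly does not matter.
#' @param hash_seed Integer seed of the 64-bit hash. The hash is splitmix64
#'   over the 2-bit-packed k-mer xored with a seed-derived constant, truncated
#'   to its top 53 bits so values are exactly representable as R doubles.
#'   Fixed default so sketches are reproducible across sessions.
#' @return An object of class `kmer_config`.
#' @export
#' @examples
#' kmer_config(k = 21)
kmer_config <- function(k = 21L, canonical = TRUE, hash_seed = 42L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 32L) abort("k must be an integer in 1..32")
  stopifnot(is.logical(canonical), length(canonical) == 1L)
  structure(
    list(k = k, canonical = isTRUE(canonical), hash_seed = as.integer(hash_seed)),
    class = "kmer_config"
  )
}

#' @export
print.kmer_config <- function(x, ...) {
  cat(sprintf("<kmer_config> k=%d canonical=%s hash_seed=%d\n",
              x$k, x$canonical, x$hash_seed))
  invisible(x)
}

same_config <- function(a, b) {
  identical(a$k, b$k) && identical(a$canonical, b$canonical) &&
    identical(a$hash_seed, b$hash_seed)
}

#' Build the distinct-k-mer hash set of a genome
#'
#' Every distinct (canonical) k-mer counts once, regardless of multiplicity.
#' Windows containing any non-ACGT character are skipped. For multi-record
#' input the k-mers of all records are pooled and no window spans a record
#' boundary.
#'
#' @param seq A nucleotide string, a character vector of records (pooled), or
#'   a genome record with a `$seq` field. Case-insensitive.
#' @param config A [kmer_config()].
#' @param genome_id Optional label carried along for bookkeeping.
#' @return An object of class `kmer_set` with fields `config`, `genome_id`,
#'   `hashes` (sorted distinct hash values) and `n_distinct`.
#' @export
#' @examples
#' ks <- build_kmer_set("ACGTT", kmer_config(k = 3, canonical = FALSE))
#' ks$n_distinct
build_kmer_set <- function(seq, config = kmer_config(), genome_id = NULL) {
  stopifnot(inherits(config, "kmer_config"))
  seqs <- if (is.character(seq)) seq else as_genome(seq)$seq
  if (is.null(genome_id) && is.list(seq) && !is.null(seq$id)) genome_id <- seq$id
  h <- kmer_hashes_cpp(as.character(seqs), config$k, config$canonical,
                       as.double(config$hash_seed))
  structure(
    list(config = config, genome_id = genome_id, hashes = h,
         n_distinct = length(h)),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %s: %d distinct %d-mers (canonical=%s)\n",
              x$genome_id %||% "?", x$n_distinct, x$config$k,
              x$config$canonical))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Jaccard index of two k-mer sets
#'
#' The ratio of the number of distinct shared k-mers to the number of distinct
#' k-mers in either genome. By convention an empty union yields 0, flagged via
#' `attr(., "empty_union")`.
#'
#' @param a,b `kmer_set` objects built under the same configuration.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' cfg <- kmer_config(k = 3, canonical = FALSE)
#' exact_jaccard(build_kmer_set("ACGTT", cfg), build_kmer_set("CGTTA", cfg))
exact_jaccard <- function(a, b) {
  stopifnot(inherits(a, "kmer_set"), inherits(b, "kmer_set"))
  if (!same_config(a$config, b$config)) {
    abort("k-mer sets were built under different configurations")
  }
  inter <- sorted_intersection_size_cpp(a$hashes, b$hashes)
  uni <- a$n_distinct + b$n_distinct - inter
  if (uni == 0) {
    out <- 0
    attr(out, "empty_union") <- TRUE
    return(out)
  }
  inter / uni
}

#' Build a bottom-s MinHash sketch
#'
#' The sketch keeps the `s` smallest distinct hash values of the genome's
#' k-mer set (fewer if the genome has fewer distinct k-mers). Deterministic
#' given the hash seed.
#'
#' @inheritParams build_kmer_set
#' @param s Sketch size, an integer >= 1 (Mash's default is 1000).
#' @return An object of class `kmer_sketch` with fields `config`, `s`,
#'   `genome_id` and `hashes` (strictly increasing, length <= s).
#' @export
build_sketch <- function(seq, config = kmer_config(), s = 1000L,
                         genome_id = NULL) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) abort("sketch size s must be >= 1")
  ks <- build_kmer_set(seq, config, genome_id)
  structure(
    list(config = config, s = s, genome_id = ks$genome_id,
         hashes = head(ks$hashes, s)),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("<kmer_sketch> %s: %d/%d hashes, k=%d\n",
              x$genome_id %||% "?", length(x$hashes), x$s, x$config$k))
  invisible(x)
}

#' Sketched Jaccard estimate
#'
#' The default estimator is the merged-sketch form computed by the Mash tool:
#' take the `s` smallest values of the union of the two sketches and return
#' the fraction of those present in both sketches. `literal = TRUE` selects
#' instead the plain intersection-over-union of the two sketch hash lists.
#'
#' @param a,b `kmer_sketch` objects with the same configuration and `s`.
#' @param literal Use the literal intersection/union form instead of the
#'   merged-sketch estimator.
#' @return A number in \[0, 1\].
#' @export
sketch_jaccard <- function(a, b, literal = FALSE) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (!same_config(a$config, b$config) || a$s != b$s) {
    abort("sketches were built under different configurations")
  }
  if (length(a$hashes) == 0 && length(b$hashes) == 0) {
    out <- 0
    attr(out, "empty_union") <- TRUE
    return(out)
  }
  if (literal) {
    inter <- sorted_intersection_size_cpp(a$hashes, b$hashes)
    uni <- length(a$hashes) + length(b$hashes) - inter
    return(inter / uni)
  }
  merged <- head(sort(unique(c(a$hashes, b$hashes))), a$s)
  shared <- sorted_intersection_size_cpp(
    merged, sort(intersect(a$hashes, b$hashes))
  )
  shared / length(merged)
}

#' Mash index and distance from a Jaccard estimate
#'
#' Under the Poisson mutation model with unique, independent k-mers, the
#' expected fraction of mutated k-mers relates the (sketched) Jaccard J to the
#' per-base divergence d via `mash_index = 1 + log(2 J / (1 + J)) / k` and
#' `mash_distance = 1 - mash_index` (the number of mutations hitting a k-mer
#' is k d). At J = 0 the index diverges to -Inf; following the Mash
#' convention the result saturates at distance 1 / index 0 and is flagged.
#'
#' @param J Jaccard estimate(s) in \[0, 1\] (vectorised).
#' @param k The k-mer length used to compute `J`.
#' @return A tibble with columns `jaccard`, `mash_index`, `mash_distance`,
#'   `k`, `saturated`.
#' @export
#' @examples
#' mash_index(0.5, k = 21) # index = 1 + log(2/3)/21
mash_index <- function(J, k = 21L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("k must be >= 1")
  if (any(is.na(J)) || any(J < 0) || any(J > 1)) {
    abort("J must be in [0, 1]")
  }
  idx <- ifelse(J > 0, 1 + log(2 * J / (1 + J)) / k, 0)
  tibble::tibble(
    jaccard = as.numeric(J),
    mash_index = pmax(idx, 0),
    mash_distance = pmin(1 - idx, 1),
    k = k,
    saturated = J == 0 | idx < 0
  )
}

#' Fraction of the k-mer spectrum observed in a genome
#'
#' The number of distinct k-mers (forward strand, non-canonical) pooled over
#' the input sequences, divided by the number of possible k-mers 4^k
#' (computed in log space for large k).
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param k K-mer length.
#' @return A number in (0, 1\].
#' @export
#' @examples
#' kmer_spectrum_fraction("AACGT", 2) # 4 distinct 2-mers / 16
kmer_spectrum_fraction <- function(seqs, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 32L) abort("k must be an integer in 1..32")
  n <- kmer_distinct_count_cpp(as.character(seqs), k, FALSE)
  if (n == 0) return(0)
  exp(log(n) - k * log(4))
}

#' Pairwise k-mer distances over a genome set
#'
#' Computes Jaccard (exact or sketched) and the derived Mash index/distance
#' for every unordered pair in a genome set.
#'
#' @param genomes A tibble with columns `id` and `seq` (e.g. from
#'   [read_fasta()] or [simulate_dataset()]), a named character vector, or a
#'   `DNAStringSet`.
#' @param config A [kmer_config()].
#' @param mode `"exact"` (full k-mer sets) or `"sketch"` (bottom-s MinHash).
#' @param s Sketch size when `mode = "sketch"`.
#' @param literal Passed to [sketch_jaccard()].
#' @return A tibble with columns `query`, `reference`, `jaccard`,
#'   `mash_index`, `mash_distance` (one row per unordered pair, query <
#'   reference lexicographically).
#' @export
pairwise_kmer <- function(genomes, config = kmer_config(),
                          mode = c("exact", "sketch"), s = 1000L,
                          literal = FALSE) {
  mode <- match.arg(mode)
  g <- as_genome_tbl(genomes)
  if (nrow(g) < 2) abort("need at least two genomes")
  objs <- purrr::map2(g$seq, g$id, function(sq, id) {
    if (mode == "exact") build_kmer_set(sq, config, genome_id = id)
    else build_sketch(sq, config, s = s, genome_id = id)
  })
  names(objs) <- g$id
  pairs <- utils::combn(sort(g$id), 2)
  J <- purrr::map_dbl(seq_len(ncol(pairs)), function(i) {
    a <- objs[[pairs[1, i]]]
    b <- objs[[pairs[2, i]]]
    if (mode == "exact") exact_jaccard(a, b) else sketch_jaccard(a, b, literal)
  })
  m <- mash_index(J, config$k)
  tibble::tibble(
    query = pairs[1, ], reference = pairs[2, ],
    jaccard = m$jaccard, mash_index = m$mash_index,
    mash_distance = m$mash_distance
  )
}
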