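#' Build a pair table joining estimator values and tree distances
#'
#' Joins one column per method over the unordered genome pairs, after a
#' documented label normalization (directory and FASTA extension stripped).
#' Missing entries are kept as `NA` and flagged, never silently dropped.
#'
#' @param values A named list of per-method values; each element is either a
#'   long tibble with columns `query`, `reference` and one value column, or a
#'   labeled symmetric matrix. A single tibble carrying several value columns
#'   is also accepted.
#' @param tree_distances Optional `phylo` tree or labeled distance matrix;
#'   joined as column `tree_distance`.
#' @return A tibble with `query`, `reference` (query < reference), one column
#'   per method, optionally `tree_distance`, and a logical `complete` column
#'   flagging rows with no missing values.
#' @export
make_pair_table <- function(values, tree_distances = NULL) {
  if (is.data.frame(values)) values <- list(values)
  if (is.null(names(values))) {
    names(values) <- paste0("method_", seq_along(values))
  }
  as_long <- function(x, nm) {
    if (is.matrix(x)) return(dist_long(x, value = nm))
    stopifnot(is.data.frame(x))
    x <- tibble::as_tibble(x)
    stopifnot(all(c("query", "reference") %in% names(x)))
    vcols <- setdiff(names(x), c("query", "reference"))
    if (length(vcols) == 1 && nzchar(nm) && !grepl("^method_", nm)) {
      names(x)[names(x) == vcols] <- nm
    }
    x
  }
  longs <- purrr::imap(values, as_long)
  norm_pairs <- function(x) {
    q <- normalize_label(x$query)
    r <- normalize_label(x$reference)
    x$query <- pmin(q, r)
    x$reference <- pmax(q, r)
    x <- x[x$query != x$reference, , drop = FALSE] # drop self pairs
    dplyr::distinct(x, .data$query, .data$reference, .keep_all = TRUE)
  }
  longs <- purrr::map(longs, norm_pairs)
  labels <- sort(Reduce(union, purrr::map(longs, ~ union(.x$query, .x$reference))))
  if (!is.null(tree_distances)) {
    td <- tree_distance_matrix(tree_distances)
    rownames(td) <- normalize_label(rownames(td))
    colnames(td) <- normalize_label(colnames(td))
    labels <- intersect(labels, rownames(td))
  }
  if (length(labels) < 3) {
    abort("fewer than 3 genomes shared across inputs; correlation undefined")
  }
  pairs <- utils::combn(labels, 2)
  out <- tibble::tibble(query = pairs[1, ], reference = pairs[2, ])
  for (x in longs) out <- dplyr::left_join(out, x, by = c("query", "reference"))
  if (!is.null(tree_distances)) {
    td <- tree_distance_matrix(tree_distances)
    rownames(td) <- normalize_label(rownames(td))
    colnames(td) <- normalize_label(colnames(td))
    out$tree_distance <- td[cbind(out$query, out$reference)]
  }
  out$complete <- stats::complete.cases(out)
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Tie-aware Spearman rank correlation with log-space p-values
#'
#' Ranks use average-rank tie handling; rho is the Pearson correlation of the
#' ranks. For n > 8 the p-value uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` with the tail evaluated in log space, so
#' extremely small p-values (log10 p near -300) are representable without
#' underflow; |rho| = 1 saturates at log10 p = -320, flagged. For n <= 8 an
#' exact permutation p-value is computed instead. A constant input vector
#' yields a flagged result with `rho = NA`.
#'
#' @param x A numeric vector, or a data frame (then `y` names two columns).
#' @param y A numeric vector, or (with a data frame `x`) unused; see `cols`.
#' @param cols When `x` is a data frame: a character vector of the two column
#'   names to correlate.
#' @param alternative `"two_sided"` (default) or `"negative"` (one-sided,
#'   the expected direction for a similarity vs a tree distance).
#' @return An object of class `rank_eval` with fields `rho`, `log10_p`, `n`,
#'   `alternative`, `method`, `flags`.
#' @export
#' @examples
#' spearman_log10p(c(1, 2, 3), c(3, 2, 1))$rho # -1
spearman_log10p <- function(x, y = NULL, cols = NULL,
                            alternative = c("two_sided", "negative")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) {
    stopifnot(length(cols) == 2)
    y <- x[[cols[2]]]
    x <- x[[cols[1]]]
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(new_rank_eval(NA_real_, NA_real_, n, alternative,
                         flags = "constant_input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  flags <- character(0)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    eps <- 1e-12
    p <- if (alternative == "two_sided") {
      mean(abs(rhos) >= abs(rho) - eps)
    } else {
      mean(rhos <= rho + eps)
    }
    log10_p <- log10(p)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      log10_p <- -320
      flags <- c(flags, "rho_saturated")
      method <- "t approximation (capped)"
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      lp_one <- pt(-abs(tstat), df = n - 2, log.p = TRUE)
      lp <- if (alternative == "two_sided") log(2) + lp_one
            else pt(tstat, df = n - 2, log.p = TRUE)
      log10_p <- max(lp / log(10), -320)
      if (log10_p <= -320) flags <- c(flags, "log10p_capped")
      method <- "t approximation"
    }
  }
  new_rank_eval(rho, log10_p, n, alternative, method = method, flags = flags)
}

new_rank_eval <- function(rho, log10_p, n, alternative,
                          method = "t approximation", flags = character(0)) {
  structure(
    list(rho = rho, log10_p = log10_p, n = n, alternative = alternative,
         method = method, flags = flags),
    class = "rank_eval"
  )
}

#' @export
print.rank_eval <- function(x, ...) {
  cat(sprintf("<rank_eval> rho = %.4f, log10 p = %.2f, n = %d (%s, %s)\n",
              x$rho, x$log10_p, x$n, x$alternative, x$method))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rank_eval <- function(x, ...) {
  tibble::tibble(rho = x$rho, log10_p = x$log10_p, n = x$n,
                 alternative = x$alternative, method = x$method)
}

#' @exportS3Method generics::glance
glance.rank_eval <- function(x, ...) tidy(x)

#' Merge two rankings by rank averaging
#'
#' Ranks each value column (average-rank ties), averages the two rank
#' vectors element-wise, and re-ranks the averages - the bi-k merged ranking
#' used to combine the complementary information of a short and a long k-mer
#' length.
#'
#' @param values_k1,values_k2 Numeric vectors over the same pairs, in the
#'   same order.
#' @return A numeric vector of merged ranks, directly usable in
#'   [spearman_log10p()].
#' @export
merged_rank_distance <- function(values_k1, values_k2) {
  if (length(values_k1) != length(values_k2)) {
    abort("the two value vectors must have equal length")
  }
  if (anyNA(values_k1) || anyNA(values_k2)) {
    abort("merged ranking requires complete columns")
  }
  rank((rank(values_k1) + rank(values_k2)) / 2)
}

#' Spearman statistics across a k-mer length sweep
#'
#' Computes the pairwise (exact or sketched) Jaccard at each k and its
#' Spearman correlation against the tree distance. Similarities are expected
#' to correlate negatively with tree distance; values are reported unchanged
#' (rho < 0 is the good direction).
#'
#' @param genomes A genome set (tibble with `id`, `seq`).
#' @param ks Integer vector of k-mer lengths.
#' @param tree A `phylo` tree or labeled distance matrix.
#' @param mode `"exact"` or `"sketch"`.
#' @param s Sketch size for `mode = "sketch"`.
#' @param canonical,hash_seed Passed to [kmer_config()].
#' @param alternative Passed to [spearman_log10p()].
#' @return A tibble of class `k_sweep` with columns `k`, `rho`, `log10_p`,
#'   `n`; attributes `best_k` (argmin of log10_p) and `local_minima`
#'   (interior local minima of the log10_p curve).
#' @export
k_sweep <- function(genomes, ks, tree, mode = c("exact", "sketch"),
                    s = 1000L, canonical = TRUE, hash_seed = 42L,
                    alternative = "two_sided") {
  mode <- match.arg(mode)
  g <- as_genome_tbl(genomes)
  td <- tree_distance_matrix(tree)
  rows <- purrr::map(ks, function(k) {
    cfg <- kmer_config(k = k, canonical = canonical, hash_seed = hash_seed)
    pk <- pairwise_kmer(g, cfg, mode = mode, s = s)
    pt <- make_pair_table(list(jaccard = pk[c("query", "reference", "jaccard")]),
                          tree_distances = td)
    ev <- spearman_log10p(pt$jaccard, pt$tree_distance,
                          alternative = alternative)
    tibble::tibble(k = as.integer(k), rho = ev$rho, log10_p = ev$log10_p,
                   n = ev$n)
  })
  out <- dplyr::bind_rows(rows)
  lp <- out$log10_p
  interior <- which(diff(sign(diff(lp))) > 0) + 1L # local minima of log10_p
  structure(
    out,
    class = c("k_sweep", class(out)),
    best_k = out$k[which.min(lp)],
    local_minima = out$k[interior]
  )
}

#' Rank agreement between two estimators
#'
#' Spearman correlation between two estimator columns after orientation
#' normalization: two similarities (or two distances) are compared directly;
#' a similarity against a distance is compared after negating the distance,
#' so perfect agreement is always rho = 1.
#'
#' @param values_a,values_b Numeric vectors over the same pairs.
#' @param orientation_a,orientation_b `"similarity"` or `"distance"`.
#' @param alternative Passed to [spearman_log10p()].
#' @return A `rank_eval`.
#' @export
tool_agreement <- function(values_a, values_b,
                           orientation_a = "similarity",
                           orientation_b = "similarity",
                           alternative = "two_sided") {
  ornt <- function(v, o) {
    o <- match.arg(o, c("similarity", "distance"))
    if (o == "distance") -v else v
  }
  spearman_log10p(ornt(values_a, orientation_a),
                  ornt(values_b, orientation_b),
                  alternative = alternative)
}
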