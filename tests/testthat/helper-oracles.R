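# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package (naive enumeration, quadratic DP,
# exhaustive subset search) so that agreement is informative.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All maximal exact matches by longest-common-extension enumeration.
oracle_mems <- function(q, r, min_len) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  nq <- length(qc); nr <- length(rc)
  lce <- matrix(0L, nq + 1L, nr + 1L)
  for (i in nq:1) {
    ext <- lce[i + 1L, 2:(nr + 1L)] + 1L
    lce[i, 1:nr] <- ifelse(qc[i] == rc, ext, 0L)
  }
  rows <- list()
  for (i in seq_len(nq)) {
    for (j in seq_len(nr)) {
      len <- lce[i, j]
      if (len >= min_len && (i == 1L || j == 1L || qc[i - 1L] != rc[j - 1L])) {
        rows[[length(rows) + 1L]] <- c(i - 1L, j - 1L, len)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(q_start = integer(0), r_start = integer(0),
                          length = integer(0)))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(q_start = m[, 1], r_start = m[, 2], length = m[, 3])
  dplyr::arrange(out, q_start, r_start, length)
}

count_substring <- function(s, pat) {
  n <- nchar(s); L <- nchar(pat)
  if (L > n) return(0L)
  starts <- seq_len(n - L + 1L)
  sum(substring(s, starts, starts + L - 1L) == pat)
}

oracle_mums <- function(q, r, min_len) {
  mems <- oracle_mems(q, r, min_len)
  keep <- vapply(seq_len(nrow(mems)), function(i) {
    pat <- substr(q, mems$q_start[i] + 1L, mems$q_start[i] + mems$length[i])
    count_substring(q, pat) == 1L && count_substring(r, pat) == 1L
  }, logical(1))
  mems[keep, , drop = FALSE]
}

# Exhaustive maximum chain weight over all collinear subsets with bounded
# gaps (anchors as a tibble with q_start, r_start, length).
oracle_chain_weight <- function(anchors, max_gap) {
  n <- nrow(anchors)
  qs <- anchors$q_start; rs <- anchors$r_start; len <- anchors$length
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    idx <- idx[order(qs[idx], rs[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (t in seq_len(length(idx) - 1L)) {
        i <- idx[t]; j <- idx[t + 1L]
        gq <- qs[j] - (qs[i] + len[i])
        gr <- rs[j] - (rs[i] + len[i])
        if (gq < 0 || gr < 0 || gq > max_gap || gr > max_gap) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(len[idx]))
  }
  best
}

# Exhaustive maximum weight over subsets of hits that are pairwise
# non-overlapping on both axes; weight = aligned_cols * identity.
oracle_one_to_one_weight <- function(hits) {
  n <- nrow(hits)
  w <- hits$aligned_cols * hits$identity
  ov <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    ok <- TRUE
    if (length(idx) > 1) {
      cmb <- utils::combn(idx, 2)
      for (t in seq_len(ncol(cmb))) {
        i <- cmb[1, t]; j <- cmb[2, t]
        if (ov(hits$q_start[i], hits$q_end[i], hits$q_start[j], hits$q_end[j]) ||
            ov(hits$r_start[i], hits$r_end[i], hits$r_start[j], hits$r_end[j])) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(w[idx]))
  }
  best
}

# Full quadratic Smith-Waterman (affine gaps) returning the best local score.
oracle_local_score <- function(a, b, sc) {
  A <- utf8ToInt(toupper(a)); B <- utf8ToInt(toupper(b))
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + sc$gap_open + sc$gap_extend,
                     E[i, j - 1] + sc$gap_extend)
      FF[i, j] <- max(H[i - 1, j] + sc$gap_open + sc$gap_extend,
                      FF[i - 1, j] + sc$gap_extend)
      s <- if (A[i - 1] == B[j - 1]) sc$match else sc$mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], perms_of(v[-i]))
  }))
}

# Exact two-sided permutation p for Spearman rho, independent of the package
# internals (uses stats::cor with method = "spearman").
oracle_spearman_perm <- function(x, y, alternative = "two_sided") {
  rho <- stats::cor(x, y, method = "spearman")
  pm <- perms_of(seq_along(y))
  rhos <- apply(pm, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  eps <- 1e-12
  if (alternative == "two_sided") mean(abs(rhos) >= abs(rho) - eps)
  else mean(rhos <= rho + eps)
}

# Patristic distances via leaf depths and MRCA depths (independent of
# cophenetic): d(i, j) = depth(i) + depth(j) - 2 depth(mrca(i, j)).
oracle_patristic <- function(tree) {
  dep <- ape::node.depth.edgelength(tree)
  tips <- tree$tip.label
  n <- length(tips)
  mr <- ape::mrca(tree)
  m <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- dep[i] + dep[j] - 2 * dep[mr[i, j]]
    }
  }
  m
}

# A small evolved genome pair sharing an ancestor, for convergence checks.
make_related_pair <- function(len = 30000, branch = 10, seed = 1) {
  cfg <- sim_config(n_leaves = 2, n_genes = 1L, gene_len = as.integer(len),
                    root_to_leaf_len = branch, seed = seed, indel_rate = 0)
  set.seed(seed)
  root <- generate_root_genome(cfg, seed = seed)
  a <- evolve_branch(root, branch, cfg)$genome
  b <- evolve_branch(root, branch, cfg)$genome
  list(a = genome_seq(a), b = genome_seq(b))
}
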