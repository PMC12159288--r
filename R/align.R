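#' Alignment scoring scheme
#'
#' Match reward and (non-positive) mismatch / affine gap penalties used by all
#' alignment-based estimators. The defaults are blastn-like: +1 match, -2
#' mismatch, -5 gap open, -2 gap extend. A gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param match Positive match reward.
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Gap opening penalty (<= 0), charged once per gap.
#' @param gap_extend Gap extension penalty (<= 0), charged per gap base.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) abort("match reward must be positive")
  if (mismatch > 0L || gap_open > 0L || gap_extend > 0L) {
    abort("mismatch and gap penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

hit_tibble <- function(lst, query_id = NA_character_, ref_id = NA_character_,
                       strand = "+") {
  cols <- lst$aligned_cols
  tibble::tibble(
    query_id = query_id, ref_id = ref_id,
    q_start = lst$a_start, q_end = lst$a_end,
    r_start = lst$b_start, r_end = lst$b_end,
    strand = strand,
    matches = lst$matches, aligned_cols = cols,
    identity = if (cols > 0) lst$matches / cols else 0,
    score = lst$score
  )
}

#' Banded local alignment of two sequences
#'
#' Best-scoring local alignment under an affine-gap scheme, optionally
#' restricted to a diagonal band. `band = 0` runs the full quadratic dynamic
#' program. Degenerate inputs yield an empty hit with identity 0.
#'
#' @param a,b Nucleotide strings.
#' @param scoring A [scoring_scheme()].
#' @param band Half-width of the band around `diag`; 0 means no banding.
#' @param diag Center diagonal (offset `j - i`) of the band.
#' @return A one-row tibble (an alignment hit) with 0-based half-open
#'   intervals `q_start`/`q_end` (on `a`), `r_start`/`r_end` (on `b`),
#'   `matches`, `aligned_cols`, `identity` and `score`.
#' @export
local_align_banded <- function(a, b, scoring = scoring_scheme(), band = 0L,
                               diag = 0L) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  if (band < 0) abort("band must be >= 0")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(hit_tibble(list(score = 0L, a_start = 0L, a_end = 0L, b_start = 0L,
                           b_end = 0L, matches = 0L, aligned_cols = 0L)))
  }
  res <- align_pair_cpp(a, b, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend, TRUE,
                        as.integer(band), as.integer(diag))
  hit_tibble(res)
}

#' Find maximal exact matches (MEMs) or maximal unique matches (MUMs)
#'
#' Exact matches of length >= `min_len` between `q` and both strands of `r`
#' that cannot be extended on either side. In `mum` mode only matches whose
#' matched substring occurs exactly once in the query and once in the searched
#' reference strand are kept, as in NUCmer's MUM anchoring (the `mem` mode
#' corresponds to NUCmer's maxmatch behaviour).
#'
#' Coordinates are 0-based; `r_start` is given on the searched strand (i.e. on
#' the reverse complement of `r` for `-` anchors), which keeps minus-strand
#' anchor sets collinear for chaining. The forward-strand interval of a minus
#' anchor is `[len_r - r_start - length, len_r - r_start)`.
#'
#' @param q,r Nucleotide strings.
#' @param min_len Minimum match length (>= 1).
#' @param mode `"mem"` or `"mum"`.
#' @param both_strands Search the reverse complement of `r` too (default).
#' @return A tibble of anchors: `q_start`, `r_start`, `length`, `strand`,
#'   `unique_in_query`, `unique_in_reference`.
#' @export
#' @examples
#' find_maximal_matches("ACGTACGT", "TTACGTTT", min_len = 4,
#'                      mode = "mem", both_strands = FALSE)
find_maximal_matches <- function(q, r, min_len, mode = c("mem", "mum"),
                                 both_strands = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.character(q), is.character(r), length(q) == 1L,
            length(r) == 1L)
  if (min_len < 1) abort("min_len must be >= 1")
  mum <- mode == "mum"
  fwd <- tibble::as_tibble(find_mems_cpp(q, r, as.integer(min_len), mum))
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (both_strands && nchar(r) >= min_len) {
    rev <- tibble::as_tibble(find_mems_cpp(q, revcomp(r),
                                           as.integer(min_len), mum))
    if (nrow(rev) > 0) {
      rev$strand <- "-"
      out <- dplyr::bind_rows(fwd, rev)
    }
  }
  out$unique_in_query <- if (mum) rep(TRUE, nrow(out)) else rep(NA, nrow(out))
  out$unique_in_reference <- out$unique_in_query
  out
}

best_chain <- function(anc, max_gap) {
  # weighted longest-increasing-subsequence over anchors sorted by q_start;
  # weight = anchor length
  n <- nrow(anc)
  ord <- order(anc$q_start, anc$r_start)
  anc <- anc[ord, ]
  qs <- anc$q_start; rs <- anc$r_start
  qe <- qs + anc$length
  re <- rs + anc$length
  w <- as.numeric(anc$length)
  best <- w
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)[-1]) {
    i <- seq_len(j - 1L)
    gq <- qs[j] - qe[i]
    gr <- rs[j] - re[i]
    ok <- gq >= 0 & gr >= 0 & gq <= max_gap & gr <= max_gap
    if (any(ok)) {
      cand <- best[i]
      cand[!ok] <- -Inf
      bi <- which.max(cand)
      if (cand[bi] + w[j] > best[j]) {
        best[j] <- cand[bi] + w[j]
        prev[j] <- bi
      }
    }
  }
  end <- which.max(best)
  idx <- integer(0)
  while (!is.na(end)) {
    idx <- c(end, idx)
    end <- prev[end]
  }
  list(anchors = anc[idx, , drop = FALSE], weight = max(best))
}

#' Chain anchors into collinear clusters
#'
#' Partitions anchors from one (query, reference, strand) triple into
#' collinear clusters: within a cluster, anchors increase in both coordinates
#' and consecutive anchors are separated by at most `max_gap` on both axes.
#' Chains are extracted greedily by repeatedly taking the chain that
#' maximizes total anchor length (weighted longest increasing subsequence),
#' removing its anchors, and repeating.
#'
#' @param anchors A tibble of anchors as from [find_maximal_matches()], all on
#'   one strand.
#' @param max_gap Maximum coordinate gap between consecutive anchors (NUCmer's
#'   documented cluster gap default is 90).
#' @return A list of anchor tibbles (clusters), ordered by decreasing total
#'   anchor length.
#' @export
chain_anchors <- function(anchors, max_gap = 90L) {
  stopifnot(is.data.frame(anchors))
  if (nrow(anchors) == 0) return(list())
  if (length(unique(anchors$strand %||% "+")) > 1) {
    abort("chain_anchors expects anchors from a single strand")
  }
  remaining <- anchors
  clusters <- list()
  while (nrow(remaining) > 0) {
    ch <- best_chain(remaining, max_gap)
    clusters[[length(clusters) + 1L]] <- ch$anchors
    key_all <- paste(remaining$q_start, remaining$r_start, remaining$length)
    key_used <- paste(ch$anchors$q_start, ch$anchors$r_start,
                      ch$anchors$length)
    remaining <- remaining[!(key_all %in% key_used), , drop = FALSE]
  }
  clusters
}

#' Extend a cluster of anchors into a single alignment
#'
#' Anchors contribute exact-match columns; the gaps between consecutive
#' anchors are closed with banded global alignment (band = difference of the
#' two gap lengths + 20). The hit spans the cluster from the first to the
#' last anchor. For minus-strand clusters the reported `r_start`/`r_end` are
#' mapped back to forward-strand coordinates of `r`.
#'
#' @param q,r Nucleotide strings (forward strands).
#' @param cluster An anchor tibble from [chain_anchors()].
#' @param scoring A [scoring_scheme()].
#' @return A one-row alignment-hit tibble as in [local_align_banded()].
#' @export
extend_cluster_to_alignment <- function(q, r, cluster,
                                        scoring = scoring_scheme()) {
  stopifnot(nrow(cluster) >= 1)
  strand <- cluster$strand[1] %||% "+"
  r_aln <- if (identical(strand, "-")) revcomp(r) else r
  cluster <- cluster[order(cluster$q_start), , drop = FALSE]
  matches <- sum(cluster$length)
  cols <- sum(cluster$length)
  n <- nrow(cluster)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      qg_from <- cluster$q_start[i] + cluster$length[i]
      qg_to <- cluster$q_start[i + 1L]
      rg_from <- cluster$r_start[i] + cluster$length[i]
      rg_to <- cluster$r_start[i + 1L]
      dq <- qg_to - qg_from
      dr <- rg_to - rg_from
      if (dq == 0 && dr == 0) next
      if (dq == 0 || dr == 0) {
        cols <- cols + max(dq, dr) # pure gap between anchors
        next
      }
      band <- abs(dq - dr) + 20L
      sub_q <- substr(q, qg_from + 1L, qg_to)
      sub_r <- substr(r_aln, rg_from + 1L, rg_to)
      res <- align_pair_cpp(sub_q, sub_r, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend, FALSE,
                            as.integer(band), as.integer(dr - dq) %/% 2L)
      matches <- matches + res$matches
      cols <- cols + res$aligned_cols
    }
  }
  q_start <- cluster$q_start[1]
  q_end <- cluster$q_start[n] + cluster$length[n]
  rs <- cluster$r_start[1]
  re <- cluster$r_start[n] + cluster$length[n]
  if (identical(strand, "-")) {
    lr <- nchar(r)
    tmp <- lr - re
    re <- lr - rs
    rs <- tmp
  }
  tibble::tibble(
    query_id = NA_character_, ref_id = NA_character_,
    q_start = q_start, q_end = q_end, r_start = rs, r_end = re,
    strand = strand, matches = matches, aligned_cols = cols,
    identity = if (cols > 0) matches / cols else 0,
    score = NA_integer_
  )
}

intervals_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

hits_compatible <- function(h, i, j) {
  !intervals_overlap(h$q_start[i], h$q_end[i], h$q_start[j], h$q_end[j]) &&
    !intervals_overlap(h$r_start[i], h$r_end[i], h$r_start[j], h$r_end[j])
}

# Exact max-weight subset of mutually compatible hits via branch and bound.
best_one_to_one_exact <- function(h, w) {
  n <- nrow(h)
  ord <- order(w, decreasing = TRUE)
  h <- h[ord, , drop = FALSE]
  w <- w[ord]
  comp <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) comp[i, j] <- hits_compatible(h, i, j)
    }
  }
  suffix <- rev(cumsum(rev(w)))
  best_w <- 0
  best_set <- integer(0)
  recurse <- function(i, cur, cur_w) {
    if (cur_w > best_w) {
      best_w <<- cur_w
      best_set <<- cur
    }
    if (i > n) return()
    if (cur_w + suffix[i] <= best_w) return() # bound
    ok <- all(comp[cur, i]) || length(cur) == 0
    if (ok) recurse(i + 1L, c(cur, i), cur_w + w[i])
    recurse(i + 1L, cur, cur_w)
  }
  recurse(1L, integer(0), 0)
  h[sort(best_set), , drop = FALSE]
}

#' One-to-one filtering of alignment hits
#'
#' Emulates `delta-filter -1`: retains a subset of hits that are mutually
#' non-overlapping on the query axis and on the reference axis, maximizing
#' the total weight `aligned_cols * identity` (= matched bases). For up to 25
#' hits the optimum is found exactly (branch and bound); beyond that a greedy
#' weight-ordered selection is used.
#'
#' @param hits A tibble of alignment hits for one genome pair.
#' @return The retained hits, in query order.
#' @export
filter_one_to_one <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) <= 1) return(hits)
  w <- hits$aligned_cols * hits$identity
  if (nrow(hits) <= 25) {
    out <- best_one_to_one_exact(hits, w)
  } else {
    ord <- order(w, decreasing = TRUE)
    keep <- integer(0)
    for (i in ord) {
      ok <- all(vapply(keep, function(j) hits_compatible(hits, i, j),
                       logical(1)))
      if (ok) keep <- c(keep, i)
    }
    out <- hits[sort(keep), , drop = FALSE]
  }
  out[order(out$q_start), , drop = FALSE]
}

# Total length covered by a union of half-open intervals.
interval_union_len <- function(s, e) {
  if (length(s) == 0) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

ani_result <- function(ani, af, n_hits, method, params = list(),
                       zero_hits = FALSE) {
  tibble::tibble(
    ani = ani, af = af, ani_af = ani * af, n_hits = n_hits,
    method = method, zero_hits = zero_hits
  )
}

#' ANIm-style distance via MEM/MUM anchoring
#'
#' NUCmer-like pipeline: find maximal (unique) exact matches on both strands,
#' chain them into collinear clusters, extend each cluster into an alignment
#' by closing inter-anchor gaps with banded global alignment, optionally
#' apply 1-to-1 filtering (delta-filter -1 semantics), and summarize.
#' ANI is the alignment-length-weighted percent identity over retained hits;
#' AF is (aligned query bases + aligned reference bases) / (len q + len r).
#' Zero retained hits yield ANI 0 / AF 0 with `zero_hits = TRUE` - the
#' characteristic failure mode of MUM anchoring on distant genomes.
#'
#' @param q,r Genomes (strings, records, or one-row genome tibbles).
#' @param min_match_len Minimum anchor length (NUCmer default 20; lowering it
#'   increases sensitivity on distant genomes).
#' @param mode `"mum"` (anchors unique in both genomes) or `"mem"`
#'   (all maximal matches, NUCmer's maxmatch).
#' @param one_to_one Apply [filter_one_to_one()] to the extended hits.
#' @param scoring A [scoring_scheme()].
#' @param max_gap Cluster gap bound for [chain_anchors()].
#' @param min_cluster_len Discard clusters whose total anchor length is below
#'   this (NUCmer's cluster length default is 65).
#' @return A one-row tibble: `ani`, `af`, `ani_af`, `n_hits`, `method`,
#'   `zero_hits`.
#' @export
anim_distance <- function(q, r, min_match_len = 20L, mode = c("mum", "mem"),
                          one_to_one = TRUE, scoring = scoring_scheme(),
                          max_gap = 90L, min_cluster_len = 65L) {
  mode <- match.arg(mode)
  qg <- as_genome(q, "query"); rg <- as_genome(r, "reference")
  if (nchar(qg$seq) == 0 || nchar(rg$seq) == 0) abort("empty genome")
  anchors <- find_maximal_matches(qg$seq, rg$seq, min_match_len, mode)
  hits <- NULL
  if (nrow(anchors) > 0) {
    hits <- dplyr::bind_rows(lapply(split(anchors, anchors$strand), function(a) {
      cl <- chain_anchors(a, max_gap)
      cl <- cl[vapply(cl, function(x) sum(x$length), 0) >= min_cluster_len]
      dplyr::bind_rows(lapply(cl, function(x) {
        extend_cluster_to_alignment(qg$seq, rg$seq, x, scoring)
      }))
    }))
  }
  if (is.null(hits) || nrow(hits) == 0) {
    return(ani_result(0, 0, 0L, "anim", zero_hits = TRUE))
  }
  if (one_to_one) hits <- filter_one_to_one(hits)
  ani <- 100 * sum(hits$matches) / sum(hits$aligned_cols)
  qb <- interval_union_len(hits$q_start, hits$q_end)
  rb <- interval_union_len(hits$r_start, hits$r_end)
  af <- (qb + rb) / (nchar(qg$seq) + nchar(rg$seq))
  out <- ani_result(ani, af, nrow(hits), "anim")
  attr(out, "hits") <- hits
  out
}

split_fragments <- function(seq, frag_len, min_trailing = 100L) {
  L <- nchar(seq)
  starts <- seq(1L, L, by = frag_len)
  ends <- pmin(starts + frag_len - 1L, L)
  keep <- (ends - starts + 1L) >= min_trailing | (ends - starts + 1L) == frag_len
  starts <- starts[keep]; ends <- ends[keep]
  # full fragments always pass; trailing fragment kept only if >= min_trailing
  tibble::tibble(start = starts - 1L, end = ends,
                 seq = substring(seq, starts, ends))
}

best_hit_both_strands <- function(frag, ref, scoring, seed_len, band) {
  fw <- best_fragment_hit_cpp(frag, ref, seed_len, band, 3L, scoring$match,
                              scoring$mismatch, scoring$gap_open,
                              scoring$gap_extend)
  rv <- best_fragment_hit_cpp(frag, revcomp(ref), seed_len, band, 3L,
                              scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend)
  if (rv$score > fw$score) {
    lr <- nchar(ref)
    tmp <- lr - rv$b_end
    rv$b_end <- lr - rv$b_start
    rv$b_start <- tmp
    rv$strand <- "-"
    rv
  } else {
    fw$strand <- "+"
    fw
  }
}

#' ANIb-style fragment ANI
#'
#' The query is split into consecutive non-overlapping fragments (default
#' 1020 bp; a trailing fragment is kept if at least 100 bp). Each fragment's
#' best local alignment against either strand of the reference (seeded by
#' shared 11-mers, banded extension) is retained iff its identity exceeds
#' `min_identity` and its aligned coverage of the fragment exceeds
#' `min_coverage` - the classical ">30% identity over >70% of the length"
#' rule. ANI is the unweighted mean identity (x100) of retained fragments;
#' AF is the retained-fragment bases divided by the query length. Note the
#' method is asymmetric in (q, r).
#'
#' @inheritParams anim_distance
#' @param frag_len Fragment length (>= 100; classical value 1020).
#' @param min_identity Identity threshold (fraction, default 0.30).
#' @param min_coverage Fragment coverage threshold (fraction, default 0.70).
#' @param seed_len Seed word length for candidate diagonal detection.
#' @param band Band half-width for the seeded extension.
#' @return A one-row tibble: `ani`, `af`, `ani_af`, `n_hits`, `method`,
#'   `zero_hits`.
#' @export
anib_distance <- function(q, r, frag_len = 1020L, min_identity = 0.30,
                          min_coverage = 0.70, scoring = scoring_scheme(),
                          seed_len = 11L, band = 50L) {
  if (frag_len < 100) abort("frag_len must be >= 100")
  qg <- as_genome(q, "query"); rg <- as_genome(r, "reference")
  if (nchar(qg$seq) == 0 || nchar(rg$seq) == 0) abort("empty genome")
  frags <- split_fragments(qg$seq, as.integer(frag_len))
  if (nrow(frags) == 0) return(ani_result(0, 0, 0L, "anib", zero_hits = TRUE))
  ids <- numeric(0)
  kept_bases <- 0
  for (i in seq_len(nrow(frags))) {
    hit <- best_hit_both_strands(frags$seq[i], rg$seq, scoring, seed_len, band)
    if (hit$aligned_cols == 0) next
    identity <- hit$matches / hit$aligned_cols
    coverage <- (hit$a_end - hit$a_start) / nchar(frags$seq[i])
    if (identity > min_identity && coverage > min_coverage) {
      ids <- c(ids, identity)
      kept_bases <- kept_bases + nchar(frags$seq[i])
    }
  }
  if (length(ids) == 0) return(ani_result(0, 0, 0L, "anib", zero_hits = TRUE))
  ani_result(100 * mean(ids), kept_bases / nchar(qg$seq), length(ids), "anib")
}

#' OrthoANI-style reciprocal-best-hit fragment ANI
#'
#' Both genomes are split into fragments (default 1020 bp). Each fragment is
#' aligned against the whole other genome (both strands, seeded banded local
#' alignment); its partner is the fragment of the other genome containing the
#' midpoint of its best hit. Only reciprocal best pairs - fragment pairs that
#' choose each other in both directions - contribute, each with the mean of
#' its two directional identities. ANI is the mean (x100) over reciprocal
#' pairs; AF is the paired-fragment bases over the summed genome lengths.
#' Symmetric in (a, b) by construction. A best hit is only eligible as a
#' partner when its alignment covers at least `min_coverage` of the fragment
#' (the OrthoANI rule, 35%), which keeps short spurious perfect matches
#' between unrelated fragments from inflating the mean identity.
#'
#' @inheritParams anib_distance
#' @param a,b Genomes (strings, records, or one-row genome tibbles).
#' @param min_coverage Minimum aligned fraction of a fragment for its best
#'   hit to count (default 0.35).
#' @return A one-row tibble: `ani`, `af`, `ani_af`, `n_hits`, `method`,
#'   `zero_hits`.
#' @export
orthoani_distance <- function(a, b, frag_len = 1020L,
                              scoring = scoring_scheme(), seed_len = 11L,
                              band = 50L, min_coverage = 0.35) {
  if (frag_len < 100) abort("frag_len must be >= 100")
  ag <- as_genome(a, "a"); bg <- as_genome(b, "b")
  if (nchar(ag$seq) == 0 || nchar(bg$seq) == 0) abort("empty genome")
  fa <- split_fragments(ag$seq, as.integer(frag_len))
  fb <- split_fragments(bg$seq, as.integer(frag_len))
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    return(ani_result(0, 0, 0L, "orthoani", zero_hits = TRUE))
  }
  direction <- function(frags, other_seq) {
    purrr::map(seq_len(nrow(frags)), function(i) {
      hit <- best_hit_both_strands(frags$seq[i], other_seq, scoring,
                                   seed_len, band)
      if (hit$aligned_cols == 0) return(NULL)
      if ((hit$a_end - hit$a_start) / nchar(frags$seq[i]) < min_coverage) {
        return(NULL)
      }
      mid <- (hit$b_start + hit$b_end) / 2
      list(partner = floor(mid / frag_len) + 1L,
           identity = hit$matches / hit$aligned_cols,
           score = hit$score)
    })
  }
  ab <- direction(fa, bg$seq)
  ba <- direction(fb, ag$seq)
  ids <- numeric(0)
  paired_a <- integer(0); paired_b <- integer(0)
  for (i in seq_along(ab)) {
    h <- ab[[i]]
    if (is.null(h)) next
    j <- h$partner
    if (j >= 1 && j <= length(ba) && !is.null(ba[[j]]) &&
        ba[[j]]$partner == i) {
      ids <- c(ids, (h$identity + ba[[j]]$identity) / 2)
      paired_a <- c(paired_a, i); paired_b <- c(paired_b, j)
    }
  }
  if (length(ids) == 0) {
    return(ani_result(0, 0, 0L, "orthoani", zero_hits = TRUE))
  }
  bases <- sum(nchar(fa$seq[paired_a])) + sum(nchar(fb$seq[unique(paired_b)]))
  af <- bases / (nchar(ag$seq) + nchar(bg$seq))
  ani_result(100 * mean(ids), af, length(ids), "orthoani")
}

#' Digital-DDH distance formulas
#'
#' The three pairwise distances used by digital DDH, computed from a pool of
#' local alignment hits (both comparison directions pooled by the caller):
#' `d1 = 1 - total alignment length / (len_q + len_r)` (one minus the
#' alignment fraction), `d2 = 1 - identical bases / total alignment length`,
#' `d3 = 1 - identical bases / (len_q + len_r)`. With no alignments d2 is
#' undefined and returned as `NA` with `d2_missing = TRUE`.
#'
#' @param hits A tibble of alignment hits with `matches` and `aligned_cols`.
#' @param len_q,len_r Genome lengths in bases.
#' @return A one-row tibble: `d1`, `d2`, `d3`, `d2_missing`.
#' @export
#' @examples
#' h <- tibble::tibble(matches = 900, aligned_cols = 1000)
#' ddh_distances(h, 1000, 1000) # d1 = 0.5, d2 = 0.1, d3 = 0.55
ddh_distances <- function(hits, len_q, len_r) {
  stopifnot(is.data.frame(hits))
  tot <- sum(hits$aligned_cols)
  ident <- sum(hits$matches)
  denom <- len_q + len_r
  tibble::tibble(
    d1 = 1 - tot / denom,
    d2 = if (tot > 0) 1 - ident / tot else NA_real_,
    d3 = 1 - ident / denom,
    d2_missing = tot == 0
  )
}

#' Pairwise alignment-based ANI over a genome set
#'
#' Runs one of the alignment-based estimators on every unordered genome pair.
#' ANIb is asymmetric; for it the (query, reference) orientation follows the
#' lexicographic pair order.
#'
#' @param genomes A genome set (tibble with `id` and `seq`, named character
#'   vector, or `DNAStringSet`).
#' @param method `"anim"`, `"anib"` or `"orthoani"`.
#' @param ... Passed to the per-pair estimator.
#' @return A tibble with one row per unordered pair: `query`, `reference`,
#'   `ani`, `af`, `ani_af`, `n_hits`, `method`, `zero_hits`.
#' @export
pairwise_ani <- function(genomes, method = c("anim", "anib", "orthoani"),
                         ...) {
  method <- match.arg(method)
  g <- as_genome_tbl(genomes)
  if (nrow(g) < 2) abort("need at least two genomes")
  g <- g[order(g$id), ]
  fn <- switch(method, anim = anim_distance, anib = anib_distance,
               orthoani = orthoani_distance)
  pairs <- utils::combn(g$id, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    qi <- pairs[1, i]; ri <- pairs[2, i]
    res <- fn(g$seq[g$id == qi], g$seq[g$id == ri], ...)
    dplyr::bind_cols(tibble::tibble(query = qi, reference = ri), res)
  })
  dplyr::bind_rows(rows)
}
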