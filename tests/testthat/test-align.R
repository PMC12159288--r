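test_that("local alignment recovers identical strings and matches the DP oracle", {
  sc <- scoring_scheme()
  h <- local_align_banded("ACGTACGT", "ACGTACGT", sc)
  expect_equal(h$identity, 1)
  expect_equal(h$q_start, 0); expect_equal(h$q_end, 8)
  expect_equal(h$aligned_cols, 8)
  # spec-style small case with a heavier mismatch penalty
  sc2 <- scoring_scheme(match = 1, mismatch = -2)
  h2 <- local_align_banded("ACGT", "AGGT", sc2)
  expect_equal(h2$score, oracle_local_score("ACGT", "AGGT", sc2))
  # degenerate input
  expect_equal(local_align_banded("", "ACGT", sc)$identity, 0)
  # random pairs: full DP equals the quadratic oracle score
  set.seed(71)
  for (i in 1:20) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    h <- local_align_banded(a, b, sc)
    expect_equal(h$score, oracle_local_score(a, b, sc))
    expect_gte(h$identity, 0); expect_lte(h$identity, 1)
    expect_lte(h$matches, h$aligned_cols)
  }
})

test_that("banded score never exceeds the full-DP score", {
  sc <- scoring_scheme()
  set.seed(81)
  for (i in 1:15) {
    a <- random_dna(200)
    b <- random_dna(200)
    full <- local_align_banded(a, b, sc, band = 0)
    for (band in c(2, 5, 20)) {
      banded <- local_align_banded(a, b, sc, band = band)
      expect_lte(banded$score, full$score)
    }
  }
})

test_that("maximal match finding agrees with brute-force enumeration", {
  # hand case: the only left-maximal matches >= 4 are (0,2,4) and (3,1,5);
  # (3,1,5) "TACGT" is unique in both strings, hence the only MUM
  mem <- find_maximal_matches("ACGTACGT", "TTACGTTT", 4, "mem",
                              both_strands = FALSE)
  expect_equal(mem$q_start, c(0, 3))
  expect_equal(mem$r_start, c(2, 1))
  expect_equal(mem$length, c(4, 5))
  mum <- find_maximal_matches("ACGTACGT", "TTACGTTT", 4, "mum",
                              both_strands = FALSE)
  expect_equal(nrow(mum), 1)
  expect_equal(mum$length, 5)
  # q == r in mem mode includes the full-length anchor
  s <- random_dna(50)
  self <- find_maximal_matches(s, s, 10, "mem", both_strands = FALSE)
  expect_true(any(self$q_start == 0 & self$r_start == 0 & self$length == 50))
  # reported anchors verify substring equality and maximality, and the set
  # equals the oracle on random strings (reduced alphabet forces repeats)
  set.seed(91)
  for (i in 1:25) {
    alpha <- if (i %% 3 == 0) c("A", "C") else c("A", "C", "G", "T")
    q <- random_dna(sample(40:120, 1), alpha)
    r <- random_dna(sample(40:120, 1), alpha)
    min_len <- sample(4:8, 1)
    got <- find_maximal_matches(q, r, min_len, "mem", both_strands = FALSE)
    want <- oracle_mems(q, r, min_len)
    expect_equal(as.data.frame(got[c("q_start", "r_start", "length")]),
                 as.data.frame(want), ignore_attr = TRUE)
    for (j in seq_len(nrow(got))) {
      expect_identical(substr(q, got$q_start[j] + 1,
                              got$q_start[j] + got$length[j]),
                       substr(r, got$r_start[j] + 1,
                              got$r_start[j] + got$length[j]))
    }
    gotu <- find_maximal_matches(q, r, min_len, "mum", both_strands = FALSE)
    wantu <- oracle_mums(q, r, min_len)
    expect_equal(as.data.frame(gotu[c("q_start", "r_start", "length")]),
                 as.data.frame(wantu), ignore_attr = TRUE)
  }
})

test_that("reverse-strand anchors map to the reverse complement", {
  q <- "AAACCCGGGTTTAAA"
  r <- revcomp(q)
  mm <- find_maximal_matches(q, r, 15, "mem")
  minus <- mm[mm$strand == "-", ]
  expect_true(any(minus$q_start == 0 & minus$length == 15))
})

test_that("anchor chaining respects gap thresholds and matches exhaustive search", {
  one <- tibble::tibble(q_start = 0L, r_start = 0L, length = 10L,
                        strand = "+")
  expect_length(chain_anchors(one), 1)
  # two collinear anchors: gap below threshold -> one cluster, above -> two
  close_pair <- tibble::tibble(q_start = c(0L, 50L), r_start = c(0L, 52L),
                               length = c(20L, 20L), strand = "+")
  expect_length(chain_anchors(close_pair, max_gap = 90), 1)
  far_pair <- tibble::tibble(q_start = c(0L, 200L), r_start = c(0L, 202L),
                             length = c(20L, 20L), strand = "+")
  expect_length(chain_anchors(far_pair, max_gap = 90), 2)
  # chain weight equals exhaustive search over all collinear subsets
  set.seed(101)
  for (i in 1:12) {
    n <- sample(3:12, 1)
    anc <- tibble::tibble(
      q_start = sample(0:300, n), r_start = sample(0:300, n),
      length = sample(5:30, n, replace = TRUE), strand = "+"
    )
    max_gap <- sample(c(30, 90), 1)
    cl <- chain_anchors(anc, max_gap = max_gap)
    got <- sum(cl[[1]]$length)
    expect_equal(got, oracle_chain_weight(anc, max_gap))
  }
})

test_that("cluster extension aggregates anchors and closed gaps", {
  sc <- scoring_scheme()
  # identical sequences, one full-length anchor
  s <- random_dna(80)
  cl <- tibble::tibble(q_start = 0L, r_start = 0L, length = 80L, strand = "+")
  hit <- extend_cluster_to_alignment(s, s, cl, sc)
  expect_equal(hit$identity, 1)
  expect_equal(hit$aligned_cols, 80)
  # two anchors separated by a single substitution
  set.seed(111)
  left <- random_dna(30); right <- random_dna(30)
  q <- paste0(left, "A", right)
  r <- paste0(left, "C", right)
  anc <- find_maximal_matches(q, r, 10, "mem", both_strands = FALSE)
  cl <- chain_anchors(anc)[[1]]
  hit <- extend_cluster_to_alignment(q, r, cl, sc)
  expect_equal(hit$aligned_cols, 61)
  expect_equal(hit$matches, 60)
  # identity never below the anchor-only lower bound
  expect_gte(hit$identity, sum(cl$length) / hit$aligned_cols)
})

test_that("one-to-one filtering matches the exhaustive subset oracle", {
  mk <- function(qs, qe, rs, re, id = 1) {
    tibble::tibble(q_start = qs, q_end = qe, r_start = rs, r_end = re,
                   matches = round((qe - qs) * id), aligned_cols = qe - qs,
                   identity = id)
  }
  # non-overlapping input is unchanged
  h <- rbind(mk(0, 10, 0, 10), mk(20, 30, 20, 30))
  expect_equal(nrow(filter_one_to_one(h)), 2)
  # duplicate query interval: the heavier hit survives
  h2 <- rbind(mk(0, 100, 0, 100, 0.9), mk(0, 100, 200, 300, 0.99))
  kept <- filter_one_to_one(h2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$identity, 0.99)
  # exhaustive-subset equivalence on random hit sets
  set.seed(121)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    qs <- sample(0:200, n); rs <- sample(0:200, n)
    len <- sample(10:80, n, replace = TRUE)
    h <- tibble::tibble(
      q_start = qs, q_end = qs + len, r_start = rs, r_end = rs + len,
      matches = round(len * runif(n, 0.5, 1)), aligned_cols = len,
      identity = runif(n, 0.5, 1)
    )
    kept <- filter_one_to_one(h)
    got <- sum(kept$aligned_cols * kept$identity)
    expect_equal(got, oracle_one_to_one_weight(h), tolerance = 1e-9)
    # hard assertion: no overlap on either axis among retained hits
    if (nrow(kept) > 1) {
      cmb <- utils::combn(nrow(kept), 2)
      for (t in seq_len(ncol(cmb))) {
        a <- cmb[1, t]; b <- cmb[2, t]
        expect_false(max(kept$q_start[a], kept$q_start[b]) <
                       min(kept$q_end[a], kept$q_end[b]))
        expect_false(max(kept$r_start[a], kept$r_start[b]) <
                       min(kept$r_end[a], kept$r_end[b]))
      }
    }
  }
})

test_that("anim reports perfect identity on self and zero on unrelated genomes", {
  set.seed(131)
  g <- random_dna(8000)
  for (mode in c("mum", "mem")) {
    r <- anim_distance(g, g, mode = mode)
    expect_equal(r$ani, 100)
    expect_equal(r$af, 1)
    expect_equal(r$ani_af, 100)
  }
  # two unrelated genomes, long anchors: the zero-ANI failure mode
  h <- random_dna(8000)
  r0 <- anim_distance(g, h, min_match_len = 20, mode = "mem")
  expect_equal(r0$ani, 0)
  expect_equal(r0$af, 0)
  expect_true(r0$zero_hits)
  expect_error(anim_distance("", g), "empty")
})

test_that("anib splits fragments, applies thresholds, and is perfect on self", {
  set.seed(141)
  g <- random_dna(5 * 1020)
  expect_equal(nrow(anibench:::split_fragments(g, 1020L)), 5)
  # trailing fragment below 100 bp is dropped, above is kept
  expect_equal(nrow(anibench:::split_fragments(random_dna(1020 + 50), 1020L)), 1)
  expect_equal(nrow(anibench:::split_fragments(random_dna(1020 + 150), 1020L)), 2)
  r <- anib_distance(g, g)
  expect_equal(r$ani, 100)
  expect_equal(r$af, 1)
  expect_equal(r$n_hits, 5)
  # a fragment present at ~85% identity is retained; an absent fragment is not
  cfg <- sim_config(n_leaves = 2, n_genes = 1, gene_len = 2040, seed = 7,
                    indel_rate = 0)
  root <- generate_root_genome(cfg, seed = 7)
  mut <- genome_seq(evolve_branch(root, 12, cfg)$genome)
  q <- paste0(mut, random_dna(1020)) # two homologous frags + one alien frag
  r2 <- anib_distance(q, genome_seq(root))
  expect_equal(r2$n_hits, 2)
  expect_lt(r2$af, 1)
  expect_gt(r2$ani, 80)
})

test_that("orthoani uses reciprocal best hits and is symmetric", {
  set.seed(151)
  g <- random_dna(4 * 1020)
  r <- orthoani_distance(g, g)
  expect_equal(r$ani, 100)
  expect_equal(r$af, 1)
  expect_equal(r$n_hits, 4)
  # a duplicated fragment in A cannot claim two partners in B
  base <- random_dna(1020)
  a <- paste0(base, base, random_dna(1020))
  b <- paste0(base, random_dna(1020), random_dna(1020))
  rd <- orthoani_distance(a, b)
  expect_lte(rd$n_hits, 2) # at most the duplicated (once) + nothing else
  # symmetry on an evolved pair
  pair <- make_related_pair(len = 3 * 1020, branch = 8, seed = 9)
  r_ab <- orthoani_distance(pair$a, pair$b)
  r_ba <- orthoani_distance(pair$b, pair$a)
  expect_equal(r_ab$ani, r_ba$ani, tolerance = 1e-12)
  expect_equal(r_ab$af, r_ba$af, tolerance = 1e-12)
})

test_that("ddh distances follow the three closed forms", {
  h <- tibble::tibble(matches = 900, aligned_cols = 1000)
  d <- ddh_distances(h, 1000, 1000)
  expect_equal(d$d1, 0.5)
  expect_equal(d$d2, 0.1)
  expect_equal(d$d3, 0.55)
  # identical genomes fully aligned
  full <- tibble::tibble(matches = c(1000, 1000), aligned_cols = c(1000, 1000))
  d0 <- ddh_distances(full, 1000, 1000)
  expect_equal(unlist(d0[c("d1", "d2", "d3")]), c(d1 = 0, d2 = 0, d3 = 0))
  # no alignments: d2 undefined and flagged
  none <- tibble::tibble(matches = numeric(0), aligned_cols = numeric(0))
  dn <- ddh_distances(none, 1000, 1000)
  expect_equal(dn$d1, 1)
  expect_equal(dn$d3, 1)
  expect_true(is.na(dn$d2))
  expect_true(dn$d2_missing)
})

test_that("ani_af never exceeds ani, with equality iff AF = 1", {
  pair <- make_related_pair(len = 20000, branch = 15, seed = 17)
  r <- anim_distance(pair$a, pair$b, min_match_len = 14, mode = "mem")
  expect_lte(r$ani_af, r$ani)
  self <- anim_distance(pair$a, pair$a)
  expect_equal(self$af, 1)
  expect_equal(self$ani_af, self$ani)
})
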