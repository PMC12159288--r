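test_that("k-mer sets enumerate distinct windows and respect the contract", {
  cfg3 <- kmer_config(k = 3, canonical = FALSE)
  # no window fits
  expect_equal(build_kmer_set("AC", cfg3)$n_distinct, 0L)
  expect_equal(build_kmer_set("", cfg3)$n_distinct, 0L)
  # brute-force window enumeration: ACGTT -> ACG, CGT, GTT
  expect_equal(build_kmer_set("ACGTT", cfg3)$n_distinct, 3L)
  # multiplicity discarded
  expect_equal(build_kmer_set("ACGACGACG", cfg3)$n_distinct, 3L)
  # windows with non-ACGT characters are skipped
  expect_equal(build_kmer_set("ACGNACG", cfg3)$n_distinct, 1L)
  # pooling across records, no window spans the boundary
  two <- build_kmer_set(c("ACG", "CGT"), cfg3)
  expect_equal(two$n_distinct, 2L)
  # canonical collapses a k-mer with its reverse complement
  can <- kmer_config(k = 3, canonical = TRUE)
  expect_equal(build_kmer_set("ACG", can)$hashes,
               build_kmer_set("CGT", can)$hashes)
  # parameter validation
  expect_error(kmer_config(k = 0))
  expect_error(kmer_config(k = 33))
})

test_that("exact Jaccard matches brute-force set arithmetic", {
  cfg <- kmer_config(k = 3, canonical = FALSE)
  a <- build_kmer_set("ACGTT", cfg)
  b <- build_kmer_set("CGTTA", cfg)
  # shared {CGT, GTT} = 2, union {ACG,CGT,GTT,TTA} = 4
  expect_equal(exact_jaccard(a, b), 0.5)
  expect_equal(exact_jaccard(a, a), 1)
  z <- build_kmer_set("AAAAA", cfg)
  expect_equal(exact_jaccard(a, z), 0)
  # symmetry and range on random pairs
  set.seed(11)
  for (i in 1:5) {
    x <- build_kmer_set(random_dna(300), cfg)
    y <- build_kmer_set(random_dna(300), cfg)
    j <- exact_jaccard(x, y)
    expect_identical(j, exact_jaccard(y, x))
    expect_gte(j, 0); expect_lte(j, 1)
  }
  # mismatched configurations refuse to compare
  other <- build_kmer_set("ACGTT", kmer_config(k = 4, canonical = FALSE))
  expect_error(exact_jaccard(a, other), "config")
  seeded <- build_kmer_set("ACGTT", kmer_config(k = 3, canonical = FALSE,
                                                hash_seed = 7))
  expect_error(exact_jaccard(a, seeded), "config")
})

test_that("duplicating an internal segment perturbs the k-mer set by at most 2(k-1)", {
  set.seed(21)
  k <- 9L
  cfg <- kmer_config(k = k, canonical = FALSE)
  g <- random_dna(4000)
  other <- random_dna(4000)
  seg <- substr(g, 1001, 2000)
  dup <- paste0(substr(g, 1, 2500), seg, substr(g, 2501, 4000))
  A <- build_kmer_set(g, cfg)
  A2 <- build_kmer_set(dup, cfg)
  B <- build_kmer_set(other, cfg)
  new_kmers <- length(setdiff(A2$hashes, A$hashes))
  expect_lte(new_kmers, 2 * (k - 1))
  uni <- length(union(A$hashes, B$hashes))
  expect_lte(abs(exact_jaccard(A2, B) - exact_jaccard(A, B)),
             2 * (k - 1) / uni)
})

test_that("sketches are deterministic bottom-s subsets of the k-mer set", {
  set.seed(31)
  cfg <- kmer_config(k = 15)
  g <- random_dna(5000)
  full <- build_kmer_set(g, cfg)
  sk <- build_sketch(g, cfg, s = 200)
  expect_length(sk$hashes, 200)
  expect_true(all(sk$hashes %in% full$hashes))
  expect_identical(sk$hashes, sort(full$hashes)[1:200])
  expect_true(all(diff(sk$hashes) > 0))
  # s >= n_distinct: the sketch is the full set
  big <- build_sketch(g, cfg, s = full$n_distinct + 10)
  expect_identical(big$hashes, full$hashes)
  # determinism
  expect_identical(build_sketch(g, cfg, s = 200)$hashes, sk$hashes)
  expect_error(build_sketch(g, cfg, s = 0))
})

test_that("sketched Jaccard equals 1 on identical inputs and 0 on disjoint", {
  cfg <- kmer_config(k = 11)
  set.seed(41)
  g <- random_dna(2000)
  a <- build_sketch(g, cfg, s = 100)
  expect_equal(sketch_jaccard(a, a), 1)
  b <- build_sketch(paste(rep("ACCA", 600), collapse = ""), cfg, s = 100)
  expect_equal(sketch_jaccard(a, b), 0)
})

test_that("sketched Jaccard converges to exact Jaccard within the binomial bound", {
  pair <- make_related_pair(len = 30000, branch = 6, seed = 5)
  cfg <- kmer_config(k = 16)
  ja <- build_kmer_set(pair$a, cfg)
  jb <- build_kmer_set(pair$b, cfg)
  J <- exact_jaccard(ja, jb)
  expect_gt(J, 0.05)
  for (s in c(1000, 5000)) {
    sa <- build_sketch(pair$a, cfg, s = s)
    sb <- build_sketch(pair$b, cfg, s = s)
    Js <- sketch_jaccard(sa, sb)
    expect_lte(abs(Js - J), 3 * sqrt(J * (1 - J) / s))
  }
  # the literal intersection/union estimator is also consistent
  sa <- build_sketch(pair$a, cfg, s = 5000)
  sb <- build_sketch(pair$b, cfg, s = 5000)
  expect_lte(abs(sketch_jaccard(sa, sb, literal = TRUE) - J), 0.1)
})

test_that("Mash index follows the closed form and saturates at J = 0", {
  expect_equal(mash_index(1, 21)$mash_index, 1)
  expect_equal(mash_index(1, 21)$mash_distance, 0)
  m <- mash_index(0.5, 21)
  expect_equal(m$mash_index, 1 + log(2 / 3) / 21, tolerance = 1e-12)
  expect_equal(m$mash_index, 1 - m$mash_distance)
  z <- mash_index(0, 21)
  expect_equal(z$mash_distance, 1)
  expect_equal(z$mash_index, 0)
  expect_true(z$saturated)
  expect_error(mash_index(1.2, 21))
  expect_error(mash_index(-0.1, 21))
  # strictly increasing in J on (0, 1]
  J <- seq(0.01, 1, by = 0.01)
  idx <- mash_index(J, 21)$mash_index
  expect_true(all(diff(idx) > 0))
  expect_true(all(diff(mash_index(J, 21)$mash_distance) < 0))
})

test_that("k-mer spectrum fraction matches enumeration and shrinks with k", {
  expect_equal(kmer_spectrum_fraction("ACGT", 1), 1)
  expect_equal(kmer_spectrum_fraction("AACGT", 2), 4 / 16)
  set.seed(51)
  g <- random_dna(100000)
  fr <- vapply(1:12, function(k) kmer_spectrum_fraction(g, k), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr > 0 & fr <= 1))
})

test_that("pairwise_kmer produces one row per unordered pair", {
  set.seed(61)
  g <- tibble::tibble(id = c("a", "b", "c"),
                      seq = replicate(3, random_dna(1000)))
  pk <- pairwise_kmer(g, kmer_config(k = 11))
  expect_equal(nrow(pk), 3)
  expect_true(all(pk$query < pk$reference))
  expect_true(all(pk$jaccard >= 0 & pk$jaccard <= 1))
  expect_true(all(pk$mash_distance >= 0))
})
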