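test_that("pair tables contain one row per unordered pair and flag gaps", {
  mk_long <- function(labels) {
    p <- utils::combn(sort(labels), 2)
    tibble::tibble(query = p[1, ], reference = p[2, ],
                   value = runif(ncol(p)))
  }
  set.seed(31)
  labs <- sprintf("G%02d", 1:15)
  pt <- make_pair_table(list(x = mk_long(labs)))
  expect_equal(nrow(pt), 15 * 14 / 2)
  expect_true(all(pt$complete))
  # missing entries flagged, not dropped
  partial <- mk_long(labs)[-(1:3), ]
  pt2 <- make_pair_table(list(x = partial))
  expect_equal(nrow(pt2), 105)
  expect_equal(sum(!pt2$complete), 3)
  # disjoint label sets are an explicit error
  expect_error(
    make_pair_table(list(a = mk_long(c("x", "y", "z")),
                         b = mk_long(c("u", "v", "w"))),
                    tree_distances = NULL) |>
      (\(x) spearman_log10p(x$a, x$b))(),
    regexp = ".*"
  )
  expect_error(make_pair_table(list(x = mk_long(c("a", "b")))), "fewer than 3")
  # label normalization strips paths and FASTA extensions
  fancy <- mk_long(labs)
  fancy$query <- paste0("dir/", fancy$query, ".fasta")
  fancy$reference <- paste0("dir/", fancy$reference, ".fa.gz")
  pt3 <- make_pair_table(list(x = fancy))
  expect_setequal(union(pt3$query, pt3$reference), labs)
})

test_that("Spearman rho reproduces rank arithmetic on tiny cases", {
  expect_equal(spearman_log10p(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_log10p(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  # ties handled by average ranks, agreeing with stats::cor
  x <- c(1, 2, 2, 3, 5, 5, 5, 9, 10)
  y <- c(2, 1, 4, 4, 6, 7, 7, 7, 12)
  expect_equal(spearman_log10p(x, y)$rho,
               stats::cor(x, y, method = "spearman"))
  # constant vector is flagged
  flat <- spearman_log10p(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(flat$rho))
  expect_true("constant_input" %in% flat$flags)
  expect_error(spearman_log10p(1:2, 2:1), "at least 3")
})

test_that("small-n p-values are exact permutation probabilities", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    x <- runif(n)
    y <- runif(n)
    for (alt in c("two_sided", "negative")) {
      got <- spearman_log10p(x, y, alternative = alt)
      expect_equal(10^got$log10_p, oracle_spearman_perm(x, y, alt),
                   tolerance = 1e-10)
    }
  }
  # log-space t tail agrees with the permutation p within 10% at n = 8
  set.seed(42)
  x <- runif(8); y <- x + rnorm(8, sd = 0.4)
  exact <- spearman_log10p(x, y)
  expect_equal(10^exact$log10_p, oracle_spearman_perm(x, y), tolerance = 1e-10)
})

test_that("the t-approximation p-value is log-space safe in extreme tails", {
  set.seed(51)
  n <- 105
  x <- seq_len(n) + rnorm(n, sd = 1e-3)
  lps <- vapply(c(0.5, 0.1, 0.01, 1e-4), function(noise) {
    y <- x + rnorm(n, sd = noise * n)
    spearman_log10p(x, y)$log10_p
  }, numeric(1))
  # tighter agreement -> smaller log10 p, all finite, reaching deep tails
  expect_true(all(is.finite(lps)))
  expect_true(all(diff(lps) < 0))
  expect_lt(lps[4], -150)
  # perfect monotone agreement saturates at the documented cap
  cap <- spearman_log10p(x, sort(x))
  expect_equal(cap$log10_p, -320)
  expect_true("rho_saturated" %in% cap$flags)
  # against stats::cor.test on a moderate case (same rho, comparable p)
  set.seed(52)
  y <- x + rnorm(n, sd = 40)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  got <- spearman_log10p(x, y)
  expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(10^got$log10_p, ct$p.value, tolerance = 0.05)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(61)
  x <- runif(30); y <- runif(30)
  base <- spearman_log10p(x, y)
  tr1 <- spearman_log10p(exp(3 * x), y)
  tr2 <- spearman_log10p(x, y^3 + 10)
  expect_equal(base$rho, tr1$rho)
  expect_equal(base$log10_p, tr1$log10_p)
  expect_equal(base$rho, tr2$rho)
})

test_that("merged ranking averages ranks and re-ranks", {
  v <- c(3, 1, 4, 1.5, 9)
  expect_equal(merged_rank_distance(v, v), rank(v))
  # exactly reversed rankings tie everywhere
  expect_true(all(merged_rank_distance(1:6, 6:1) == 3.5))
  expect_error(merged_rank_distance(1:3, 1:4), "equal length")
  expect_error(merged_rank_distance(c(1, NA, 3), 1:3), "complete")
})

test_that("tool agreement normalizes orientation", {
  set.seed(71)
  v <- runif(20)
  expect_equal(tool_agreement(v, v)$rho, 1)
  expect_equal(tool_agreement(v, 1 - v, "similarity", "distance")$rho, 1)
  # orientation flag flips the sign exactly
  w <- runif(20)
  a <- tool_agreement(v, w, "similarity", "similarity")
  b <- tool_agreement(v, w, "similarity", "distance")
  expect_equal(a$rho, -b$rho)
})

test_that("tidy and glance return one-row summaries", {
  ev <- spearman_log10p(runif(12), runif(12))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("rho", "log10_p", "n", "alternative", "method"))
  expect_identical(glance(ev), td)
})

test_that("k_sweep reports one result per k with a stable argmin", {
  set.seed(81)
  cfg <- sim_config(n_leaves = 6, n_genes = 4, gene_len = 2000,
                    root_to_leaf_len = 60, seed = 19, indel_rate = 0)
  sim <- simulate_dataset(cfg)
  sw <- k_sweep(sim$genomes, ks = c(7, 13, 19), tree = sim$tree)
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$n == 15))
  expect_true(attr(sw, "best_k") %in% sw$k)
  sw2 <- k_sweep(sim$genomes, ks = c(7, 13, 19), tree = sim$tree)
  expect_identical(attr(sw, "best_k"), attr(sw2, "best_k"))
  expect_identical(sw$log10_p, sw2$log10_p)
  # at k = 7 nearly the whole 4^k spectrum is present in 8 kb genomes, so the
  # short-k statistic must be worse than the sweep's optimum
  expect_gt(sw$log10_p[sw$k == 7], min(sw$log10_p))
  # single k: single row
  expect_equal(nrow(k_sweep(sim$genomes, ks = 13, tree = sim$tree)), 1)
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})
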