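test_that("hypergeometric enrichment matches the exact combinatorial tail", {
  universe <- paste0("g", 1:100)
  coll <- gene_set_collection(
    list(hit = paste0("g", 1:10),
         null = paste0("g", 11:30),
         empty_overlap = paste0("g", 90:99)),
    universe)
  res <- hypergeom_enrich(paste0("g", 1:10), coll)
  hit <- res[res$set_id == "hit", ]
  expect_equal(hit$fold_enrichment, 10)
  expect_equal(hit$p, 1 / choose(100, 10), tolerance = 1e-12)
  # k/n = K/N gives fold enrichment 1 (k = 2, n = 10, K = 20, N = 100)
  prop <- hypergeom_enrich(paste0("g", c(1, 11, 21:28)),
                           gene_set_collection(
                             list(s = paste0("g", 1:20)), universe))
  expect_equal(prop[prop$set_id == "s", "fold_enrichment"], 1)
  # disjoint query: upper tail at k = 0 is 1
  expect_equal(res[res$set_id == "empty_overlap", "p"], 1)
})

test_that("enrichment flags respect both strict display cut-offs", {
  universe <- paste0("g", 1:60)
  coll <- gene_set_collection(list(big = paste0("g", 1:12),
                                   tiny = paste0("g", 1:3)), universe)
  res <- hypergeom_enrich(paste0("g", 1:12), coll, min_count = 3,
                          min_neglog10p = 1)
  expect_true(res[res$set_id == "big", "passing"])
  # k = 3 hits is not > 3: fails the count rule regardless of p
  expect_false(res[res$set_id == "tiny", "passing"])
  expect_error(hypergeom_enrich(character(0), coll), "empty query")
})

test_that("hypergeometric tail agrees with Monte-Carlo resampling", {
  set.seed(66)
  N <- 40; K <- 12; n <- 9
  draws <- replicate(20000, sum(sample.int(N, n) <= K))
  for (k in c(3, 5, 7)) {
    mc <- mean(draws >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(mc - p), 3 * se + 1e-6)
  }
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))      # monotone in p
  expect_true(all(bh_fdr(q) >= q - 1e-12))           # re-adjusting never lowers
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GMT files round-trip through the collection object", {
  coll <- gene_set_collection(
    list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4")),
    universe = paste0("g", 1:5),
    descriptions = c(setA = "first", setB = "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = paste0("g", 1:5))
  expect_identical(back$sets, coll$sets)
  expect_identical(back$descriptions, coll$descriptions)
  # members outside the universe are dropped and counted
  dropped <- gene_set_collection(list(s = c("g1", "zz")), paste0("g", 1:5))
  expect_identical(unname(dropped$dropped["s"]), 1L)
  expect_identical(dropped$sets$s, "g1")
})

test_that("2^-ddCT relative quantification follows the textbook identities", {
  qpcr <- expand.grid(sample = c("cal", "s1", "s2"),
                      gene = c("T", "r1", "r2", "r3"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qpcr$ct <- c(25, 22, 24,      # target per sample
               20, 20, 20, 21, 21, 21, 22, 22, 22)
  res <- relative_expression_ddct(qpcr, "T", c("r1", "r2", "r3"), "cal")
  expect_equal(res$rq[res$sample == "cal"], 1)
  # s1 target CT 3 cycles below calibrator, same references: RQ = 8
  expect_equal(res$rq[res$sample == "s1"], 8)
  # geometric mean of (20, 21, 22)
  expect_equal(res$dct[res$sample == "cal"], 25 - prod(20:22)^(1/3))
  # a constant added to every sample's target CT cancels in RQ
  q2 <- qpcr
  q2$ct[q2$gene == "T"] <- q2$ct[q2$gene == "T"] + 1.7
  res2 <- relative_expression_ddct(q2, "T", c("r1", "r2", "r3"), "cal")
  expect_equal(res2$rq, res$rq)
  # missing reference is reported
  expect_error(relative_expression_ddct(qpcr[qpcr$gene != "r2", ], "T",
                                        c("r1", "r2", "r3"), "cal"), "r2")
})

test_that("platform concordance recovers exact and simulated relations", {
  a <- c(-2, 0, 1, 3, 5)
  same <- platform_concordance(a, a)
  expect_equal(same$r_squared, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(platform_concordance(a, -a)$r, -1)
  set.seed(12)
  x <- rnorm(100, sd = 2)
  y <- 2 * x + rnorm(100, sd = 0.1)
  fit <- platform_concordance(x, y)
  expect_true(fit$slope > 1.9 && fit$slope < 2.1)
  expect_gt(fit$r_squared, 0.95)
  expect_identical(platform_concordance(c(x, NA), c(y, 1))$n_dropped, 1L)
  expect_error(platform_concordance(1:2, 2:3), ">= 3")
})
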