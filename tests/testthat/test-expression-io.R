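test_that("expression matrices validate their metadata", {
  e <- toy_expression()
  expect_s3_class(e, "expression_matrix")
  expect_identical(dim(e$values), c(2L, 12L))

  samples <- e$samples
  bad <- samples[-1, ]
  expect_error(expression_matrix(e$values, bad),
               samples$sample_id[1])
  dup <- e$values
  rownames(dup) <- c("g1", "g1")
  expect_error(expression_matrix(dup, samples), "duplicate gene")
  neg <- e$values
  neg[2, 3] <- -1
  expect_error(expression_matrix(neg, samples), "g2")
  off <- samples
  off$tissue[4] <- "liver"
  expect_error(expression_matrix(e$values, off, tissues = e$tissues),
               off$sample_id[4])
})

test_that("expression files round-trip and match the in-memory object", {
  run <- default_run(101, 0)
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(run$sim$expression, mp, sp)
  back <- read_expression(mp, sp, tissues = run$design$tissues,
                          days = run$design$days)
  expect_equal(back$values, run$sim$expression$values, tolerance = 1e-12)
  expect_equal(back$samples, run$sim$expression$samples)
})

test_that("log2FC profiles follow the pseudocount ratio definition", {
  vals <- matrix(7, nrow = 2, ncol = 12)
  vals[2, ] <- rep(c(1, 1, 15, 15, 15, 15), 2)  # day0 reps = 1, others 15
  e <- toy_expression(values = vals)
  prof <- log2fc_profiles(e)
  expect_identical(colnames(prof),
                   c("endometrium:6", "endometrium:12", "ovary:6", "ovary:12"))
  expect_equal(unname(prof["g1", ]), rep(0, 4))           # 7 vs 7
  expect_equal(unname(prof["g2", "endometrium:6"]), 3.0)  # log2(16/2)
})

test_that("a tissue without baseline samples is reported by name", {
  e <- toy_expression()
  keep <- !(e$samples$tissue == "ovary" & e$samples$day == 0)
  e2 <- expression_matrix(e$values[, e$samples$sample_id[keep]],
                          e$samples[keep, ], tissues = e$tissues,
                          days = e$days)
  expect_error(log2fc_profiles(e2), "ovary")
})

test_that("DEG-table profiles agree with profiles recomputed from FPKM", {
  run <- default_run(101, 0)
  from_deg <- deg_to_profiles(run$sim$deg, run$design$tissues,
                              run$design$days)
  from_expr <- log2fc_profiles(run$sim$expression)
  expect_equal(as.matrix(from_deg),
               as.matrix(from_expr)[rownames(from_deg), ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("deg_to_profiles enforces the declared design", {
  deg <- expand.grid(tissue = c("endometrium", "ovary", "oviduct"),
                     day = c(3, 6, 9, 12, 15, 18),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  deg$gene <- "g1"
  deg$log2fc <- seq_len(nrow(deg))
  deg$q <- 0.5
  prof <- deg_to_profiles(deg, c("endometrium", "ovary", "oviduct"),
                          c(0, 3, 6, 9, 12, 15, 18))
  expect_identical(dim(prof), c(1L, 18L))

  miss <- deg[-5, ]
  expect_error(deg_to_profiles(miss, c("endometrium", "ovary", "oviduct"),
                               c(0, 3, 6, 9, 12, 15, 18)),
               "g1.*strict", )
  filled <- deg_to_profiles(miss, c("endometrium", "ovary", "oviduct"),
                            c(0, 3, 6, 9, 12, 15, 18), fill = "zero")
  expect_identical(sum(as.matrix(filled) == 0), 1L)
})

test_that("z-scoring standardizes rows and guards constant rows", {
  expect_equal(unname(zscore_rows(matrix(1:3, nrow = 1))[1, ]),
               c(-1, 0, 1))
  expect_equal(unname(zscore_rows(matrix(5, nrow = 1, ncol = 3))[1, ]),
               c(0, 0, 0))
  set.seed(1)
  m <- matrix(rnorm(50), nrow = 5)
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)  # idempotent
  expect_error(zscore_rows(matrix(1, nrow = 2, ncol = 1)), "2 columns")
})

test_that("fold-change bin selection is a strict threshold on max |log2FC|", {
  m <- matrix(0, nrow = 2, ncol = 18)
  m[1, 4] <- 3.1
  m[2, 7] <- -2.9
  prof <- toy_profiles(m)
  expect_identical(select_fc_bins(prof, 8), "g1")
  expect_error(select_fc_bins(prof, 1), "> 1")
})

test_that("fold-change bins are nested across thresholds", {
  set.seed(42)
  m <- matrix(rnorm(40 * 18, sd = 3), nrow = 40)
  prof <- toy_profiles(m)
  sel <- lapply(c(2, 4, 8, 16), function(t) select_fc_bins(prof, t))
  for (i in 2:4) expect_true(all(sel[[i]] %in% sel[[i - 1]]))
})

test_that("profile and DEG tables round-trip through TSV", {
  run <- default_run(101, 0)
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(run$profiles, pp)
  expect_equal(as.matrix(read_profiles(pp)), as.matrix(run$profiles),
               tolerance = 1e-12)
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_deg(run$sim$deg, dp)
  expect_equal(read_deg(dp), run$sim$deg, tolerance = 1e-12)
})
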