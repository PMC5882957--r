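test_that("default archetypes match the documented temporal windows", {
  days <- c(0, 3, 6, 9, 12, 15, 18)
  arcs <- default_archetypes(days)
  expect_length(arcs, 5)
  tissues <- vapply(arcs, `[[`, character(1), "tissue")
  expect_equal(as.vector(table(tissues)[c("endometrium", "ovary",
                                          "oviduct")]),
               c(2L, 2L, 1L))
  # baseline day forced to zero in every profile
  for (a in arcs) expect_identical(unname(a$profile[["0"]]), 0)
  # endometrial up-regulation peaks between days 6 and 12
  eu <- arcs$endometrium_up$profile
  expect_true(as.integer(names(which.max(eu))) %in% c(6, 9, 12))
  # ovarian up-regulation spans days 3 through 12
  ou <- arcs$ovary_up$profile
  expect_true(all(ou[as.character(c(3, 6, 9, 12))] != 0))
  expect_error(default_archetypes(c(3, 6, 9)), "baseline day")
})

test_that("simulation is reproducible from the seed", {
  design <- synthetic_design(module_sizes = c(endometrium_up = 10),
                             n_bridging = 0, n_background = 5, seed = 7)
  a <- simulate_dataset(design)
  b <- simulate_dataset(design)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$deg, b$deg)
  expect_identical(a$truth$true_log2fc, b$truth$true_log2fc)
  # and a different seed changes the data
  design2 <- synthetic_design(module_sizes = c(endometrium_up = 10),
                              n_bridging = 0, n_background = 5, seed = 8)
  expect_false(identical(simulate_dataset(design2)$expression$values,
                         a$expression$values))
})

test_that("noise-free observed log2FC matches the planted signal", {
  run <- default_run(101, 0)
  sim <- run$sim
  obs <- deg_to_profiles(sim$deg, run$design$tissues, run$design$days)
  truth <- sim$truth
  genes <- rownames(obs)
  err <- abs(as.matrix(obs) - truth$true_log2fc[genes, colnames(obs)])
  # pseudocount distortion is bounded by the baseline floor; for
  # up-regulated signal at per-tissue baseline >= 100 it is < 0.02
  s <- run$sim$expression$samples
  v <- run$sim$expression$values
  base <- sapply(run$design$tissues, function(t) {
    rowMeans(v[genes, s$tissue == t & s$day == 0, drop = FALSE])
  })
  cc <- do.call(rbind, strsplit(colnames(obs), ":"))
  for (j in seq_len(ncol(obs))) {
    up_ok <- truth$true_log2fc[genes, j] >= 0 & base[, cc[j, 1]] >= 100
    expect_lt(max(err[up_ok, j]), 0.02)
  }
  # down-regulation inflates the pseudocount effect; it stays below the
  # margin that separates the planted peak (>= 3.4) from the 3.0 cut-off
  expect_lt(max(err), 0.4)
})

test_that("without jitter, genes sharing an archetype correlate exactly +1", {
  # in the exact-copy limit (no gene-level kinetic heterogeneity) planted
  # profiles are proportional, so their Pearson correlation is exactly 1
  design <- synthetic_design(module_sizes = c(endometrium_up = 6,
                                              oviduct_down = 6),
                             n_bridging = 0, n_background = 0,
                             noise_sd = 0, profile_jitter_sd = 0, seed = 2)
  truth <- simulate_dataset(design)$truth
  tg <- truth$genes
  for (arch in c("endometrium_up", "oviduct_down")) {
    genes <- tg$gene[tg$archetype == arch]
    tis <- tg$tissue[match(genes[1], tg$gene)]
    cols <- grep(paste0("^", tis, ":"), colnames(truth$true_log2fc))
    r <- cor(t(truth$true_log2fc[genes, cols]))
    expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)
  }
})

test_that("q-values are consistent with the planted activity threshold", {
  run <- default_run(101, 0)
  deg <- run$sim$deg
  truth <- run$sim$truth
  key <- paste(deg$tissue, deg$day, sep = ":")
  tfc <- truth$true_log2fc[cbind(match(deg$gene, rownames(truth$true_log2fc)),
                                 match(key, colnames(truth$true_log2fc)))]
  active <- abs(tfc) >= run$design$active_abs_log2fc
  expect_true(all(deg$q[active] < 0.05))
  expect_true(all(deg$q[!active] >= 0.05))
})

test_that("the stringent filter recovers exactly the planted genes", {
  run <- default_run(101, 0)
  planted <- run$sim$truth$genes$gene[
    run$sim$truth$genes$archetype != "background"]
  expect_setequal(run$filt$kept, planted)
  expect_length(run$filt$kept, 904)
})

test_that("truth tables round-trip through TSV", {
  design <- synthetic_design(module_sizes = c(endometrium_up = 6,
                                              ovary_down = 6),
                             n_bridging = 5, n_background = 4, seed = 3)
  sim <- simulate_dataset(design)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$genes, sim$truth$genes)
  expect_equal(back$true_log2fc, sim$truth$true_log2fc)
  # exactly the planted number of bridging rows on disk
  tab <- read.delim(path)
  expect_identical(sum(tab$is_bridging), 5L)
})

test_that("an empty truth writes a header-only file", {
  design <- synthetic_design(module_sizes = c(endometrium_up = 2),
                             n_bridging = 0, n_background = 0, seed = 1)
  truth <- simulate_dataset(design)$truth
  truth$genes <- truth$genes[0, ]
  truth$true_log2fc <- truth$true_log2fc[0, , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  expect_length(readLines(path), 1L)
  back <- read_truth(path)
  expect_identical(nrow(back$genes), 0L)
})

test_that("invalid designs are rejected", {
  expect_error(synthetic_design(replicates = 0), "replicates")
  expect_error(synthetic_design(effect_size = -1), "effect_size")
  expect_error(synthetic_design(q_active_max = 0.3, q_inactive_min = 0.2),
               "q_active_max")
  expect_error(synthetic_design(days = c(0, 0, 3)), "baseline day")
  expect_error(synthetic_design(noise_sd = NaN), "noise_sd")
})
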