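triangle_net <- function(tissues = c("ovary", "ovary", "ovary")) {
  r <- matrix(0.95, 3, 3); diag(r) <- 1
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  mask <- matrix(TRUE, 3, 3); diag(mask) <- FALSE
  attrs <- data.frame(gene = c("a", "b", "c"), tissue = tissues,
                      max_abs_log2fc = c(4, 5, 6), peak_day = c(6L, 9L, 12L),
                      stringsAsFactors = FALSE)
  build_network(r, mask, attrs)
}

test_that("network edges require both PCIT significance and the threshold", {
  r <- diag(4) * 0 + 0.1; diag(r) <- 1
  r[1, 2] <- r[2, 1] <- 0.95
  r[3, 4] <- r[4, 3] <- 0.92
  dimnames(r) <- list(paste0("g", 1:4), paste0("g", 1:4))
  mask <- matrix(TRUE, 4, 4); diag(mask) <- FALSE
  mask[3, 4] <- mask[4, 3] <- FALSE   # significant threshold-passers only
  attrs <- data.frame(gene = paste0("g", 1:4), tissue = "ovary",
                      stringsAsFactors = FALSE)
  net <- build_network(r, mask, attrs)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$r, 0.95)
  expect_equal(igraph::vcount(net), 4)  # isolated nodes retained

  tighter <- build_network(r, mask, attrs, threshold = 0.99)
  expect_true(igraph::ecount(tighter) <= igraph::ecount(net))

  # r^2 mode: 0.95^2 = 0.9025 > 0.9
  r2net <- build_network(r, mask, attrs, threshold = 0.9, mode = "r2")
  expect_equal(igraph::ecount(r2net), 1)

  expect_error(build_network(r, mask, attrs[-2, ]), "g2")
})

test_that("tissue assignment follows the maximum fold change with tie rules", {
  m <- matrix(0, nrow = 3, ncol = 18)
  m[1, 8] <- 4.2           # ovary day 6 (cols 7..12 are ovary days 3..18)
  m[2, c(2, 8)] <- c(3, 3) # exact tie endometrium day 6 vs ovary day 6
  prof <- toy_profiles(m)
  asg <- assign_tissue(prof)
  expect_identical(asg$tissue[1], "ovary")
  expect_identical(asg$peak_day[1], 6L)
  expect_equal(asg$max_abs_log2fc[1], 4.2)
  expect_identical(asg$tissue[2], "endometrium")  # declared tissue order
  expect_true(asg$tie[2])
  expect_true(asg$unassigned[3])
})

test_that("tissue sub-networks keep only intra-tissue-connected genes", {
  net <- triangle_net()
  asg <- data.frame(gene = c("a", "b", "c"), tissue = "ovary",
                    stringsAsFactors = FALSE)
  subs <- extract_tissue_subnetworks(net, asg)
  expect_equal(igraph::vcount(subs$subnetworks$ovary), 3)
  expect_equal(igraph::ecount(subs$subnetworks$ovary), 3)

  # an ovary gene whose only edges reach endometrium genes is excluded
  asg2 <- data.frame(gene = c("a", "b", "c"),
                     tissue = c("ovary", "endometrium", "endometrium"),
                     stringsAsFactors = FALSE)
  subs2 <- extract_tissue_subnetworks(net, asg2)
  expect_identical(subs2$excluded, "a")
  expect_false("ovary" %in% names(Filter(function(g) igraph::vcount(g) > 0,
                                         subs2$subnetworks)))
})

test_that("bridging genes are those whose neighbours span two tissues", {
  # path a(END) - b(OVA) - c(OVI)
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.95; r[2, 3] <- r[3, 2] <- 0.95
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  mask <- abs(r) > 0.9 & !diag(3)
  asg <- data.frame(gene = c("a", "b", "c"),
                    tissue = c("endometrium", "ovary", "oviduct"),
                    stringsAsFactors = FALSE)
  net <- build_network(r, mask, asg)
  expect_identical(find_bridging_genes(net, asg), "b")

  one <- triangle_net()
  expect_length(find_bridging_genes(
    one, data.frame(gene = c("a", "b", "c"), tissue = "ovary")), 0)
})

test_that("the core network and bridge connectivity count are rebuilt", {
  net <- triangle_net(c("endometrium", "ovary", "oviduct"))
  core <- build_core_network(net, c("a", "b"))
  expect_equal(igraph::ecount(core$core), 1)
  expect_identical(core$bridge_connectivity, 3L)  # all edges touch a or b
  expect_gte(core$bridge_connectivity, igraph::ecount(core$core))

  solo <- build_core_network(net, "a")
  expect_equal(igraph::vcount(solo$core), 1)
  expect_equal(igraph::ecount(solo$core), 0)
  expect_identical(solo$bridge_connectivity, 2L)
  expect_error(build_core_network(net, "zz"), "nodes")
})

test_that("network summaries count nodes, edges, degrees and components", {
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  s <- network_summary(empty)
  expect_identical(s$nodes, 0L)
  expect_identical(s$edges, 0L)

  tri <- triangle_net()
  s2 <- network_summary(tri)
  expect_identical(s2$nodes, 3L)
  expect_identical(s2$edges, 3L)
  expect_identical(s2$degree_median, 2)
  expect_identical(s2$components, 1L)

  # invariant under relabeling
  perm <- igraph::permute(tri, c(3, 1, 2))
  s3 <- network_summary(perm)
  expect_equal(s2[, -1], s3[, -1])
})

test_that("the partition accounts for every network node", {
  run <- default_run(101, 0)
  part <- run$part
  sub_nodes <- unlist(lapply(part$subnetworks,
                             function(g) igraph::V(g)$name))
  expect_identical(anyDuplicated(sub_nodes), 0L)
  expect_setequal(c(sub_nodes, part$excluded, part$unassigned),
                  igraph::V(run$net)$name)
})
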