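test_that("MCL separates the barbell into its two triangles", {
  m <- mcl(barbell_network())
  expect_length(m$clusters, 2)
  expect_identical(m$clusters[[1]], c("A", "B", "C"))
  expect_identical(m$clusters[[2]], c("D", "E", "F"))
  expect_length(m$singletons, 0)
  expect_true(m$converged)
})

test_that("MCL handles edgeless graphs and disconnected cliques", {
  edgeless <- network(sprintf("n%d", 1:7))
  m <- mcl(edgeless)
  expect_length(m$clusters, 0)
  expect_length(m$singletons, 7)
  cl <- c(paste0("a", 1:4), paste0("b", 1:4))
  ed <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)))
  two <- network(cl, data.frame(u = ed[, 1], v = ed[, 2]))
  m2 <- mcl(two)
  expect_identical(lapply(m2$clusters, identity),
                   list(paste0("a", 1:4), paste0("b", 1:4)))
})

test_that("MCL partitions the node set and ignores relabeling and scaling", {
  pl <- planted_network(module_sizes = c(10, 10), p_in = 0.8, p_out = 0.05,
                        seed = 5)
  m <- mcl(pl$network)
  covered <- c(unlist(m$clusters), m$singletons)
  expect_setequal(covered, node_ids(pl$network))
  expect_false(anyDuplicated(covered) > 0)
  # relabeling invariance: prefix all ids, same partition up to renaming
  relab <- pl$network
  map <- setNames(paste0("x_", node_ids(relab)), node_ids(relab))
  relab$nodes$id <- unname(map[relab$nodes$id])
  relab$edges$u <- unname(map[relab$edges$u])
  relab$edges$v <- unname(map[relab$edges$v])
  m2 <- mcl(relab)
  expect_identical(lapply(m$clusters, function(x) unname(map[x])),
                   m2$clusters)
  # uniform weight scaling invariance
  scaled <- pl$network
  scaled$edges$weight <- scaled$edges$weight * 7
  m3 <- mcl(scaled)
  expect_identical(m$clusters, m3$clusters)
})

test_that("MCL recovers planted modules at moderate inflation", {
  # inflation 1.6 keeps flow coarse enough to reassemble modules of
  # within-density 0.3; higher inflation fragments them (see vignette)
  aris <- vapply(1:5, function(s) {
    pl <- planted_network(seed = s)
    m <- mcl(pl$network, inflation = 1.6)
    memb <- membership_of(m)
    mclust::adjustedRandIndex(memb, pl$labels[names(memb)])
  }, numeric(1))
  expect_gte(mean(aris), 0.85)
})

test_that("MCODE finds the 4-clique and haircuts the pendant", {
  m <- mcode(clique_pendant_network())
  expect_length(m$clusters, 1)
  expect_identical(m$clusters[[1]], c("A", "B", "C", "D"))
  expect_identical(m$singletons, "E")
})

test_that("MCODE yields nothing on edgeless graphs and splits components", {
  expect_length(mcode(network(sprintf("n%d", 1:4)))$clusters, 0)
  cl <- c(paste0("a", 1:4), paste0("b", 1:4))
  ed <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)))
  m <- mcode(network(cl, data.frame(u = ed[, 1], v = ed[, 2])))
  expect_length(m$clusters, 2)
  expect_setequal(m$clusters[[1]], paste0("a", 1:4))
  expect_setequal(m$clusters[[2]], paste0("b", 1:4))
})

test_that("MCODE is invariant to input node order", {
  base <- clique_pendant_network()
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(nrow(base$nodes))
    shuffled <- base
    shuffled$nodes <- base$nodes[perm, , drop = FALSE]
    rownames(shuffled$nodes) <- NULL
    m <- mcode(shuffled)
    expect_identical(m$clusters, mcode(base)$clusters)
  }
})

test_that("cluster promotion creates size-ordered disjoint groups", {
  m <- mcl(barbell_network())
  net <- clusters_to_groups(barbell_network(), m)
  expect_length(net$groups, 2)
  expect_identical(net$groups$cluster_1$members, c("A", "B", "C"))
  # top_k larger than available: no padding
  net2 <- clusters_to_groups(barbell_network(), m, top_k = 5)
  expect_length(net2$groups, 2)
  # top_k = 1 takes the largest only
  m2 <- mcl(network(c("A", "B", "C", "D", "E"),
                    data.frame(u = c("A", "B", "C", "D"),
                               v = c("B", "C", "A", "E"))))
  sizes <- lengths(m2$clusters)
  net3 <- clusters_to_groups(network(c("A", "B", "C", "D", "E"),
                                     data.frame(u = c("A", "B", "C", "D"),
                                                v = c("B", "C", "A", "E"))),
                             m2, top_k = 1)
  expect_length(net3$groups, 1)
  expect_length(net3$groups$cluster_1$members, max(sizes))
  # overlapping clusters refuse promotion
  fake <- structure(list(clusters = list(c("A", "B"), c("B", "C")),
                         scores = c(1, 1), singletons = character(),
                         params_used = list(), algorithm = "mcode",
                         converged = TRUE), class = "modnet_modules")
  expect_error(clusters_to_groups(barbell_network(), fake), "overlap")
})
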