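test_that("seed selection applies strict OR thresholds", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    mut_freq = c(0.03, 0.02, 0.01, 0.00),
                    cna_freq = c(0.00, 0.03, 0.05, 0.01))
  sel <- select_seeds(tab)
  expect_true("g1" %in% sel)      # 0.03 > 0.02 via mutation
  expect_false("g2" %in% sel)     # both exactly at threshold: strict >
  expect_true("g3" %in% sel)      # 0.05 > 0.03 via CNA
  expect_false("g4" %in% sel)
  expect_warning(
    sel0 <- select_seeds(data.frame(gene = "g", mut_freq = 0, cna_freq = 0)),
    "no gene")
  expect_length(sel0, 0)
  expect_error(select_seeds(tab[0, ]), "empty")
  expect_error(select_seeds(data.frame(gene = "g", mut_freq = 2, cna_freq = 0)),
               "0,1")
})

test_that("shortest-path extraction keeps exactly the tied shortest paths", {
  # unique length-2 path: linker included and flagged
  n1 <- network(c("A", "L1", "B"),
                data.frame(u = c("A", "L1"), v = c("L1", "B")))
  r1 <- extract_paths(n1, c("A", "B"), 2)
  expect_setequal(node_ids(r1), c("A", "L1", "B"))
  expect_true(r1$nodes$linker[r1$nodes$id == "L1"])
  expect_true(all(r1$nodes$seed[r1$nodes$id %in% c("A", "B")]))
  # direct edge exists: the length-2 detour is NOT shortest, excluded
  n2 <- network(c("A", "L1", "B"),
                data.frame(u = c("A", "A", "L1"), v = c("B", "L1", "B")))
  r2 <- extract_paths(n2, c("A", "B"), 2)
  expect_setequal(node_ids(r2), c("A", "B"))
  expect_identical(n_edges(r2), 1L)
  # two tied shortest paths: both linkers included
  n3 <- network(c("A", "L1", "L2", "B"),
                data.frame(u = c("A", "L1", "A", "L2"),
                           v = c("L1", "B", "L2", "B")))
  r3 <- extract_paths(n3, c("A", "B"), 2)
  expect_setequal(node_ids(r3), c("A", "L1", "L2", "B"))
  expect_identical(n_edges(r3), 4L)
})

test_that("pairs beyond the distance bound contribute nothing", {
  chain <- network(c("A", "x", "y", "B"),
                   data.frame(u = c("A", "x", "y"), v = c("x", "y", "B")))
  r <- suppressWarnings(extract_paths(chain, c("A", "B"), 2))
  expect_setequal(node_ids(r), c("A", "B"))  # dist 3 > 2: seeds only
  expect_identical(n_edges(r), 0L)
})

test_that("extraction output is a subgraph containing all present seeds", {
  set.seed(7)
  pl <- planted_network(module_sizes = c(8, 8), p_in = 0.5, p_out = 0.1,
                        seed = 7)
  seeds <- sample(node_ids(pl$network), 5)
  r <- suppressWarnings(extract_paths(pl$network, seeds, 2))
  expect_true(all(node_ids(r) %in% node_ids(pl$network)))
  key_bg <- paste(pl$network$edges$u, pl$network$edges$v)
  expect_true(all(paste(r$edges$u, r$edges$v) %in% key_bg))
  expect_true(all(seeds %in% node_ids(r)))
})

test_that("linker p-value matches the brute-force tail oracle", {
  expect_equal(linker_pvalue(20, 5, 6, 4), 540 / 38760, tolerance = 1e-12)
  expect_identical(linker_pvalue(20, 5, 6, 0), 1)
  expect_identical(linker_pvalue(8, 8, 8, 8), 1)  # degenerate universe
  expect_error(linker_pvalue(10, 4, 3, 4), "violate")
  set.seed(42)
  for (i in 1:200) {
    N <- sample(5:30, 1); s <- sample(1:N, 1); k <- sample(1:N, 1)
    x <- sample(0:min(s, k), 1)
    expect_equal(linker_pvalue(N, s, k, x), hyper_tail_oracle(N, s, k, x),
                 tolerance = 1e-10)
  }
  # monotone non-increasing in x
  for (x in 1:5)
    expect_lte(linker_pvalue(20, 8, 6, x), linker_pvalue(20, 8, 6, x - 1))
})

test_that("linker filtering removes only insignificant linkers, never seeds", {
  # background engineered so linker L has (N=20, s=5, k=6, x=4): p ~ 0.0139
  seeds <- sprintf("S%d", 1:5)
  others <- sprintf("o%02d", 1:14)
  # L adjacent to 4 seeds and 2 others (k=6, x=4) in a 20-node background
  bg <- network(c(seeds, "L", others))
  bg <- add_edges(bg, data.frame(u = "L", v = c(seeds[1:4], others[1:2])))
  # a path S1-L-S2 exists, so extraction keeps L as linker
  ext <- suppressWarnings(extract_paths(bg, seeds, 2))
  expect_true("L" %in% node_ids(ext))
  filt <- filter_linkers(ext, bg, alpha = 0.01)
  rec <- attr(filt, "linker_records")
  expect_equal(rec$p_value[rec$gene == "L"], 540 / 38760, tolerance = 1e-12)
  expect_false("L" %in% node_ids(filt))          # 0.0139 >= 0.01: removed
  expect_true(all(seeds %in% node_ids(filt)))    # seeds survive isolation
  # alpha = 1 is the identity
  filt1 <- filter_linkers(ext, bg, alpha = 1)
  expect_setequal(node_ids(filt1), node_ids(ext))
  # and a network with no linkers passes through unchanged
  noL <- suppressWarnings(extract_paths(
    network(c("A", "B"), data.frame(u = "A", v = "B")), c("A", "B"), 2))
  expect_setequal(node_ids(filter_linkers(noL, bg, 0.01)), c("A", "B"))
})

test_that("linker survivors shrink monotonically as alpha decreases", {
  set.seed(3)
  pl <- planted_network(module_sizes = c(10, 10, 10), p_in = 0.6,
                        p_out = 0.05, seed = 3)
  seeds <- node_ids(pl$network)[c(1:3, 11:13, 21:23)]
  ext <- suppressWarnings(extract_paths(pl$network, seeds, 2))
  alphas <- c(1, 0.5, 0.1, 0.01, 0.001)
  kept <- lapply(alphas, function(a) {
    rec <- attr(filter_linkers(ext, pl$network, a), "linker_records")
    rec$gene[rec$kept]
  })
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
})

test_that("correlation weighting stores signed r and |r| similarity", {
  net <- network(c("A", "B", "C", "D"),
                 data.frame(u = c("A", "A", "C"), v = c("B", "C", "D")))
  expr <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4),
                C = c(4, 3, 2, 1), D = c(1, 2, 3, 10))
  w <- weight_by_correlation(net, expr)
  e <- w$edges
  expect_equal(e$weight[e$u == "A" & e$v == "B"], 1.0)
  expect_equal(e$weight[e$u == "A" & e$v == "C"], -1.0)
  expect_equal(e$weight[e$u == "C" & e$v == "D"],
               cor(c(4, 3, 2, 1), c(1, 2, 3, 10)))
  expect_equal(e$similarity, abs(e$weight))
  # x=(1,2,3,4), y=(1,2,3,10) -> r ~ 0.8528 (direct formula)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 10)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(abs(e$weight[e$u == "C" & e$v == "D"]), r_direct,
               tolerance = 1e-10)
  # missing gene keeps weight 1 with flag; zero variance gives 0
  net2 <- network(c("A", "Z"), data.frame(u = "A", v = "Z"))
  expect_warning(w2 <- weight_by_correlation(net2, expr), "missing")
  expect_equal(w2$edges$weight, 1)
  expect_true(w2$edges$weight_missing)
  expr0 <- rbind(A = c(1, 2, 3), B = c(5, 5, 5))
  net3 <- network(c("A", "B"), data.frame(u = "A", v = "B"))
  expect_warning(w3 <- weight_by_correlation(net3, expr0), "zero-variance")
  expect_equal(w3$edges$weight, 0)
  expect_error(weight_by_correlation(net3, expr0[, 1:2, drop = FALSE]),
               "samples")
})
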