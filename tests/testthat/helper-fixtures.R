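# Shared fixtures and independent oracles.

# Exact hypergeometric upper tail by direct summation of binomials.
# choose() is exact in double precision for N <= 30, so this is an
# arbitrary-precision-grade oracle on that range, independent of phyper.
hyper_tail_oracle <- function(N, s, k, x) {
  if (x == 0) return(1)
  i <- x:min(k, s)
  sum(choose(s, i) * choose(N - s, k - i)) / choose(N, k)
}

# Benjamini-Hochberg step-up from the definition: order p ascending,
# q_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, mapped back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# two triangles joined by one edge
barbell_network <- function() {
  network(LETTERS[1:6], data.frame(
    u = c("A", "A", "B", "C", "D", "D", "E"),
    v = c("B", "C", "C", "D", "E", "F", "F")))
}

# 4-clique A-D plus pendant E on D
clique_pendant_network <- function() {
  network(c("A", "B", "C", "D", "E"), data.frame(
    u = c("A", "A", "A", "B", "B", "C", "D"),
    v = c("B", "C", "D", "C", "D", "D", "E")))
}

# two 5-cliques, each its own group
two_clique_groups <- function() {
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  ed <- rbind(t(utils::combn(a, 2)), t(utils::combn(b, 2)))
  net <- network(c(a, b), data.frame(u = ed[, 1], v = ed[, 2]))
  net <- add_group(net, a, "ga")
  add_group(net, b, "gb")
}

# flatten a modnet_modules into a named membership vector
# (each singleton becomes its own cluster)
membership_of <- function(result, include_singletons = TRUE) {
  memb <- integer(0)
  for (i in seq_along(result$clusters))
    memb[result$clusters[[i]]] <- i
  if (include_singletons && length(result$singletons)) {
    extra <- seq_along(result$singletons) + length(result$clusters)
    memb[result$singletons] <- extra
  }
  memb
}

# three-term is_a chain ontology plus an obsolete term
write_tiny_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid process",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "namespace: biological_process", "is_a: GO:0000002 ! mid process", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", ""),
    path)
  path
}

# minimal AnnotationMap with one term of K genes in a universe of N
ann_fixture <- function(N, K, term = "T1") {
  genes <- sprintf("g%02d", seq_len(N))
  tg <- genes[seq_len(K)]
  structure(list(direct = stats::setNames(list(tg), term),
                 propagated = stats::setNames(list(tg), term),
                 universe = genes),
            class = "modnet_annotations")
}
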