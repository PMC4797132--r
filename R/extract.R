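#' Default parameters for altered-network extraction
#'
#' The case-study defaults: seed genes are those recurrently altered by
#' somatic mutation (patient frequency > 0.02) or copy-number aberration
#' (patient frequency > 0.03); the subnetwork is built from all shortest
#' paths between seed pairs at distance <= 2 in a score > 900 background;
#' linkers are retained at p < 0.01 (unadjusted). All inequalities strict.
#'
#' @param max_distance pair-distance bound for shortest-path extraction.
#' @param linker_alpha significance level for linker retention.
#' @param min_score background score threshold (strict `>`).
#' @param mut_freq_min,cna_freq_min seed-selection thresholds (strict `>`).
#' @param adjust multiple-testing adjustment for linker p-values:
#'   `"none"` (default) or `"bh"`.
#' @return a named list of class `modnet_extraction_params`.
#' @export
extraction_params <- function(max_distance = 2L, linker_alpha = 0.01,
                              min_score = 900, mut_freq_min = 0.02,
                              cna_freq_min = 0.03,
                              adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(max_distance >= 1, linker_alpha > 0, linker_alpha <= 1,
            mut_freq_min >= 0, mut_freq_min <= 1,
            cna_freq_min >= 0, cna_freq_min <= 1)
  structure(list(max_distance = as.integer(max_distance),
                 linker_alpha = linker_alpha, min_score = min_score,
                 mut_freq_min = mut_freq_min, cna_freq_min = cna_freq_min,
                 adjust = adjust),
            class = "modnet_extraction_params")
}

#' Select seed genes from an alteration table
#'
#' A gene is a seed when its mutation frequency strictly exceeds
#' `mut_freq_min` OR its CNA frequency strictly exceeds `cna_freq_min`.
#'
#' @param tab data.frame with columns `gene`, `mut_freq`, `cna_freq`
#'   (frequencies as fractions in \[0,1\]).
#' @param params an [extraction_params()] list.
#' @return character vector of seed gene ids (possibly empty, with a
#'   warning).
#' @export
select_seeds <- function(tab, params = extraction_params()) {
  if (!nrow(tab)) stop("alteration table is empty", call. = FALSE)
  stopifnot(all(c("gene", "mut_freq", "cna_freq") %in% names(tab)))
  if (any(tab$mut_freq < 0 | tab$mut_freq > 1 |
          tab$cna_freq < 0 | tab$cna_freq > 1, na.rm = TRUE))
    stop("alteration frequencies must lie in [0,1]", call. = FALSE)
  if (anyDuplicated(tab$gene)) stop("duplicate gene ids", call. = FALSE)
  sel <- tab$gene[tab$mut_freq > params$mut_freq_min |
                  tab$cna_freq > params$cna_freq_min]
  if (!length(sel)) warning("no gene passes the alteration thresholds")
  as.character(sel)
}

#' Extract the all-shortest-paths subnetwork among seeds
#'
#' For every unordered seed pair at graph distance <= `d` (unweighted
#' hops), every node and edge on ANY shortest path between them enters the
#' result; pairs farther apart contribute nothing. Non-seed nodes in the
#' result are flagged `linker`; seeds are flagged `seed`.
#'
#' @param background a `modnet_network` (typically score-filtered).
#' @param seeds character vector of seed ids; seeds absent from the
#'   background are dropped with a warning.
#' @param d pair-distance bound (>= 1).
#' @return a `modnet_network`, subgraph of `background`.
#' @export
extract_paths <- function(background, seeds, d = 2L) {
  stopifnot_network(background)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  absent <- setdiff(seeds, node_ids(background))
  if (length(absent))
    warning(sprintf("dropping %d seed(s) absent from the background",
                    length(absent)))
  seeds <- intersect(unique(seeds), node_ids(background))
  if (length(seeds) < 2) {
    warning("fewer than 2 seeds found in background; returning seeds only")
    res <- induced_subnet(background, seeds)
    res$edges <- res$edges[0, , drop = FALSE]
    if (length(seeds)) res <- set_role(res, seeds, "seed")
    return(res)
  }
  g <- as_igraph(background)
  dist <- igraph::distances(g, v = seeds, to = seeds, weights = NA)
  keep_nodes <- character()
  keep_edges <- character()
  for (i in seq_along(seeds)) {
    targets <- seeds[-seq_len(i)]
    targets <- targets[is.finite(dist[i, targets]) & dist[i, targets] <= d]
    if (!length(targets)) next
    asp <- igraph::all_shortest_paths(g, from = seeds[i], to = targets,
                                      weights = NA)$vpaths
    for (p in asp) {
      ids <- igraph::as_ids(p)
      keep_nodes <- c(keep_nodes, ids)
      if (length(ids) > 1) {
        a <- ids[-length(ids)]; b <- ids[-1]
        keep_edges <- c(keep_edges,
                        paste(pmin(a, b), pmax(a, b), sep = "\r"))
      }
    }
  }
  keep_nodes <- unique(c(seeds, keep_nodes))
  res <- induced_subnet(background, keep_nodes)
  # keep only edges that lie on some shortest seed-pair path
  key <- paste(res$edges$u, res$edges$v, sep = "\r")
  res$edges <- res$edges[key %in% unique(keep_edges), , drop = FALSE]
  rownames(res$edges) <- NULL
  res <- set_role(res, seeds, "seed")
  linkers <- setdiff(node_ids(res), seeds)
  if (length(linkers)) res <- set_role(res, linkers, "linker")
  res
}

#' Hypergeometric linker significance
#'
#' Upper-tail probability that a gene of global degree `k` in a background
#' of `N` nodes hits at least `x` of the `s` seed nodes among its
#' neighbors, under random neighbor draws without replacement:
#' \deqn{p = \sum_{i=x}^{\min(k,s)} \binom{s}{i}\binom{N-s}{k-i} / \binom{N}{k}.}
#' Small p marks a linker whose connectivity to the seed set is
#' statistically surprising.
#'
#' @param N background node count (universe size).
#' @param s number of seeds in the background.
#' @param k the candidate linker's degree in the background.
#' @param x number of its neighbors that are seeds.
#' @return the tail probability in \[0,1\].
#' @export
linker_pvalue <- function(N, s, k, x) {
  if (any(c(N, s, k, x) < 0) || s > N || k > N || x > min(k, s))
    stop("linker_pvalue: arguments violate 0 <= x <= min(k,s) <= N",
         call. = FALSE)
  if (x == 0) return(1)
  stats::phyper(x - 1, m = s, n = N - s, k = k, lower.tail = FALSE)
}

#' Filter linkers by connectivity significance
#'
#' Tests every linker-flagged node of `net` against the seed set using
#' [linker_pvalue()] with universe `N` = node count of `background` (the
#' score-filtered sampling frame), degree `k` = the linker's background
#' degree, and `x` = its background neighbors that are seeds. Linkers with
#' (adjusted) p >= `alpha` are removed together with their incident edges;
#' seeds are never removed even if left isolated. The test is applied once
#' to the initial candidate set (no iterative re-testing).
#'
#' @param net output of [extract_paths()].
#' @param background the background network the extraction ran against.
#' @param alpha significance level (default 0.01).
#' @param adjust `"none"` (default) or `"bh"` for Benjamini-Hochberg
#'   adjustment across the tested linkers.
#' @return the filtered network, with the per-linker test table attached as
#'   attribute `"linker_records"` (columns `gene`, `k`, `x`, `p_value`,
#'   `p_adjusted`, `kept`).
#' @export
filter_linkers <- function(net, background, alpha = 0.01,
                           adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot_network(net); stopifnot_network(background)
  linkers <- net$nodes$id[net$nodes$linker]
  seeds <- net$nodes$id[net$nodes$seed]
  if (!length(linkers)) {
    attr(net, "linker_records") <-
      data.frame(gene = character(), k = integer(), x = integer(),
                 p_value = numeric(), p_adjusted = numeric(),
                 kept = logical())
    return(net)
  }
  N <- n_nodes(background)
  s <- length(intersect(seeds, node_ids(background)))
  rec <- data.frame(gene = linkers, k = NA_integer_, x = NA_integer_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(linkers)) {
    nb <- node_neighbors(background, linkers[i])
    rec$k[i] <- length(nb)
    rec$x[i] <- length(intersect(nb, seeds))
    rec$p_value[i] <- linker_pvalue(N, s, rec$k[i], rec$x[i])
  }
  rec$p_adjusted <- if (adjust == "bh")
    stats::p.adjust(rec$p_value, method = "BH") else rec$p_value
  rec$kept <- rec$p_adjusted < alpha
  out <- remove_nodes(net, rec$gene[!rec$kept])
  attr(out, "linker_records") <- rec[order(rec$p_value, rec$gene), ]
  out
}

#' Weight edges by expression correlation
#'
#' Sets every edge's `weight` to the Pearson correlation of the two genes'
#' expression profiles across shared samples, as a co-expression overlay on
#' the interaction network. The signed r is stored in `weight`; its
#' magnitude goes to a `similarity` edge attribute, which clustering
#' consumes (flow requires non-negative affinities).
#'
#' @param net a `modnet_network`.
#' @param expr numeric matrix, genes x samples, rownames = gene ids.
#' @param min_samples minimum number of samples required (default 3).
#' @return the network with `weight` and `similarity` edge columns; edges
#'   with a gene missing from `expr` keep weight 1 and are flagged in the
#'   `weight_missing` edge column; zero-variance genes give weight 0 with a
#'   warning.
#' @export
weight_by_correlation <- function(net, expr, min_samples = 3L) {
  stopifnot_network(net)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (ncol(expr) < min_samples)
    stop(sprintf("need >= %d samples, got %d", min_samples, ncol(expr)),
         call. = FALSE)
  ed <- net$edges
  ed$weight_missing <- FALSE
  if (nrow(ed)) {
    n_zero_var <- 0L
    for (i in seq_len(nrow(ed))) {
      u <- ed$u[i]; v <- ed$v[i]
      if (!(u %in% rownames(expr)) || !(v %in% rownames(expr))) {
        ed$weight[i] <- 1.0
        ed$weight_missing[i] <- TRUE
        next
      }
      xu <- expr[u, ]; xv <- expr[v, ]
      if (stats::sd(xu) == 0 || stats::sd(xv) == 0) {
        ed$weight[i] <- 0
        n_zero_var <- n_zero_var + 1L
      } else {
        ed$weight[i] <- stats::cor(xu, xv)
      }
    }
    if (any(ed$weight_missing))
      warning(sprintf("%d edge(s) with gene(s) missing from expression matrix keep weight 1",
                      sum(ed$weight_missing)))
    if (n_zero_var > 0)
      warning(sprintf("%d edge(s) with a zero-variance gene set to weight 0",
                      n_zero_var))
  }
  ed$similarity <- abs(ed$weight)
  net$edges <- ed
  net
}
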