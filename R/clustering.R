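#' Module (cluster) results
#'
#' Container returned by [mcl()] and [mcode()]: clusters as node-id sets
#' ordered by size descending (ties by lexicographically smallest member),
#' a per-cluster score (edge density of the induced subgraph; for MCODE,
#' density times size as in the original scoring), the unclustered
#' singletons, and the parameters used.
#'
#' @param clusters list of character vectors.
#' @param scores numeric vector, one per cluster.
#' @param singletons character vector of unclustered node ids.
#' @param params_used named list.
#' @param algorithm label, e.g. `"mcl"`.
#' @param converged logical (MCL only).
#' @return an object of class `modnet_modules`.
#' @keywords internal
module_result <- function(clusters, scores, singletons, params_used,
                          algorithm, converged = TRUE) {
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) x[1], character(1)))
  structure(list(clusters = clusters[ord], scores = scores[ord],
                 singletons = sort(singletons), params_used = params_used,
                 algorithm = algorithm, converged = converged),
            class = "modnet_modules")
}

#' @export
print.modnet_modules <- function(x, ...) {
  cat(sprintf("%s clustering: %d cluster(s), %d singleton(s)%s\n",
              toupper(x$algorithm), length(x$clusters), length(x$singletons),
              if (!x$converged) " [not converged]" else ""))
  if (length(x$clusters)) {
    sizes <- lengths(x$clusters)
    show <- utils::head(seq_along(sizes), 10)
    for (i in show)
      cat(sprintf("  cluster_%d: %d nodes (score %.3f)\n",
                  i, sizes[i], x$scores[i]))
    if (length(sizes) > 10) cat(sprintf("  ... and %d more\n", length(sizes) - 10))
  }
  invisible(x)
}

cluster_density <- function(net, members) {
  if (length(members) < 2) return(0)
  sub <- suppressWarnings(induced_subnet(net, members))
  n <- length(members)
  nrow(sub$edges) / (n * (n - 1) / 2)
}

#' Markov clustering (MCL)
#'
#' Simulates flow on the network: a column-stochastic matrix built from the
#' (similarity-weighted) adjacency with self-loops is alternately
#' *expanded* (matrix power, spreading flow) and *inflated* (entrywise
#' power followed by column renormalization, strengthening strong currents)
#' until the flow matrix is stable; clusters are read off the attractor
#' structure of the limit. Self-loops of weight equal to each node's
#' maximum incident weight are added to prevent period-2 oscillation.
#'
#' @param net a non-empty `modnet_network`.
#' @param inflation inflation exponent, > 1 (default 2).
#' @param expansion expansion power, integer >= 2 (default 2).
#' @param pruning_threshold entries below this are zeroed after each
#'   inflation (default 1e-5).
#' @param max_iter iteration cap (default 100); non-convergence returns the
#'   current interpretation with `converged = FALSE` and a warning, never an
#'   error.
#' @param convergence_eps stop when the maximum column-wise change drops
#'   below this (default 1e-8).
#' @param use_weights use the `similarity` edge attribute (|r|) when
#'   present, else |weight| (default `TRUE`); `FALSE` treats the graph as
#'   unweighted.
#' @return a `modnet_modules` whose clusters plus singletons partition the
#'   node set. Clusters of size 1 are reported as singletons.
#' @export
mcl <- function(net, inflation = 2.0, expansion = 2L,
                pruning_threshold = 1e-5, max_iter = 100L,
                convergence_eps = 1e-8, use_weights = TRUE) {
  stopifnot_network(net)
  if (n_nodes(net) == 0) stop("network is empty", call. = FALSE)
  stopifnot(inflation > 1, expansion >= 2)
  ids <- sort(node_ids(net))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    w <- if (!use_weights) rep(1, nrow(net$edges))
         else if ("similarity" %in% names(net$edges)) net$edges$similarity
         else abs(net$edges$weight)
    iu <- match(net$edges$u, ids); iv <- match(net$edges$v, ids)
    A[cbind(iu, iv)] <- w
    A[cbind(iv, iu)] <- w
  }
  # self-loop = max incident weight (1 for isolated nodes)
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_old <- M
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    M <- Mexp^inflation
    M[M < pruning_threshold] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - M_old)) < convergence_eps) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations", max_iter))
  # attractors: nodes with positive flow on the diagonal of the limit
  tau <- max(pruning_threshold, 1e-9)
  attractors <- ids[diag(M) > tau]
  if (!length(attractors)) attractors <- ids[which.max(diag(M))]
  # attractor systems: connected components among attractors in the limit
  sub <- M[attractors, attractors, drop = FALSE]
  ga <- igraph::graph_from_adjacency_matrix((sub + t(sub)) > tau,
                                            mode = "undirected", diag = FALSE)
  comp <- igraph::components(ga)$membership
  # deterministic system labels: lexicographically smallest member id
  sys_of <- split(attractors, comp)
  sys_labels <- vapply(sys_of, function(x) sort(x)[1], character(1))
  # assign every node to the system with the largest limit-matrix entry;
  # ties go to the lexicographically smaller system label
  assign <- character(n)
  for (j in seq_len(n)) {
    flow <- vapply(sys_of, function(members) sum(M[members, j]), numeric(1))
    best <- which(flow == max(flow))
    assign[j] <- sys_labels[best[order(sys_labels[best])[1]]]
  }
  parts <- split(ids, assign)
  sizes <- lengths(parts)
  clusters <- unname(parts[sizes >= 2])
  singles <- unlist(parts[sizes == 1], use.names = FALSE)
  scores <- vapply(clusters, function(m) cluster_density(net, m), numeric(1))
  module_result(clusters, scores, if (is.null(singles)) character() else singles,
                list(algorithm = "mcl", inflation = inflation,
                     expansion = expansion,
                     pruning_threshold = pruning_threshold,
                     max_iter = max_iter, convergence_eps = convergence_eps,
                     use_weights = use_weights, iterations = it),
                "mcl", converged)
}

#' MCODE molecular-complex detection
#'
#' Vertex weighting followed by greedy complex growth: each vertex is
#' weighted by the core number of the highest k-core of its closed
#' neighborhood times that core's edge density; complexes grow outward from
#' unvisited highest-weight seeds, admitting neighbors whose weight is at
#' least `(1 - vertex_weight_percentage)` of the seed weight. Vertices with
#' degree below `degree_cutoff` are never seeds and carry weight 0. The
#' optional haircut removes complex members bound by a single edge.
#' Complexes are disjoint (grown nodes are marked visited). All ties break
#' lexicographically by node id, so the result is independent of input
#' order.
#'
#' @param net a non-empty `modnet_network`.
#' @param vertex_weight_percentage admission slack in (0,1\] (default 0.2).
#' @param degree_cutoff minimum degree for a scored vertex (default 2).
#' @param haircut remove degree-1 complex members (default `TRUE`).
#' @param fluff add high-density boundary neighbors after growth
#'   (default `FALSE`); fluffed nodes may not overlap other complexes.
#' @param max_depth growth radius from the seed (default 100).
#' @return a `modnet_modules`; `scores` = core density x size, the original
#'   complex score.
#' @export
mcode <- function(net, vertex_weight_percentage = 0.2, degree_cutoff = 2L,
                  haircut = TRUE, fluff = FALSE, max_depth = 100L) {
  stopifnot_network(net)
  if (n_nodes(net) == 0) stop("network is empty", call. = FALSE)
  stopifnot(vertex_weight_percentage > 0, vertex_weight_percentage <= 1)
  ids <- sort(node_ids(net))
  g <- as_igraph(net)
  deg <- igraph::degree(g)[ids]
  adj <- lapply(ids, function(v)
    sort(igraph::neighbors(g, v)$name))
  names(adj) <- ids
  vw <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    if (deg[v] < degree_cutoff) next
    nbhd <- c(v, adj[[v]])
    sub <- igraph::induced_subgraph(g, nbhd)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_v <- names(core)[core == kmax]
    core_sub <- igraph::induced_subgraph(sub, core_v)
    nc <- length(core_v)
    dens <- if (nc < 2) 0 else
      igraph::ecount(core_sub) / (nc * (nc - 1) / 2)
    vw[v] <- kmax * dens
  }
  visited <- stats::setNames(logical(length(ids)), ids)
  clusters <- list()
  seed_order <- ids[order(-vw[ids], ids)]
  for (seed in seed_order) {
    if (visited[seed] || vw[seed] <= 0 || deg[seed] < degree_cutoff) next
    thr <- vw[seed] * (1 - vertex_weight_percentage)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- character()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!visited[w] && vw[w] >= thr) {
            visited[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- sort(nxt)
      depth <- depth + 1L
    }
    if (haircut && length(members) > 1) {
      repeat {
        indeg <- vapply(members, function(v)
          length(intersect(adj[[v]], members)), integer(1))
        drop <- members[indeg < 2]
        if (!length(drop) || length(members) <= 2) break
        visited[drop] <- FALSE
        members <- setdiff(members, drop)
      }
    }
    if (fluff) {
      boundary <- setdiff(unique(unlist(adj[members])), members)
      for (w in sort(boundary)) {
        if (visited[w]) next
        nbhd <- c(w, adj[[w]])
        nn <- length(nbhd)
        dens_w <- if (nn < 2) 0 else {
          sub <- igraph::induced_subgraph(g, nbhd)
          igraph::ecount(sub) / (nn * (nn - 1) / 2)
        }
        if (dens_w > 0.5) { visited[w] <- TRUE; members <- c(members, w) }
      }
    }
    if (length(members) >= 2) clusters[[length(clusters) + 1L]] <- members
  }
  clustered <- unlist(clusters, use.names = FALSE)
  scores <- vapply(clusters, function(m)
    cluster_density(net, m) * length(m), numeric(1))
  module_result(clusters, scores, setdiff(ids, clustered),
                list(algorithm = "mcode",
                     vertex_weight_percentage = vertex_weight_percentage,
                     degree_cutoff = degree_cutoff, haircut = haircut,
                     fluff = fluff, max_depth = max_depth),
                "mcode")
}

#' Promote clusters to groups
#'
#' The `top_k` largest non-singleton clusters become groups labeled
#' `cluster_1` .. `cluster_k` in size order, so discovered modules can be
#' laid out and styled as units.
#'
#' @param net the clustered `modnet_network`.
#' @param result a `modnet_modules`.
#' @param top_k how many clusters to promote (default: all).
#' @param shape group display shape.
#' @return the network with groups added.
#' @export
clusters_to_groups <- function(net, result, top_k = NULL,
                               shape = c("convex_hull", "rectangle", "circle")) {
  shape <- match.arg(shape)
  stopifnot_network(net)
  if (!inherits(result, "modnet_modules"))
    stop("expected a modnet_modules result", call. = FALSE)
  cl <- result$clusters
  if (!is.null(top_k)) cl <- utils::head(cl, top_k)
  if (length(cl) > 1) {
    all_m <- unlist(cl, use.names = FALSE)
    if (anyDuplicated(all_m))
      stop("promoted clusters overlap; cannot form disjoint groups",
           call. = FALSE)
  }
  for (i in seq_along(cl))
    net <- add_group(net, cl[[i]], label = sprintf("cluster_%d", i),
                     shape = shape)
  net
}
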