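#' Attributed undirected network with groups and hyper-edges
#'
#' `network()` builds the core data structure used throughout modnet: a
#' simple undirected graph (no self-loops, no multi-edges) whose nodes and
#' edges carry typed attributes, extended with two constructs common in
#' pathway visualization platforms:
#'
#' * **group (compound) nodes** -- named, pairwise-disjoint sets of member
#'   nodes with a display shape (`rectangle`, `circle`, `convex_hull`),
#'   typically holding a discovered cluster;
#' * **hyper-edges** -- relations among two or more participants with
#'   free-form roles (e.g. enzyme/substrate/product). Hyper-edges are a
#'   data-model construct only: degree, shortest paths, clustering and
#'   layout forces all ignore them.
#'
#' Nodes additionally carry two role flags, `seed` (a gene selected by
#' alteration-frequency thresholds) and `linker` (a non-seed gene on a
#' shortest path between seeds). A node is never both: seed wins.
#'
#' @param nodes character vector of node ids (whitespace-stripped,
#'   case-sensitive, unique, non-empty).
#' @param edges optional data.frame with columns `u`, `v` and optionally
#'   `weight` (signed real, default 1) and `score` (non-negative source
#'   confidence). Duplicate unordered pairs collapse to one edge keeping the
#'   maximum score (and its weight); self-loops are an error.
#' @param name network name.
#' @return an object of class `modnet_network`.
#' @examples
#' net <- network(c("A", "B", "C"),
#'                data.frame(u = c("A", "B"), v = c("B", "C")))
#' node_degree(net, "B")
#' @export
network <- function(nodes = character(), edges = NULL, name = "network") {
  nodes <- trimws(as.character(nodes))
  if (any(nodes == "")) stop("node ids must be non-empty", call. = FALSE)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  net <- structure(list(
    name = name,
    nodes = data.frame(id = nodes, seed = logical(length(nodes)),
                       linker = logical(length(nodes)),
                       stringsAsFactors = FALSE),
    edges = data.frame(u = character(), v = character(),
                       weight = numeric(), score = numeric(),
                       stringsAsFactors = FALSE),
    hyperedges = list(),
    groups = list(),
    schema = c(seed = "logical", linker = "logical")
  ), class = "modnet_network")
  if (!is.null(edges) && nrow(edges) > 0) net <- add_edges(net, edges)
  net
}

#' @export
print.modnet_network <- function(x, ...) {
  cat(sprintf("modnet network '%s': %d nodes, %d edges, %d groups, %d hyperedges\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              length(x$groups), length(x$hyperedges)))
  flags <- c(seeds = sum(x$nodes$seed), linkers = sum(x$nodes$linker))
  if (any(flags > 0))
    cat(sprintf("  %d seed, %d linker nodes\n", flags[1], flags[2]))
  invisible(x)
}

node_ids <- function(net) net$nodes$id

#' Number of nodes / edges
#' @param net a `modnet_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

stopifnot_network <- function(net) {
  if (!inherits(net, "modnet_network"))
    stop("expected a modnet_network", call. = FALSE)
}

check_ids <- function(net, ids, what = "node") {
  missing <- setdiff(ids, node_ids(net))
  if (length(missing))
    stop(sprintf("unknown %s id(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Add nodes to a network
#' @param net a `modnet_network`.
#' @param ids character vector of new node ids; ids already present are
#'   silently kept.
#' @return the updated network.
#' @export
add_nodes <- function(net, ids) {
  stopifnot_network(net)
  ids <- trimws(as.character(ids))
  if (any(ids == "")) stop("node ids must be non-empty", call. = FALSE)
  new <- setdiff(unique(ids), node_ids(net))
  if (length(new)) {
    add <- net$nodes[0, , drop = FALSE][seq_along(new), , drop = FALSE]
    add$id <- new
    add$seed <- FALSE
    add$linker <- FALSE
    for (col in setdiff(names(add), c("id", "seed", "linker")))
      add[[col]] <- vector(class(net$nodes[[col]]), length(new))[seq_along(new)]
    rownames(add) <- NULL
    net$nodes <- rbind(net$nodes, add)
    rownames(net$nodes) <- NULL
  }
  net
}

# canonical unordered key: u < v lexicographically
canon_edges <- function(df) {
  swap <- df$u > df$v
  tmp <- df$u[swap]; df$u[swap] <- df$v[swap]; df$v[swap] <- tmp
  df
}

#' Add edges to a network
#'
#' Endpoints not yet present are created. Duplicate unordered pairs
#' (including reciprocal rows) collapse to one undirected edge keeping the
#' maximum score; self-loops are rejected.
#'
#' @param net a `modnet_network`.
#' @param edges data.frame with columns `u`, `v`, and optionally `weight`
#'   and `score`.
#' @return the updated network.
#' @export
add_edges <- function(net, edges) {
  stopifnot_network(net)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$u <- trimws(as.character(edges$u))
  edges$v <- trimws(as.character(edges$v))
  if (any(edges$u == edges$v))
    stop("self-loops are not allowed", call. = FALSE)
  if (is.null(edges$weight)) edges$weight <- 1.0
  if (is.null(edges$score)) edges$score <- NA_real_
  if (any(!is.na(edges$score) & edges$score < 0))
    stop("edge scores must be >= 0", call. = FALSE)
  net <- add_nodes(net, c(edges$u, edges$v))
  keep <- intersect(c("u", "v", "weight", "score"), names(edges))
  edges <- canon_edges(edges[keep])
  all <- rbind(net$edges[keep], edges)
  # keep max score per unordered pair (stable: first occurrence on ties)
  key <- paste(all$u, all$v, sep = "\r")
  sc <- ifelse(is.na(all$score), -Inf, all$score)
  ord <- order(key, -sc)
  all <- all[ord[!duplicated(key[ord])], , drop = FALSE]
  all <- all[order(all$u, all$v), , drop = FALSE]
  rownames(all) <- NULL
  net$edges <- all
  net
}

#' Remove nodes (and incident edges, group memberships, hyperedges)
#' @param net a `modnet_network`.
#' @param ids node ids to remove; unknown ids are ignored.
#' @return the updated network.
#' @export
remove_nodes <- function(net, ids) {
  stopifnot_network(net)
  net$nodes <- net$nodes[!net$nodes$id %in% ids, , drop = FALSE]
  net$edges <- net$edges[!(net$edges$u %in% ids | net$edges$v %in% ids), ,
                         drop = FALSE]
  rownames(net$nodes) <- rownames(net$edges) <- NULL
  net$groups <- Filter(function(g) length(g$members) > 0, lapply(net$groups, function(g) {
    g$members <- setdiff(g$members, ids); g
  }))
  net$hyperedges <- Filter(function(h) {
    !any(h$participants$id %in% ids)
  }, net$hyperedges)
  net
}

#' Node degree and neighborhood
#'
#' Binary-edge degree only: hyper-edges never contribute.
#'
#' @param net a `modnet_network`.
#' @param id a single node id.
#' @return `node_degree`: integer; `node_neighbors`: character vector of
#'   adjacent node ids.
#' @export
node_degree <- function(net, id) {
  length(node_neighbors(net, id))
}

#' @rdname node_degree
#' @export
node_neighbors <- function(net, id) {
  stopifnot_network(net)
  check_ids(net, id)
  sort(unique(c(net$edges$v[net$edges$u == id],
                net$edges$u[net$edges$v == id])))
}

#' Set or get a node attribute
#'
#' Attribute names are registered in the network's schema on first use; the
#' declared type (numeric, character or logical) is enforced thereafter.
#'
#' @param net a `modnet_network`.
#' @param name attribute name.
#' @param values named vector (names = node ids) or vector of length
#'   `n_nodes(net)`.
#' @return `set_node_attr`: the updated network; `node_attr`: a named
#'   vector over all nodes.
#' @export
set_node_attr <- function(net, name, values) {
  stopifnot_network(net)
  type <- if (is.numeric(values)) "numeric"
          else if (is.logical(values)) "logical" else "character"
  if (name %in% names(net$schema)) {
    if (net$schema[[name]] != type)
      stop(sprintf("attribute '%s' declared as %s", name, net$schema[[name]]),
           call. = FALSE)
  } else net$schema[name] <- type
  if (!name %in% names(net$nodes))
    net$nodes[[name]] <- vector(type, nrow(net$nodes))
  if (!is.null(names(values))) {
    check_ids(net, names(values))
    net$nodes[[name]][match(names(values), net$nodes$id)] <- unname(values)
  } else {
    if (length(values) != nrow(net$nodes))
      stop("unnamed attribute vector must cover all nodes", call. = FALSE)
    net$nodes[[name]] <- values
  }
  net
}

#' @rdname set_node_attr
#' @export
node_attr <- function(net, name) {
  stopifnot_network(net)
  if (!name %in% names(net$nodes))
    stop(sprintf("no node attribute '%s'", name), call. = FALSE)
  stats::setNames(net$nodes[[name]], net$nodes$id)
}

#' Flag nodes as seeds or linkers
#'
#' A node never carries both flags: setting `seed` clears `linker` and a
#' `linker` flag on a seed node is ignored (seed wins).
#'
#' @param net a `modnet_network`.
#' @param ids node ids to flag.
#' @param role `"seed"` or `"linker"`.
#' @return the updated network.
#' @export
set_role <- function(net, ids, role = c("seed", "linker")) {
  role <- match.arg(role)
  stopifnot_network(net)
  check_ids(net, ids)
  i <- net$nodes$id %in% ids
  if (role == "seed") {
    net$nodes$seed[i] <- TRUE
    net$nodes$linker[i] <- FALSE
  } else {
    net$nodes$linker[i] <- !net$nodes$seed[i] & TRUE
  }
  net
}

#' Add a group (compound node)
#'
#' Groups are hyper-nodes holding member nodes, here the vehicle for
#' displaying clusters. Member sets of distinct groups must be disjoint.
#'
#' @param net a `modnet_network`.
#' @param members non-empty character vector of node ids.
#' @param label display label (also the group id).
#' @param shape one of `"rectangle"`, `"circle"`, `"convex_hull"`.
#' @param style named list of visual style attributes.
#' @return the updated network; the new group is `net$groups[[label]]`.
#' @export
add_group <- function(net, members, label,
                      shape = c("convex_hull", "rectangle", "circle"),
                      style = list()) {
  shape <- match.arg(shape)
  stopifnot_network(net)
  members <- unique(as.character(members))
  if (!length(members)) stop("group members must be non-empty", call. = FALSE)
  check_ids(net, members)
  if (label %in% names(net$groups))
    stop(sprintf("group '%s' already exists", label), call. = FALSE)
  taken <- unlist(lapply(net$groups, `[[`, "members"), use.names = FALSE)
  clash <- intersect(members, taken)
  if (length(clash))
    stop(sprintf("node(s) already grouped: %s", paste(clash, collapse = ", ")),
         call. = FALSE)
  net$groups[[label]] <- list(id = label, label = label,
                              members = sort(members),
                              shape = shape, style = style)
  net
}

#' Add a hyper-edge
#'
#' A relation among two or more participants with roles, e.g. the
#' enzyme/substrate/product structure of a reaction. Hyper-edges live next
#' to the binary graph and are ignored by degree, paths, clustering and
#' layout. Participants must be nodes, never groups.
#'
#' @param net a `modnet_network`.
#' @param participants data.frame with columns `id` and `role` (non-empty
#'   strings), at least 2 rows.
#' @param id optional hyperedge id (default `he<k>`).
#' @return the updated network.
#' @export
add_hyperedge <- function(net, participants, id = NULL) {
  stopifnot_network(net)
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  if (nrow(participants) < 2)
    stop("a hyperedge needs at least 2 participants", call. = FALSE)
  if (any(!nzchar(participants$role)))
    stop("participant roles must be non-empty", call. = FALSE)
  check_ids(net, participants$id)
  if (is.null(id)) id <- sprintf("he%d", length(net$hyperedges) + 1L)
  if (id %in% names(net$hyperedges))
    stop(sprintf("hyperedge '%s' already exists", id), call. = FALSE)
  net$hyperedges[[id]] <- list(id = id,
                               participants = participants[c("id", "role")],
                               attrs = list())
  net
}

#' Induced subnetwork
#'
#' Keeps the given nodes and every edge with both endpoints among them;
#' group memberships and hyperedges are restricted accordingly (a hyperedge
#' survives only if all its participants survive).
#'
#' @param net a `modnet_network`.
#' @param ids node ids to keep; unknown ids are ignored with a warning.
#' @return a new `modnet_network`.
#' @export
induced_subnet <- function(net, ids) {
  stopifnot_network(net)
  unknown <- setdiff(ids, node_ids(net))
  if (length(unknown))
    warning(sprintf("ignoring %d unknown node id(s)", length(unknown)))
  remove_nodes(net, setdiff(node_ids(net), ids))
}

#' Convert between modnet networks and igraph graphs
#'
#' Node attributes, role flags, group membership (attribute `__group`) and
#' coordinates travel as igraph vertex attributes; `weight`, `score` and any
#' further edge attributes as edge attributes. Hyperedges are not
#' representable in igraph and are dropped (use the GraphML sidecar for
#' persistence).
#'
#' @param net a `modnet_network`.
#' @return an undirected igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot_network(net)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$id)
  for (col in setdiff(names(net$nodes), "id"))
    g <- igraph::set_vertex_attr(g, col, value = net$nodes[[col]])
  grp <- rep("", nrow(net$nodes))
  for (gr in net$groups) grp[net$nodes$id %in% gr$members] <- gr$id
  g <- igraph::set_vertex_attr(g, "__group", value = grp)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$u, net$edges$v))
    for (col in setdiff(names(net$edges), c("u", "v")))
      g <- igraph::set_edge_attr(g, col, value = net$edges[[col]])
  }
  g
}

#' @rdname as_igraph
#' @param g an undirected igraph graph with a `name` vertex attribute.
#' @param name network name for the result.
#' @export
from_igraph <- function(g, name = "network") {
  ids <- igraph::vertex_attr(g, "name")
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  net <- network(ids, name = name)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    ed <- data.frame(u = el[, 1], v = el[, 2], stringsAsFactors = FALSE)
    for (col in igraph::edge_attr_names(g))
      ed[[col]] <- igraph::edge_attr(g, col)
    net <- add_edges(net, ed)
    extra <- setdiff(igraph::edge_attr_names(g), c("weight", "score"))
    if (length(extra)) {
      key_in <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
      key_out <- paste(net$edges$u, net$edges$v, sep = "\r")
      for (col in extra)
        net$edges[[col]] <- ed[[col]][match(key_out, key_in)]
    }
  }
  grp <- igraph::vertex_attr(g, "__group")
  # "id" is igraph's own GraphML node identifier (n0, n1, ...), not data
  for (col in setdiff(igraph::vertex_attr_names(g),
                      c("name", "id", "__group"))) {
    vals <- igraph::vertex_attr(g, col)
    if (col %in% c("seed", "linker")) vals <- as.logical(vals)
    net <- set_node_attr(net, col, stats::setNames(vals, ids))
  }
  if (!is.null(grp)) {
    for (gid in setdiff(unique(grp), c("", "NA", NA)))
      net <- add_group(net, ids[which(grp == gid)], label = gid)
  }
  net
}
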