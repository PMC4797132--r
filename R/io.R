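#' Read a SIF interaction file
#'
#' Simple interaction format: whitespace- or tab-delimited lines
#' `source relation target [target2 ...]`. Every source-target pair becomes
#' an undirected edge; the relation string is kept as edge attribute
#' `relation` (first occurrence wins on duplicates). Lines with a single
#' column declare an isolated node.
#'
#' @param path file path.
#' @param name network name.
#' @return a `modnet_network`.
#' @export
read_sif <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  net <- network(name = name)
  edges <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(parts) == 1) {
      net <- add_nodes(net, parts)
    } else if (length(parts) == 2) {
      stop(sprintf("SIF parse error at line %d: 2 columns (need 1 or >= 3)", i),
           call. = FALSE)
    } else {
      edges[[length(edges) + 1L]] <- data.frame(
        u = parts[1], v = parts[3:length(parts)], relation = parts[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    rel <- ed$relation
    net <- add_edges(net, ed[c("u", "v")])
    key_in <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
    key_out <- paste(net$edges$u, net$edges$v, sep = "\r")
    net$edges$relation <- rel[match(key_out, key_in)]
  }
  net
}

#' Read a tabular interaction file
#'
#' Expects at least `source<TAB>target`, optionally a third score column and
#' further attribute columns. A header row is detected heuristically: if the
#' first row's score column is non-numeric, the row is treated as a header.
#'
#' @param path file path.
#' @param score_column name (with header) or index of the score column;
#'   `NULL` for no scores. Default 3 when the file has >= 3 columns and the
#'   column is numeric, else none.
#' @param name network name.
#' @return a `modnet_network`.
#' @export
read_interaction_tsv <- function(path, score_column = NULL,
                                 name = basename(path)) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 2)
    stop(sprintf("format error in %s: need >= 2 columns", path), call. = FALSE)
  header <- NULL
  score_idx <- NULL
  if (!is.null(score_column) && is.numeric(score_column))
    score_idx <- as.integer(score_column)
  if (is.null(score_idx) && (ncol(raw) >= 3)) score_idx <- 3L
  first_score <- if (!is.null(score_idx) && score_idx <= ncol(raw))
    suppressWarnings(as.numeric(raw[1, score_idx])) else NA
  has_header <- (!is.null(score_idx) && score_idx <= ncol(raw) &&
                 is.na(first_score)) ||
                (is.character(score_column) && score_column %in% unlist(raw[1, ]))
  if (has_header) {
    header <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    names(raw) <- header
    if (is.character(score_column)) {
      score_idx <- match(score_column, header)
      if (is.na(score_idx))
        stop(sprintf("score column '%s' not found", score_column), call. = FALSE)
    }
  }
  if (!nrow(raw))
    return(network(name = name))
  ed <- data.frame(u = raw[[1]], v = raw[[2]], stringsAsFactors = FALSE)
  if (!is.null(score_idx)) {
    if (score_idx > ncol(raw))
      stop(sprintf("format error in %s: no column %d", path, score_idx),
           call. = FALSE)
    sc <- suppressWarnings(as.numeric(raw[[score_idx]]))
    bad <- which(is.na(sc) & nzchar(raw[[score_idx]]))
    if (length(bad))
      stop(sprintf("format error in %s at line %d: non-numeric score '%s'",
                   path, bad[1] + has_header, raw[[score_idx]][bad[1]]),
           call. = FALSE)
    if (anyNA(sc))
      stop(sprintf("format error in %s at line %d: missing score",
                   path, which(is.na(sc))[1] + has_header), call. = FALSE)
    ed$score <- sc
  }
  add_edges(network(name = name), ed)
}

hyperedge_sidecar_path <- function(path) {
  paste0(sub("\\.graphml$", "", path), ".hyperedges.json")
}

#' Write / read a network as GraphML
#'
#' Nodes, edges and all attributes are serialized; group membership travels
#' as node attribute `__group`, role flags as `seed`/`linker`, coordinates
#' (when attached via [attach_coords()]) as `x`/`y`. GraphML has no
#' hyperedge standard, so hyperedges and group shapes/styles go to a sidecar
#' JSON file (`<base>.hyperedges.json`), written only when needed and read
#' back automatically.
#'
#' @param net a `modnet_network`.
#' @param path output `.graphml` path.
#' @return `write_graphml`: `path`, invisibly. `read_graphml`: a
#'   `modnet_network`.
#' @export
write_graphml <- function(net, path) {
  stopifnot_network(net)
  g <- as_igraph(net)
  # igraph encodes NA numerics as NaN in graphml; drop all-NA score column
  if ("score" %in% igraph::edge_attr_names(g) &&
      all(is.na(igraph::edge_attr(g, "score"))))
    g <- igraph::delete_edge_attr(g, "score")
  igraph::write_graph(g, path, format = "graphml")
  side <- hyperedge_sidecar_path(path)
  if (length(net$hyperedges) || length(net$groups)) {
    meta <- list(
      name = net$name,
      hyperedges = lapply(unname(net$hyperedges), function(h)
        list(id = h$id, participants = h$participants, attrs = h$attrs)),
      groups = lapply(unname(net$groups), function(gr)
        list(id = gr$id, label = gr$label, shape = gr$shape,
             style = gr$style))
    )
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (file.exists(side)) unlink(side)
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  net <- from_igraph(g, name = sub("\\.graphml$", "", basename(path)))
  side <- hyperedge_sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
    if (!is.null(meta$name)) net$name <- meta$name
    if (length(meta$hyperedges)) {
      hes <- meta$hyperedges
      for (i in seq_len(nrow(hes))) {
        p <- as.data.frame(hes$participants[[i]], stringsAsFactors = FALSE)
        net <- add_hyperedge(net, p, id = hes$id[i])
      }
    }
    if (length(meta$groups)) {
      grs <- meta$groups
      for (i in seq_len(nrow(grs))) {
        gid <- grs$id[i]
        if (gid %in% names(net$groups)) {
          net$groups[[gid]]$shape <- grs$shape[i]
          net$groups[[gid]]$label <- grs$label[i]
          st <- grs$style
          if (is.data.frame(st) && ncol(st)) {
            net$groups[[gid]]$style <- as.list(st[i, , drop = FALSE])
          }
        }
      }
    }
  }
  net
}

#' Attach layout coordinates as node attributes
#'
#' @param net a `modnet_network`.
#' @param state a `modnet_layout` state (see [run_layout()]).
#' @return the network with numeric `x`, `y` node attributes.
#' @export
attach_coords <- function(net, state) {
  co <- state$coords
  net <- set_node_attr(net, "x", stats::setNames(co[, 1], rownames(co)))
  set_node_attr(net, "y", stats::setNames(co[, 2], rownames(co)))
}
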