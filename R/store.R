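#' Background interaction stores
#'
#' A store directory holds named, persisted background networks (the
#' headless analogue of an interaction-source manager): each source is one
#' GraphML file plus a JSON manifest, so a source imported once is available
#' by name on every later run without the original file.
#'
#' @param path interaction file to import.
#' @param name unique source name within the store.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param score_column for `tsv`: score column name or index (see
#'   [read_interaction_tsv()]); recorded in the manifest.
#' @param store_dir store directory (created if missing).
#' @return `import_source` / `open_source`: a `modnet_store` object with
#'   elements `source_name`, `network`, `score_column`, `storage_path`,
#'   `created`.
#' @export
import_source <- function(path, name, format = c("tsv", "sif", "graphml"),
                          score_column = NULL,
                          store_dir = getOption("modnet.store_dir", "modnet_store")) {
  format <- match.arg(format)
  if (!dir.exists(store_dir)) dir.create(store_dir, recursive = TRUE)
  manifest <- file.path(store_dir, paste0(name, ".manifest.json"))
  if (file.exists(manifest))
    stop(sprintf("source '%s' already exists in %s", name, store_dir),
         call. = FALSE)
  net <- switch(format,
    tsv = read_interaction_tsv(path, score_column = score_column),
    sif = read_sif(path),
    graphml = read_graphml(path))
  net$name <- name
  storage <- file.path(store_dir, paste0(name, ".graphml"))
  write_graphml(net, storage)
  has_score <- "score" %in% names(net$edges) && any(!is.na(net$edges$score))
  meta <- list(source_name = name, format = format,
               score_column = if (has_score) "score" else NULL,
               n_nodes = n_nodes(net), n_edges = n_edges(net),
               storage_path = basename(storage),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE, pretty = TRUE)
  structure(list(source_name = name, network = net,
                 score_column = meta$score_column,
                 storage_path = storage, created = meta$created),
            class = "modnet_store")
}

#' @rdname import_source
#' @export
open_source <- function(name,
                        store_dir = getOption("modnet.store_dir", "modnet_store")) {
  manifest <- file.path(store_dir, paste0(name, ".manifest.json"))
  if (!file.exists(manifest))
    stop(sprintf("no source '%s' in %s", name, store_dir), call. = FALSE)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  storage <- file.path(store_dir, meta$storage_path)
  net <- read_graphml(storage)
  net$name <- meta$source_name
  structure(list(source_name = meta$source_name, network = net,
                 score_column = meta$score_column,
                 storage_path = storage, created = meta$created),
            class = "modnet_store")
}

#' @rdname import_source
#' @export
list_sources <- function(store_dir = getOption("modnet.store_dir", "modnet_store")) {
  if (!dir.exists(store_dir)) return(character())
  sub("\\.manifest\\.json$", "",
      basename(list.files(store_dir, pattern = "\\.manifest\\.json$")))
}

#' @rdname import_source
#' @export
delete_source <- function(name,
                          store_dir = getOption("modnet.store_dir", "modnet_store")) {
  manifest <- file.path(store_dir, paste0(name, ".manifest.json"))
  if (!file.exists(manifest))
    stop(sprintf("no source '%s' in %s", name, store_dir), call. = FALSE)
  storage <- file.path(store_dir, paste0(name, ".graphml"))
  unlink(c(manifest, storage, hyperedge_sidecar_path(storage)))
  invisible(TRUE)
}

#' @export
print.modnet_store <- function(x, ...) {
  cat(sprintf("modnet source '%s' (%d nodes, %d edges)%s\n  stored at %s\n",
              x$source_name, n_nodes(x$network), n_edges(x$network),
              if (!is.null(x$score_column)) " with scores" else "",
              x$storage_path))
  invisible(x)
}

#' Score-thresholded background subnetwork
#'
#' Keeps edges whose confidence score is strictly greater than `min_score`
#' (e.g. the STRING-style `score > 900` convention for high-confidence
#' interactions) and drops nodes left isolated.
#'
#' @param store a `modnet_store` (or a `modnet_network` with a score edge
#'   column).
#' @param min_score threshold; edges with `score > min_score` survive.
#' @return a `modnet_network`.
#' @export
subnetwork_by_score <- function(store, min_score) {
  net <- if (inherits(store, "modnet_store")) store$network else store
  stopifnot_network(net)
  if (!"score" %in% names(net$edges) || all(is.na(net$edges$score)))
    stop("no score column declared for this source", call. = FALSE)
  net$edges <- net$edges[!is.na(net$edges$score) & net$edges$score > min_score, ,
                         drop = FALSE]
  rownames(net$edges) <- NULL
  keep <- unique(c(net$edges$u, net$edges$v))
  induced_subnet(net, keep)
}

#' Neighborhood expansion
#'
#' Induced subgraph on the query ids plus every node within graph distance
#' `depth` of any of them (unweighted hops). Query ids absent from the
#' background are ignored with a warning.
#'
#' @param store a `modnet_store` or `modnet_network`.
#' @param ids query node ids.
#' @param depth integer >= 1.
#' @return a `modnet_network`.
#' @export
expand <- function(store, ids, depth = 1L) {
  net <- if (inherits(store, "modnet_store")) store$network else store
  stopifnot_network(net)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  unknown <- setdiff(ids, node_ids(net))
  if (length(unknown))
    warning(sprintf("expand: ignoring %d id(s) absent from the background",
                    length(unknown)))
  ids <- intersect(ids, node_ids(net))
  if (!length(ids)) return(network(name = net$name))
  g <- as_igraph(net)
  d <- igraph::distances(g, v = ids, weights = NA)
  keep <- colnames(d)[apply(d, 2, min) <= depth]
  suppressWarnings(induced_subnet(net, keep))
}
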