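#' Data-to-visual mapping
#'
#' A monotone mapping from a data attribute to a visual channel: numeric
#' ranges for `node_size` / `edge_width`, a 2- or 3-anchor color gradient
#' (linear RGB interpolation, hex sRGB output) for `node_color` /
#' `edge_color`. A 3-anchor (diverging) gradient requires a 3-value domain
#' giving the explicit midpoint, e.g. `c(-2, 0, 2)` with
#' `c("blue", "white", "red")`.
#'
#' @param source_attr data attribute to map.
#' @param target one of `"node_size"`, `"node_color"`, `"edge_width"`,
#'   `"edge_color"`.
#' @param domain numeric vector of length 2 (min, max) or 3 (min, mid,
#'   max, for diverging colors), strictly increasing; or `"auto"` for the
#'   observed \[min, max\].
#' @param range numeric `c(min, max)` for size/width targets; character
#'   vector of 2-3 colors for color targets.
#' @param out_of_domain `"clamp"` (map to the nearest endpoint) or
#'   `"hide"` (flag the element hidden).
#' @return an object of class `modnet_mapping`.
#' @export
visual_mapping <- function(source_attr,
                           target = c("node_size", "node_color",
                                      "edge_width", "edge_color"),
                           domain = "auto", range = NULL,
                           out_of_domain = c("clamp", "hide")) {
  target <- match.arg(target)
  out_of_domain <- match.arg(out_of_domain)
  is_color <- target %in% c("node_color", "edge_color")
  if (is.null(range))
    range <- if (is_color) c("#0000FF", "#FF0000") else c(10, 30)
  if (is_color) {
    if (!is.character(range) || !length(range) %in% 2:3)
      stop("color targets need a 2-3 anchor color range", call. = FALSE)
  } else {
    if (!is.numeric(range) || length(range) != 2)
      stop("size/width targets need a numeric (min, max) range", call. = FALSE)
  }
  if (!identical(domain, "auto")) {
    if (!is.numeric(domain) || !length(domain) %in% 2:3 ||
        any(diff(domain) <= 0))
      stop("domain must be strictly increasing of length 2 or 3", call. = FALSE)
    if (is_color && length(range) == 3 && length(domain) != 3)
      stop("a 3-anchor gradient needs a 3-value domain (explicit midpoint)",
           call. = FALSE)
  }
  structure(list(source_attr = source_attr, target = target,
                 domain = domain, range = range,
                 out_of_domain = out_of_domain, is_color = is_color),
            class = "modnet_mapping")
}

neutral_style <- function(mapping) {
  if (mapping$is_color) "#BEBEBE" else mean(range(mapping$range))
}

resolve_domain <- function(mapping, values) {
  if (!identical(mapping$domain, "auto")) return(mapping$domain)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to map", call. = FALSE)
  d <- range(v)
  if (d[1] == d[2]) return(d)  # constant; handled by caller
  if (mapping$is_color && length(mapping$range) == 3) c(d[1], mean(d), d[2])
  else d
}

interp_colors <- function(anchors, t) {
  # linear RGB interpolation over equally spaced anchors, t in [0,1]
  ramp <- grDevices::colorRamp(anchors, space = "rgb")
  rgb_vals <- ramp(pmin(pmax(t, 0), 1))
  grDevices::rgb(rgb_vals[, 1], rgb_vals[, 2], rgb_vals[, 3],
                 maxColorValue = 255)
}

map_values <- function(mapping, values, domain) {
  n <- length(values)
  style <- if (mapping$is_color) character(n) else numeric(n)
  absent <- !is.finite(values)
  hidden <- logical(n)
  lo <- domain[1]; hi <- domain[length(domain)]
  constant <- lo == hi
  v <- values
  oob <- !absent & (v < lo | v > hi)
  if (mapping$out_of_domain == "clamp") {
    v <- pmin(pmax(v, lo), hi)
  } else {
    hidden[oob] <- TRUE
  }
  t <- if (constant) rep(0.5, n) else {
    if (length(domain) == 3) {
      mid <- domain[2]
      ifelse(v <= mid, 0.5 * (v - lo) / (mid - lo),
             0.5 + 0.5 * (v - mid) / (hi - mid))
    } else (v - lo) / (hi - lo)
  }
  t[absent] <- NA
  if (mapping$is_color) {
    style[!absent] <- interp_colors(mapping$range, t[!absent])
  } else {
    style[!absent] <- mapping$range[1] +
      t[!absent] * (mapping$range[2] - mapping$range[1])
  }
  style[absent] <- neutral_style(mapping)
  list(style = style, absent = absent, hidden = hidden, constant = constant)
}

#' Apply a visual mapping to a network
#'
#' Linearly interpolates the mapped attribute from its domain to the
#' visual range. Missing or non-finite values receive the neutral style
#' (grey / range midpoint) and are flagged `absent`; values outside the
#' domain are clamped or flagged `hidden` per the mapping. A constant
#' attribute under an `"auto"` domain maps everything to the range
#' midpoint with a warning.
#'
#' @param net a `modnet_network`.
#' @param mapping a [visual_mapping()].
#' @return a data.frame styled attribute table: `id` (node id or
#'   `"u|v"` edge key), `value`, `style`, `absent`, `hidden`, with
#'   attribute `"domain"` recording the domain used.
#' @export
apply_mapping <- function(net, mapping) {
  stopifnot_network(net)
  on_nodes <- mapping$target %in% c("node_size", "node_color")
  if (on_nodes) {
    if (!mapping$source_attr %in% names(net$nodes))
      stop(sprintf("no node attribute '%s'", mapping$source_attr),
           call. = FALSE)
    ids <- net$nodes$id
    values <- as.numeric(net$nodes[[mapping$source_attr]])
  } else {
    if (!mapping$source_attr %in% names(net$edges))
      stop(sprintf("no edge attribute '%s'", mapping$source_attr),
           call. = FALSE)
    ids <- paste(net$edges$u, net$edges$v, sep = "|")
    values <- as.numeric(net$edges[[mapping$source_attr]])
  }
  domain <- resolve_domain(mapping, values)
  m <- map_values(mapping, values, domain)
  if (m$constant)
    warning("constant attribute under auto domain; mapping to range midpoint")
  out <- data.frame(id = ids, value = values, style = m$style,
                    absent = m$absent, hidden = m$hidden,
                    stringsAsFactors = FALSE)
  attr(out, "domain") <- domain
  attr(out, "mapping") <- mapping
  out
}

#' Condition series
#'
#' An ordered set of per-node values under multiple experimental
#' conditions (e.g. per-subtype mean expression or log2 fold change),
#' for serial or animated overlay on one network.
#'
#' @param values numeric matrix, nodes x conditions, with dimnames.
#' @return an object of class `modnet_series` with elements `conditions`
#'   and `values`.
#' @export
condition_series <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have node rownames and condition colnames", call. = FALSE)
  if (!ncol(values))
    stop("at least one condition is required", call. = FALSE)
  structure(list(conditions = colnames(values), values = values),
            class = "modnet_series")
}

#' Serial multi-condition overlay
#'
#' Produces one styled frame per condition on IDENTICAL coordinates, with
#' a single domain shared across all conditions (default) so styles are
#' comparable between frames: a node holding the series-wide maximum gets
#' the range-max style whichever condition it occurs in.
#'
#' @param net a `modnet_network`.
#' @param series a [condition_series()].
#' @param mapping a [visual_mapping()] with a node target.
#' @param coords a `modnet_layout` covering the network's nodes.
#' @param shared_domain share one domain across conditions (default
#'   `TRUE`); `FALSE` resolves the domain per condition.
#' @return list of class `modnet_overlay`: per condition, a list with
#'   `condition`, `styles` (as from [apply_mapping()]) and `coords` (the
#'   one shared coordinate matrix).
#' @export
overlay_series <- function(net, series, mapping, coords,
                           shared_domain = TRUE) {
  stopifnot_network(net)
  if (!mapping$target %in% c("node_size", "node_color"))
    stop("overlay mapping must target a node channel", call. = FALSE)
  if (!all(node_ids(net) %in% rownames(coords$coords)))
    stop("coords do not cover the network's nodes", call. = FALSE)
  ids <- node_ids(net)
  vals <- matrix(NA_real_, length(ids), length(series$conditions),
                 dimnames = list(ids, series$conditions))
  common <- intersect(ids, rownames(series$values))
  vals[common, ] <- series$values[common, , drop = FALSE]
  domain <- if (shared_domain) resolve_domain(mapping, as.numeric(vals))
            else NULL
  co <- coords$coords[ids, , drop = FALSE]
  frames <- lapply(series$conditions, function(cond) {
    v <- vals[, cond]
    dom <- if (is.null(domain)) resolve_domain(mapping, v) else domain
    m <- map_values(mapping, v, dom)
    if (all(m$absent))
      warning(sprintf("condition '%s': all values missing; neutral frame",
                      cond))
    styles <- data.frame(id = ids, value = v, style = m$style,
                         absent = m$absent, hidden = m$hidden,
                         stringsAsFactors = FALSE)
    attr(styles, "domain") <- dom
    list(condition = cond, styles = styles, coords = co)
  })
  names(frames) <- series$conditions
  structure(frames, class = "modnet_overlay")
}

#' Condition matrix export
#'
#' The heat-map view of a series: a genes x conditions table, rows ordered
#' by the given order (e.g. cluster order, so co-clustered genes form
#' contiguous blocks) else input order.
#'
#' @param series a [condition_series()].
#' @param node_order optional character vector of node ids.
#' @param path optional output TSV path; when given, the matrix is written
#'   with a header row of condition names and a leading `gene` column.
#' @return the ordered numeric matrix, invisibly when `path` is given.
#' @export
condition_matrix <- function(series, node_order = NULL, path = NULL) {
  m <- series$values
  if (!is.null(node_order)) {
    keep <- node_order[node_order %in% rownames(m)]
    m <- m[c(keep, setdiff(rownames(m), keep)), , drop = FALSE]
  }
  if (!is.null(path)) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(m))
  }
  m
}
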