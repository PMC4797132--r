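#' Load an ontology from an OBO file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2 file: term id, name,
#' namespace, `is_a` parents and obsolete flags. Only the `is_a` relation
#' is retained (part_of and other relationships are ignored, the smallest
#' defensible propagation closure). Obsolete terms are excluded from the
#' DAG. A cycle among `is_a` edges is a format error.
#'
#' @param path path to an OBO file.
#' @return an object of class `modnet_ontology`: list with `terms`
#'   (data.frame `id`, `name`, `namespace`) and `parents` (named list,
#'   term id -> character vector of parent ids).
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, parents = character(),
                  obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+): *(.*)$", ln))[[1]]
      if (length(kv) < 3) next
      key <- kv[2]; val <- kv[3]
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a") cur$parents <- c(cur$parents,
                                               sub(" *!.*$", "", val))
      else if (key == "is_obsolete" && grepl("^true", val)) cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no terms found in OBO file", call. = FALSE)
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  # cycle check by topological elimination
  remaining <- ids
  pc <- parents
  repeat {
    leaves <- remaining[vapply(pc[remaining], length, integer(1)) == 0]
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
    pc[remaining] <- lapply(pc[remaining], setdiff, leaves)
  }
  if (length(remaining))
    stop(sprintf("cyclic is_a relation involving: %s",
                 paste(utils::head(remaining, 5), collapse = ", ")),
         call. = FALSE)
  structure(list(
    terms = data.frame(id = ids,
                       name = vapply(terms, `[[`, character(1), "name"),
                       namespace = vapply(terms, `[[`, character(1), "namespace"),
                       row.names = NULL, stringsAsFactors = FALSE),
    parents = parents), class = "modnet_ontology")
}

#' @export
print.modnet_ontology <- function(x, ...) {
  cat(sprintf("ontology with %d terms (%s)\n", nrow(x$terms),
              paste(unique(stats::na.omit(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

#' All is_a ancestors of a term (excluding itself)
#' @param dag a `modnet_ontology`.
#' @param id term id.
#' @return character vector of ancestor ids.
#' @export
term_ancestors <- function(dag, id) {
  out <- character()
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                        out)
  }
  sort(out)
}

#' Load gene annotations and propagate over the ontology
#'
#' Accepts GAF 2.x (17-column tab-separated, `!` comment lines; gene =
#' column 3 DB Object Symbol, term = column 5, evidence = column 7, rows
#' with a NOT qualifier skipped) or a 2-column `gene<TAB>term` TSV.
#' Annotations to unknown or obsolete terms are skipped with a warning.
#' Each annotation is propagated to all is_a ancestors (the true-path
#' rule), and the annotation universe is every gene with at least one
#' propagated annotation.
#'
#' @param path annotation file.
#' @param dag a `modnet_ontology`.
#' @param format `"auto"` (default; GAF when a line has >= 15 columns),
#'   `"gaf"` or `"tsv"`.
#' @param evidence_filter optional character vector of GAF evidence codes
#'   to keep (e.g. `c("EXP","IDA")`).
#' @return an object of class `modnet_annotations`: list with `direct` and
#'   `propagated` (term -> gene-id character vectors) and `universe`.
#' @export
load_annotations <- function(path, dag, format = c("auto", "gaf", "tsv"),
                             evidence_filter = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (length(fields) && length(fields[[1]]) >= 15) "gaf" else "tsv"
  if (format == "gaf") {
    keep <- vapply(fields, function(f) {
      length(f) >= 7 && !grepl("NOT", f[4]) &&
        (is.null(evidence_filter) || f[7] %in% evidence_filter)
    }, logical(1))
    fields <- fields[keep]
    genes <- vapply(fields, `[[`, character(1), 3)
    termv <- vapply(fields, `[[`, character(1), 5)
  } else {
    bad <- which(lengths(fields) < 2)
    if (length(bad))
      stop(sprintf("annotation TSV parse error at line %d", bad[1]),
           call. = FALSE)
    genes <- vapply(fields, `[[`, character(1), 1)
    termv <- vapply(fields, `[[`, character(1), 2)
  }
  known <- termv %in% dag$terms$id
  if (any(!known))
    warning(sprintf("skipping %d annotation(s) to unknown or obsolete terms",
                    sum(!known)))
  genes <- genes[known]; termv <- termv[known]
  if (!length(genes)) {
    return(structure(list(direct = list(), propagated = list(),
                          universe = character()),
                     class = "modnet_annotations"))
  }
  direct <- lapply(split(genes, termv), function(x) sort(unique(x)))
  propagated <- direct
  for (t in names(direct)) {
    for (anc in term_ancestors(dag, t)) {
      propagated[[anc]] <- sort(union(propagated[[anc]], direct[[t]]))
    }
  }
  structure(list(direct = direct, propagated = propagated,
                 universe = sort(unique(genes))),
            class = "modnet_annotations")
}

#' @export
print.modnet_annotations <- function(x, ...) {
  cat(sprintf("annotations: %d terms (propagated), %d genes in universe\n",
              length(x$propagated), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For a query gene set against an annotation universe of size N, each
#' term with K annotated genes is tested for enrichment of the x query hits
#' among the n query genes with the upper-tail hypergeometric probability
#' \deqn{p = \sum_{i=x}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n},}
#' the same sampling-without-replacement kernel as the linker test.
#'
#' @param query character vector of gene ids. Genes outside the universe
#'   are dropped with a warning (and n reduced); an empty effective query
#'   is an error.
#' @param ann a `modnet_annotations`.
#' @param universe optional override of the universe gene set (default:
#'   all genes with >= 1 propagated annotation).
#' @param adjust `"bh"` (default), `"bonferroni"` or `"none"`.
#' @param min_term_size terms annotating fewer than this many universe
#'   genes are skipped (default 3).
#' @param dag optional `modnet_ontology` to attach term names.
#' @return a data.frame of class `modnet_enrichment` with columns
#'   `term_id`, `term_name`, `x`, `n`, `K`, `N`, `p_raw`, `p_adjusted`,
#'   sorted by `p_raw` ascending.
#' @export
overrepresentation <- function(query, ann, universe = NULL,
                               adjust = c("bh", "bonferroni", "none"),
                               min_term_size = 3L, dag = NULL) {
  adjust <- match.arg(adjust)
  uni <- if (is.null(universe)) ann$universe else unique(as.character(universe))
  query <- unique(as.character(query))
  dropped <- setdiff(query, uni)
  if (length(dropped))
    warning(sprintf("dropping %d query gene(s) absent from the universe",
                    length(dropped)))
  query <- intersect(query, uni)
  if (!length(query))
    stop("query has no genes in the universe", call. = FALSE)
  N <- length(uni); n <- length(query)
  rows <- list()
  for (t in sort(names(ann$propagated))) {
    tg <- intersect(ann$propagated[[t]], uni)
    K <- length(tg)
    if (K < min_term_size) next
    x <- length(intersect(query, tg))
    p <- if (x == 0) 1 else
      stats::phyper(x - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
    rows[[t]] <- data.frame(term_id = t, x = x, n = n, K = K, N = N,
                            p_raw = p, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), x = integer(), n = integer(),
               K = integer(), N = integer(), p_raw = numeric())
  res$p_adjusted <- stats::p.adjust(res$p_raw, method =
    switch(adjust, bh = "BH", bonferroni = "bonferroni", none = "none"))
  res$term_name <- if (!is.null(dag))
    dag$terms$name[match(res$term_id, dag$terms$id)]
  else rep(NA_character_, nrow(res))
  res <- res[order(res$p_raw, res$term_id),
             c("term_id", "term_name", "x", "n", "K", "N",
               "p_raw", "p_adjusted")]
  rownames(res) <- NULL
  class(res) <- c("modnet_enrichment", "data.frame")
  attr(res, "adjust") <- adjust
  res
}

#' @export
print.modnet_enrichment <- function(x, ...) {
  cat(sprintf("over-representation: %d terms tested (adjust = %s)\n",
              nrow(x), attr(x, "adjust")))
  print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Per-group enrichment
#'
#' Runs [overrepresentation()] for every group of a network and stacks the
#' results with a leading `group` column.
#'
#' @param net a `modnet_network` with groups.
#' @param ann a `modnet_annotations`.
#' @param ... passed to [overrepresentation()].
#' @return a data.frame; groups whose members have no annotated gene are
#'   skipped with a warning.
#' @export
enrich_groups <- function(net, ann, ...) {
  stopifnot_network(net)
  out <- list()
  for (gr in net$groups) {
    res <- tryCatch(overrepresentation(gr$members, ann, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("group '%s' has no genes in the annotation universe; skipped",
                      gr$id))
      next
    }
    if (nrow(res)) out[[gr$id]] <- cbind(group = gr$id,
                                         as.data.frame(res))
  }
  if (!length(out))
    return(data.frame(group = character(), term_id = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
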