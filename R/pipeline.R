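#' Read pipeline input tables
#'
#' `read_alteration_table` expects a TSV with header
#' `gene<TAB>mut_freq<TAB>cna_freq`; `read_expression_tsv` a TSV whose
#' first column is the gene id and remaining columns are samples (or
#' conditions).
#'
#' @param path file path.
#' @return a data.frame / numeric matrix with gene rownames.
#' @export
read_alteration_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "mut_freq", "cna_freq")
  if (!all(need %in% names(tab)))
    stop(sprintf("alteration table needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  tab
}

#' @rdname read_alteration_table
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

pipeline_defaults <- function() {
  list(
    source_name = "background",
    score_column = NULL,
    extraction = list(min_score = 900, max_distance = 2, linker_alpha = 0.01,
                      adjust = "none", mut_freq_min = 0.02,
                      cna_freq_min = 0.03),
    clustering = list(algorithm = "mcl", inflation = 2.0,
                      vertex_weight_percentage = 0.2, top_k = NULL),
    layout = list(seed = 42, max_iter = 300),
    enrichment = list(adjust = "bh", min_term_size = 3),
    mapping = list(target = "node_color",
                   range = c("#0000FF", "#FFFFFF", "#FF0000"))
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop(sprintf("unknown config key '%s.%s'", k, bad[1]), call. = FALSE)
      defaults[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

validate_config <- function(config) {
  allowed <- c("interactions", "score_column", "alterations", "expression",
               "conditions", "obo", "annotations", "out_dir", "source_name",
               "extraction", "clustering", "layout", "enrichment", "mapping")
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (k in c("interactions", "alterations", "expression", "out_dir"))
    if (is.null(config[[k]]))
      stop(sprintf("config key '%s' is required", k), call. = FALSE)
  for (k in c("interactions", "alterations", "expression", "conditions",
              "obo", "annotations"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop(sprintf("input file for '%s' not found: %s", k, config[[k]]),
           call. = FALSE)
  merge_config(pipeline_defaults(), config)
}

#' Run the full discovery pipeline
#'
#' Executes the case-study stages in order -- import the background source,
#' score-filter it, select seeds from the alteration table, extract the
#' all-shortest-paths subnetwork, filter linkers by significance, weight
#' edges by expression correlation, cluster, promote clusters to groups,
#' optionally run GO over-representation per group, lay the network out,
#' and optionally export per-condition overlay frames. Every intermediate
#' is written to the output directory so any stage can be inspected or
#' rerun in isolation, and a machine-readable run log (stage, parameters,
#' output checksums) is emitted. Rerunning the same config reproduces
#' byte-identical stage outputs.
#'
#' @param config a named list or path to a YAML file with keys
#'   `interactions`, `alterations`, `expression`, `out_dir` (required),
#'   `conditions`, `obo`, `annotations`, `score_column`, `source_name`
#'   (optional), and parameter blocks `extraction`, `clustering`,
#'   `layout`, `enrichment`, `mapping`. Unknown keys are rejected.
#' @return invisibly, a list with `artifacts` (named file paths),
#'   `results` (in-memory stage results) and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list()
  artifacts <- character()
  note <- function(stage, params, paths) {
    paths <- paths[file.exists(paths)]
    sums <- tools::md5sum(paths)
    log[[length(log) + 1]] <<- list(
      stage = stage, parameters = params,
      outputs = as.list(stats::setNames(unname(sums), basename(paths))))
    artifacts[basename(paths)] <<- paths
  }
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # stage 1: import + score-filter the background
  store_dir <- file.path(out_dir, "store")
  background <- run_stage("import", {
    if (config$source_name %in% list_sources(store_dir))
      delete_source(config$source_name, store_dir)
    st <- import_source(config$interactions, config$source_name,
                        format = "tsv", score_column = config$score_column,
                        store_dir = store_dir)
    subnetwork_by_score(st, config$extraction$min_score)
  })
  p1 <- file.path(out_dir, "stage1_background.graphml")
  write_graphml(background, p1)
  note("background", config$extraction["min_score"], p1)

  # stage 2: seed selection
  params <- extraction_params(
    max_distance = config$extraction$max_distance,
    linker_alpha = config$extraction$linker_alpha,
    min_score = config$extraction$min_score,
    mut_freq_min = config$extraction$mut_freq_min,
    cna_freq_min = config$extraction$cna_freq_min,
    adjust = config$extraction$adjust)
  alt <- run_stage("seeds", read_alteration_table(config$alterations))
  seeds <- run_stage("seeds", select_seeds(alt, params))
  p2 <- file.path(out_dir, "stage2_seeds.txt")
  writeLines(seeds, p2)
  note("seeds", params[c("mut_freq_min", "cna_freq_min")], p2)

  # stage 3: shortest-path extraction
  extracted <- run_stage("extract", suppressWarnings(
    extract_paths(background, seeds, params$max_distance)))
  p3 <- file.path(out_dir, "stage3_extracted.graphml")
  write_graphml(extracted, p3)
  note("extract", params["max_distance"], p3)

  # stage 4: linker significance filter
  filtered <- run_stage("filter_linkers",
    filter_linkers(extracted, background, params$linker_alpha,
                   params$adjust))
  p4 <- file.path(out_dir, "stage4_filtered.graphml")
  p4b <- file.path(out_dir, "stage4_linker_records.tsv")
  write_graphml(filtered, p4)
  wt(attr(filtered, "linker_records"), p4b)
  note("filter_linkers", params[c("linker_alpha", "adjust")], c(p4, p4b))

  # stage 5: correlation edge weights
  expr <- run_stage("weight", read_expression_tsv(config$expression))
  weighted <- run_stage("weight", suppressWarnings(
    weight_by_correlation(filtered, expr)))
  p5 <- file.path(out_dir, "stage5_weighted.graphml")
  write_graphml(weighted, p5)
  note("weight", list(), p5)

  # stage 6: clustering
  cl_cfg <- config$clustering
  modules <- run_stage("cluster",
    if (cl_cfg$algorithm == "mcl")
      mcl(weighted, inflation = cl_cfg$inflation)
    else mcode(weighted,
               vertex_weight_percentage = cl_cfg$vertex_weight_percentage))
  p6 <- file.path(out_dir, "stage6_clusters.tsv")
  cl_tab <- do.call(rbind, c(lapply(seq_along(modules$clusters), function(i)
    data.frame(cluster_id = sprintf("cluster_%d", i),
               node_id = modules$clusters[[i]],
               score = modules$scores[i])),
    list(if (length(modules$singletons))
      data.frame(cluster_id = "singleton", node_id = modules$singletons,
                 score = 0))))
  wt(cl_tab, p6)
  note("cluster", cl_cfg[names(cl_cfg) != "top_k"], p6)

  # stage 7: cluster -> group promotion
  grouped <- run_stage("groups",
    clusters_to_groups(weighted, modules, top_k = cl_cfg$top_k))
  p7 <- file.path(out_dir, "stage7_groups.graphml")
  write_graphml(grouped, p7)
  note("groups", list(top_k = cl_cfg$top_k), c(p7, hyperedge_sidecar_path(p7)))

  # stage 8: per-group GO over-representation (optional)
  enrichment <- NULL
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    enrichment <- run_stage("enrich", {
      dag <- load_ontology(config$obo)
      ann <- load_annotations(config$annotations, dag)
      suppressWarnings(enrich_groups(grouped, ann, dag = dag,
                                     adjust = config$enrichment$adjust,
                                     min_term_size = config$enrichment$min_term_size))
    })
    p8 <- file.path(out_dir, "stage8_enrichment.tsv")
    wt(enrichment, p8)
    note("enrich", config$enrichment, p8)
  }

  # stage 9: layout
  lay_par <- do.call(layout_params, config$layout)
  state <- run_stage("layout", run_layout(grouped, lay_par))
  laid <- attach_coords(grouped, state)
  p9 <- file.path(out_dir, "stage9_layout.graphml")
  write_graphml(laid, p9)
  note("layout", config$layout, c(p9, hyperedge_sidecar_path(p9)))

  # stage 10: per-condition overlay (optional)
  overlay <- NULL
  if (!is.null(config$conditions)) {
    overlay <- run_stage("overlay", {
      series_m <- read_expression_tsv(config$conditions)
      series <- condition_series(series_m)
      mapping <- visual_mapping("__series__", config$mapping$target,
                                range = config$mapping$range)
      overlay_series(laid, series, mapping, state)
    })
    p10 <- character()
    for (fr in overlay) {
      fp <- file.path(out_dir, sprintf("frame_%s.tsv", fr$condition))
      wt(cbind(fr$styles, x = fr$coords[fr$styles$id, 1],
               y = fr$coords[fr$styles$id, 2]), fp)
      p10 <- c(p10, fp)
    }
    note("overlay", config$mapping, p10)
  }

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(artifacts = artifacts,
                 results = list(background = background, seeds = seeds,
                                extracted = extracted, filtered = filtered,
                                weighted = weighted, modules = modules,
                                grouped = grouped, enrichment = enrichment,
                                layout = state, overlay = overlay),
                 log = log))
}
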