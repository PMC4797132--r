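#' Planted-partition interaction network
#'
#' Generates an undirected network with known module structure: within each
#' planted module an edge appears with probability `p_in`, across modules
#' with probability `p_out`, and every edge gets a confidence score drawn
#' uniformly from `score_range` (emulating a confidence-scored
#' interaction source). Fully deterministic per seed.
#'
#' @param module_sizes integer vector of module sizes (each >= 2).
#' @param p_in,p_out within/between module edge probabilities, with
#'   `p_in > p_out` for recoverable fixtures.
#' @param score_range `c(low, high)` uniform score bounds.
#' @param seed integer seed.
#' @return list with `network` (a `modnet_network`) and `labels` (named
#'   integer vector, node id -> planted module).
#' @export
planted_network <- function(module_sizes = rep(20L, 5L), p_in = 0.3,
                            p_out = 0.02, score_range = c(850, 1000),
                            seed = 1L) {
  stopifnot(all(module_sizes >= 2), p_in >= 0, p_in <= 1,
            p_out >= 0, p_out <= 1, length(score_range) == 2)
  n <- sum(module_sizes)
  ids <- sprintf("g%03d", seq_len(n))
  labels <- stats::setNames(rep(seq_along(module_sizes), module_sizes), ids)
  pairs <- utils::combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  edges <- with_seed(seed, {
    hit <- stats::runif(ncol(pairs)) < p
    data.frame(u = ids[pairs[1, hit]], v = ids[pairs[2, hit]],
               score = stats::runif(sum(hit), score_range[1], score_range[2]),
               stringsAsFactors = FALSE)
  })
  net <- network(ids, name = "planted")
  if (nrow(edges)) net <- add_edges(net, edges)
  list(network = net, labels = labels)
}

#' Simulate matched omics for a planted network
#'
#' Emulates the statistical structure of a tumor-cohort input set on top of
#' planted modules:
#'
#' * **expression** -- a one-factor-per-module model: gene g in module m has
#'   expression `sqrt(rho) * f_m(s) + sqrt(1 - rho) * e_gs` (all latent
#'   terms standard normal, scaled by `noise_sd`), so any two genes of one
#'   module have population correlation `rho`; per-condition mean shifts
#'   are then added to the module's genes in the samples assigned to that
#'   condition (round-robin assignment);
#' * **alterations** -- in each altered module, a fraction
#'   `altered_fraction` of genes (drawn at random) receives mutation / CNA
#'   patient frequencies uniform in `mut_freq_range` / `cna_freq_range`;
#'   all other genes draw frequencies below the default selection
#'   thresholds (mut in \[0, 0.02\], CNA in \[0, 0.03\]), so they never
#'   pass the strict-threshold seed selection;
#' * **condition series** -- per-gene mean expression per condition,
#'   the overlay input.
#'
#' @param net the planted `modnet_network`.
#' @param labels named module labels as from [planted_network()].
#' @param n_samples number of samples (default 60).
#' @param rho target within-module correlation in \[0, 1) (default 0.6).
#' @param noise_sd overall expression scale (default 1).
#' @param altered_fraction fraction of each altered module's genes given
#'   high alteration frequencies (default 0.5).
#' @param altered_modules integer module labels to alter (default: all).
#' @param mut_freq_range,cna_freq_range uniform ranges for altered genes.
#' @param condition_shifts numeric matrix modules x conditions of mean
#'   shifts, or `NULL` for a single unshifted condition `"all"`. Default:
#'   three conditions with shift `+1` rotating over modules.
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix), `alterations`
#'   (data.frame `gene`, `mut_freq`, `cna_freq`), `series` (a
#'   [condition_series()]), `sample_conditions` (named character), and
#'   `altered_genes`.
#' @export
simulate_omics <- function(net, labels, n_samples = 60L, rho = 0.6,
                           noise_sd = 1, altered_fraction = 0.5,
                           altered_modules = NULL,
                           mut_freq_range = c(0.03, 0.20),
                           cna_freq_range = c(0.04, 0.30),
                           condition_shifts = "default", seed = 1L) {
  stopifnot(rho >= 0, rho < 1, noise_sd > 0, n_samples >= 3)
  ids <- node_ids(net)
  if (!all(ids %in% names(labels)))
    stop("labels must cover all network nodes", call. = FALSE)
  labels <- labels[ids]
  modules <- sort(unique(labels))
  if (is.null(altered_modules)) altered_modules <- modules
  if (identical(condition_shifts, "default")) {
    condition_shifts <- matrix(0, length(modules), 3,
                               dimnames = list(modules,
                                               c("cond1", "cond2", "cond3")))
    for (i in seq_along(modules))
      condition_shifts[i, (i - 1) %% 3 + 1] <- 1
  }
  with_seed(seed, {
    factors <- matrix(stats::rnorm(length(modules) * n_samples),
                      length(modules), n_samples,
                      dimnames = list(modules, NULL))
    noise <- matrix(stats::rnorm(length(ids) * n_samples),
                    length(ids), n_samples)
    expr <- noise_sd * (sqrt(rho) * factors[as.character(labels), ,
                                            drop = FALSE] +
                        sqrt(1 - rho) * noise)
    dimnames(expr) <- list(ids, sprintf("s%03d", seq_len(n_samples)))
    if (is.null(condition_shifts)) {
      conds <- "all"
      sample_cond <- stats::setNames(rep("all", n_samples), colnames(expr))
    } else {
      conds <- colnames(condition_shifts)
      sample_cond <- stats::setNames(
        conds[(seq_len(n_samples) - 1) %% length(conds) + 1], colnames(expr))
      for (ci in seq_along(conds)) {
        sel <- which(sample_cond == conds[ci])
        shift <- condition_shifts[as.character(labels), ci]
        expr[, sel] <- expr[, sel] + shift
      }
    }
    altered <- character()
    for (m in altered_modules) {
      members <- ids[labels == m]
      n_alt <- ceiling(altered_fraction * length(members))
      altered <- c(altered, sort(sample(members, n_alt)))
    }
    mut <- stats::runif(length(ids), 0, 0.02)
    cna <- stats::runif(length(ids), 0, 0.03)
    is_alt <- ids %in% altered
    mut[is_alt] <- stats::runif(sum(is_alt), mut_freq_range[1],
                                mut_freq_range[2])
    cna[is_alt] <- stats::runif(sum(is_alt), cna_freq_range[1],
                                cna_freq_range[2])
    series_vals <- sapply(conds, function(cd)
      rowMeans(expr[, sample_cond == cd, drop = FALSE]))
    if (is.null(dim(series_vals)))
      series_vals <- matrix(series_vals, ncol = 1,
                            dimnames = list(ids, conds))
    list(expression = expr,
         alterations = data.frame(gene = ids, mut_freq = mut,
                                  cna_freq = cna, stringsAsFactors = FALSE),
         series = condition_series(series_vals),
         sample_conditions = sample_cond,
         altered_genes = altered)
  })
}

#' The packaged cancer-cohort-like fixture
#'
#' One call producing every input of the discovery pipeline under the
#' package's reference study conditions: a 5-module x 20-node planted
#' network (`p_in` 0.3, `p_out` 0.02) with confidence scores uniform on
#' (850, 1000), and matched omics (60 samples, within-module correlation
#' 0.6, half of each module's genes recurrently altered, three shifted
#' conditions).
#'
#' @param seed integer seed driving both generators.
#' @return list with `network`, `labels`, `expression`, `alterations`,
#'   `series`, `sample_conditions`, `altered_genes`.
#' @export
gbm_like_fixture <- function(seed = 1L) {
  pl <- planted_network(seed = seed)
  om <- simulate_omics(pl$network, pl$labels, seed = seed + 1000L)
  c(pl, om)
}

#' Write a fixture to pipeline input files
#'
#' Emits `interactions.tsv` (source, target, score), `alterations.tsv`
#' (gene, mut_freq, cna_freq), `expression.tsv` (genes x samples),
#' `conditions.tsv` (per-gene per-condition means), `sample_conditions.tsv`
#' and `labels.tsv` into `dir`.
#'
#' @param dir output directory (created if missing).
#' @param seed fixture seed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  fx <- gbm_like_fixture(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(interactions = file.path(dir, "interactions.tsv"),
         alterations = file.path(dir, "alterations.tsv"),
         expression = file.path(dir, "expression.tsv"),
         conditions = file.path(dir, "conditions.tsv"),
         sample_conditions = file.path(dir, "sample_conditions.tsv"),
         labels = file.path(dir, "labels.tsv"))
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- fx$network$edges
  wt(data.frame(source = ed$u, target = ed$v, score = ed$score),
     p["interactions"])
  wt(fx$alterations, p["alterations"])
  wt(data.frame(gene = rownames(fx$expression), fx$expression,
                check.names = FALSE), p["expression"])
  condition_matrix(fx$series, path = p["conditions"])
  wt(data.frame(sample = names(fx$sample_conditions),
                condition = fx$sample_conditions), p["sample_conditions"])
  wt(data.frame(gene = names(fx$labels), module = fx$labels), p["labels"])
  invisible(p)
}
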