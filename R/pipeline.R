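.RUN_DEFAULTS <- list(
  # simulate
  p = 30L, K = 3L, n_per_condition = 120L,
  shared_density = 0.10, specific_density = 0.05, magnitude = 0.3,
  batch_offsets = c(0, 0.8), libsize_range = c(5e5, 2e6), dispersion = 0.1,
  # preprocess
  cpm_threshold = 10, sample_fraction = 0.30, require_go_bp = FALSE,
  log_prior = 0.5,
  # infer
  grid = c(0.01, 0.03, 0.05), adaptive = TRUE, alpha = 0.05,
  admm_max_iter = 100L, admm_tol = 0.001, admm_rho = 1.0,
  # networks
  truncation = 0.05,
  # compare (synthetic species panel)
  panel_hogs = 60L, panel_pairs = 30L, conserved_fraction = 0.2,
  # enrich
  min_size = 10L, max_size = 500L, p_cut = 0.05, q_cut = 0.05,
  n_go_terms = 15L,
  # global
  seed = 42L, verbose = FALSE
)

#' Pipeline run configuration
#'
#' A flat key-value configuration covering every stage of [run_all()], with
#' the per-module defaults.  Unknown keys are rejected; the configuration
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param out_dir output directory for all produced files.
#' @param ... overrides of the defaults (see `stressnet:::.RUN_DEFAULTS`):
#'   simulation size (`p`, `K`, `n_per_condition`, densities, `magnitude`,
#'   `batch_offsets`, `libsize_range`, `dispersion`), preprocessing
#'   (`cpm_threshold`, `sample_fraction`, `require_go_bp`, `log_prior`),
#'   inference (`grid`, `adaptive`, `alpha`, `admm_*`), `truncation`,
#'   species panel (`panel_hogs`, `panel_pairs`, `conserved_fraction`),
#'   enrichment (`min_size`, `max_size`, `p_cut`, `q_cut`, `n_go_terms`),
#'   and the global `seed`.
#' @return a `RunConfig` list.
#' @export
run_config <- function(out_dir, ...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(.RUN_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- .RUN_DEFAULTS
  cfg[names(overrides)] <- overrides
  cfg$out_dir <- out_dir
  structure(cfg, class = "RunConfig")
}

#' @rdname run_config
#' @param cfg a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out_dir <- raw$out_dir
  raw$out_dir <- NULL
  do.call(run_config, c(list(out_dir = out_dir), raw))
}

# Per-stage seed derived from the global seed and the stage name, so each
# stage is individually reproducible.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 131L + as.integer(h %% 1000L)) %% 2147483647L
}

.log_stage <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run the full synthetic-to-comparison pipeline
#'
#' Chains simulate -> preprocess -> infer -> networks -> compare -> enrich
#' on synthetic data with known ground truth, writing TSV/JSON outputs and
#' a JSON manifest (file list with md5 checksums and the full parameter
#' set).  Reruns with an identical configuration reproduce byte-identical
#' TSV outputs.  A stage failure aborts with the failing stage named and
#' leaves a `<stage>.partial` marker in the output directory.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the manifest list.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "stressnet",
                   version = as.character(utils::packageVersion("stressnet")),
                   parameters = unclass(cfg), stages = list())
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  run_stage <- function(stage, fun) {
    marker <- file.path(cfg$out_dir, paste0(stage, ".partial"))
    file.create(marker)
    files <- tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    unlink(marker)
    manifest$stages[[stage]] <<- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files)))
    files
  }
  path <- function(...) file.path(cfg$out_dir, ...)
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    .log_stage(cfg, "simulate: p=", cfg$p, " K=", cfg$K)
    truth <- make_precision_set(cfg$p, cfg$K, cfg$shared_density,
                                cfg$specific_density, cfg$magnitude,
                                seed = .stage_seed(cfg$seed, "simulate"))
    sim <- simulate_expression(truth, rep(cfg$n_per_condition, cfg$K),
                               batch_offsets = cfg$batch_offsets,
                               libsize_range = cfg$libsize_range,
                               dispersion = cfg$dispersion,
                               seed = .stage_seed(cfg$seed, "simulate") + 1L)
    state$truth <- truth
    state$sim <- sim
    write_counts_tsv(sim$counts, path("counts.tsv"))
    write_metadata_tsv(sim$samples, path("metadata.tsv"))
    write_truth_json(truth, path("truth.json"))
    path(c("counts.tsv", "metadata.tsv", "truth.json"))
  })

  run_stage("preprocess", function() {
    counts <- read_counts_tsv(path("counts.tsv"))
    samples <- read_metadata_tsv(path("metadata.tsv"))
    fcfg <- gene_filter_config(cfg$cpm_threshold, cfg$sample_fraction,
                               require_go_bp = cfg$require_go_bp,
                               log_prior = cfg$log_prior)
    std <- preprocess_counts(counts, samples, fcfg)
    state$std <- std
    state$samples <- samples
    df <- data.frame(gene = rownames(std$values), std$values,
                     check.names = FALSE)
    df[-1] <- lapply(df[-1], function(x) sprintf("%.6f", x))
    write.table(df, path("standardized.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    path("standardized.tsv")
  })

  run_stage("infer", function() {
    covs <- empirical_covariance(state$std, state$samples)
    chain <- order_conditions(state$std, state$samples)
    weights <- if (isTRUE(cfg$adaptive))
      screening_weights(covs, chain, alpha = cfg$alpha) else NULL
    pcfg <- penalty_config(grid = cfg$grid, admm_max_iter = cfg$admm_max_iter,
                           admm_tol = cfg$admm_tol, admm_rho = cfg$admm_rho,
                           truncation = cfg$truncation,
                           adaptive = cfg$adaptive)
    sel <- aic_grid_search(covs, grid = cfg$grid, weights = weights,
                           chain = chain, cfg = pcfg)
    state$pset <- sel$best
    write_precision_tsv(sel$best, path("precision.tsv"))
    tab <- sel$table
    tab$aic <- sprintf("%.4f", tab$aic)
    write.table(tab, path("aic_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    path(c("precision.tsv", "aic_table.tsv"))
  })

  run_stage("networks", function() {
    nets <- lapply(seq_along(state$pset$theta), function(k)
      precision_to_network(state$pset$theta[[k]], tau = cfg$truncation,
                           species = "focal",
                           condition = state$pset$chain[k]))
    names(nets) <- state$pset$chain
    uni <- union_conditions(nets)
    state$networks <- nets
    state$union <- uni
    files <- character(0)
    for (k in names(nets)) {
      f <- path(sprintf("network_%s.tsv", k))
      write_network_tsv(nets[[k]], f)
      files <- c(files, f)
    }
    write_network_tsv(uni, path("network_union.tsv"))
    write_network_graphml(uni, path("network_union.graphml"))
    stats <- lapply(c(nets, list(union = uni)), network_stats)
    jsonlite::write_json(stats, path("network_stats.json"), digits = NA,
                         auto_unbox = TRUE)
    c(files, path(c("network_union.tsv", "network_union.graphml",
                    "network_stats.json")))
  })

  run_stage("compare", function() {
    clade_map <- c(speciesT1 = "tracheophyte", speciesT2 = "tracheophyte",
                   speciesB1 = "bryophyte", speciesB2 = "bryophyte",
                   speciesZ1 = "zygnematophyte", speciesZ2 = "zygnematophyte",
                   focal = "outgroup")
    panel <- make_species_panel(clade_map[names(clade_map) != "focal"],
                                hogs = cfg$panel_hogs,
                                conserved_fraction = cfg$conserved_fraction,
                                n_pairs = cfg$panel_pairs,
                                seed = .stage_seed(cfg$seed, "compare"))
    hog_nets <- panel_hog_networks(panel)
    # focal genes enter HOG space round-robin as an outgroup species
    focal_map <- data.frame(
      gene = state$union$nodes,
      hog = panel$hog_ids[(seq_along(state$union$nodes) - 1L) %%
                            length(panel$hog_ids) + 1L],
      stringsAsFactors = FALSE)
    hog_nets$focal <- project_to_hogs(state$union, focal_map)
    merged <- union_hog_networks(hog_nets)
    labels <- classify_hog_edges(merged, clade_map)
    tallies <- clade_sharing_tallies(merged, clade_map)
    state$labels <- labels
    state$panel <- panel
    write_hog_network_tsv(merged, path("hog_network.tsv"))
    write.table(labels, path("conservation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(tallies$pairs, path("clade_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tallies$exclusive, path("clade_exclusive.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    path(c("hog_network.tsv", "conservation.tsv", "clade_pairs.tsv",
           "clade_exclusive.tsv"))
  })

  run_stage("enrich", function() {
    background <- state$union$nodes
    hub <- network_stats(state$union, top_n = 1)$hubs$gene[1]
    query <- neighborhood_of_set(state$union, hub)
    go_map <- make_go_map(background, n_terms = cfg$n_go_terms,
                          term_size_range = c(cfg$min_size,
                                              min(2 * cfg$min_size,
                                                  length(background))),
                          planted = if (length(query) >= cfg$min_size)
                            list(`SYN:HUBNBHD` = query) else NULL,
                          seed = .stage_seed(cfg$seed, "enrich"))
    res <- ora(query, background, go_map, min_size = cfg$min_size,
               max_size = cfg$max_size, p_cut = cfg$p_cut, q_cut = cfg$q_cut)
    res$p <- sprintf("%.6g", res$p)
    res$q <- sprintf("%.6g", res$q)
    write.table(res, path("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    path("enrichment.tsv")
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Per-species HOG networks of a synthetic panel
#'
#' Builds each panel species' condition networks from its planted edge
#' list, unions them, and projects the union into HOG space with the
#' species' HOG map.
#'
#' @param panel a `SpeciesPanelTruth` from [make_species_panel()].
#' @return named list of `HogNetwork` objects, one per species with edges.
#' @export
panel_hog_networks <- function(panel) {
  stopifnot(inherits(panel, "SpeciesPanelTruth"))
  out <- list()
  for (sp in panel$species) {
    e <- panel$edges[[sp]]
    if (nrow(e) == 0) next
    nets <- lapply(unique(e$condition), function(ck)
      network(sp, ck, unique(c(e$gene_a, e$gene_b)),
              e[e$condition == ck, c("gene_a", "gene_b", "weight")]))
    out[[sp]] <- project_to_hogs(union_conditions(nets), panel$hog_map[[sp]])
  }
  out
}
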