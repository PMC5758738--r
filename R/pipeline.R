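#' Pipeline configuration
#'
#' One declarative object drives the end-to-end run. Defaults follow the
#' analysis conventions this pipeline encodes: top 5 percent per
#' centrality metric, degree cutoff at mean + 2 SD, STRING medium
#' confidence (400), MCODE defaults, BH-adjusted q <= 0.05, kappa 0.4.
#'
#' @param gene_lists named character vector/list of gene-list file paths.
#' @param network path to the interaction network file.
#' @param network_format `"edge_list"`, `"string"`, or `"sif"`.
#' @param gmt optional path to a GMT annotation for enrichment.
#' @param universe optional path to a universe gene list for enrichment.
#' @param out_dir output directory for the report bundle.
#' @param string_score_threshold STRING combined-score threshold.
#' @param expand_depth optional BFS depth to expand the network around the
#'   gene-list intersection before analysis; `NULL` (default) analyzes the
#'   network as given.
#' @param top_fraction top fraction per centrality metric.
#' @param sd_multiplier degree-cutoff SD multiplier.
#' @param mcode an [mcode_params()] list.
#' @param n_clusters number of top-scoring complexes carried into the
#'   membership matrix and the enrichment query (default 3); MCODE
#'   typically reports many low-scoring clusters and an analysis focuses
#'   on the top few. All detected complexes are still written to
#'   `complexes.tsv`.
#' @param alpha significance level for enrichment.
#' @param kappa_threshold kappa linkage threshold for term grouping.
#' @param rng_seed seed recorded in the run log (the analysis itself is
#'   deterministic; the seed matters when inputs are generated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_lists, network, network_format = "edge_list",
                            gmt = NULL, universe = NULL, out_dir = "hubpanel_out",
                            string_score_threshold = 400, expand_depth = NULL,
                            top_fraction = 0.05, sd_multiplier = 2,
                            mcode = mcode_params(), n_clusters = 3L,
                            alpha = 0.05, kappa_threshold = 0.4,
                            rng_seed = 1L) {
  structure(list(gene_lists = as.list(gene_lists), network = network,
                 network_format = network_format, gmt = gmt,
                 universe = universe, out_dir = out_dir,
                 string_score_threshold = string_score_threshold,
                 expand_depth = expand_depth, top_fraction = top_fraction,
                 sd_multiplier = sd_multiplier, mcode = mcode,
                 n_clusters = as.integer(n_clusters), alpha = alpha,
                 kappa_threshold = kappa_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `mcode` key holds [mcode_params()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- do.call(mcode_params, y$mcode %||% list())
  y$mcode <- NULL
  do.call(pipeline_config, c(y, list(mcode = mc)))
}

config_as_yaml <- function(config) {
  plain <- unclass(config)
  plain$mcode <- unclass(plain$mcode)
  yaml::as.yaml(plain)
}

#' Run the full analysis pipeline
#'
#' Stages: read gene lists and intersect them; read the network (optionally
#' expanding around the intersection); decompose into components; on the
#' main component compute the degree distribution, power-law fit and the
#' four centralities; apply the hub/bottleneck selection rules; detect
#' MCODE complexes; and, when an annotation is configured, test the
#' crucial genes (hubs plus complex members) for term over-representation
#' with kappa grouping. Every stage's table is written to the output
#' directory together with the verbatim config, its hash, and a JSON
#' summary; outputs are deterministic (sorted, LF, no timestamps) so a
#' rerun with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results plus the
#'   `summary` list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out, ".partial")
  file.create(marker)
  on.exit(if (file.exists(marker)) file.remove(marker), add = TRUE)

  # --- gene lists
  sets <- lapply(seq_along(config$gene_lists), function(i) {
    nm <- names(config$gene_lists)[i]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- NULL
    read_gene_list(config$gene_lists[[i]], name = nm)
  })
  core <- intersect_gene_sets(sets)
  report <- intersection_report(sets)
  write_gene_list(core, file.path(out, "intersection.txt"))
  write_tsv(report, file.path(out, "intersection_report.tsv"))

  # --- network
  net <- switch(config$network_format,
    edge_list = read_edge_list(config$network),
    string = read_string_links(config$network,
                               score_threshold = config$string_score_threshold),
    sif = read_sif(config$network),
    stop_stage("network", "unknown format: ", config$network_format))
  if (!is.null(config$expand_depth)) {
    net <- expand_network(net, core, depth = config$expand_depth)
  }
  part <- component_partition(net)
  write_tsv(part$sizes, file.path(out, "components.tsv"))
  main <- main_component(net)

  # --- degree distribution & scale-free fit
  dist <- degree_distribution(main)
  write_tsv(as.data.frame(dist), file.path(out, "degree_distribution.tsv"))
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  if (!is.null(fit)) {
    jsonlite::write_json(unclass(fit), file.path(out, "power_law.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- centralities & selection
  tab <- centrality_table(main)
  write_tsv(as.data.frame(tab), file.path(out, "centrality.tsv"))
  sel <- select_crucial(tab, fraction = config$top_fraction,
                        sd_multiplier = config$sd_multiplier)

  # --- complexes
  cx <- mcode(main, config$mcode)
  write_tsv(as.data.frame(cx), file.path(out, "complexes.tsv"))
  top_cx <- head(cx, config$n_clusters)

  memb <- membership_report(sel, top_cx)
  write_tsv(memb, file.path(out, "membership.tsv"))
  sel_tab <- data.frame(
    quantity = c("degree_cutoff", "n_hubs", "n_hub_bottlenecks", "n_top_bc",
                 "n_top_cc", "n_top_stress", "n_complexes"),
    value = c(sel$degree_cutoff, length(sel$hubs), length(sel$hub_bottlenecks),
              length(sel$top_bc), length(sel$top_cc), length(sel$top_stress),
              length(cx)))
  write_tsv(sel_tab, file.path(out, "selection.tsv"))

  # --- enrichment of the crucial genes (hubs + complex members)
  enr <- NULL
  n_groups <- NA_integer_
  if (!is.null(config$gmt)) {
    universe <- if (!is.null(config$universe)) {
      readLines(config$universe, warn = FALSE)
    } else NULL
    ann <- read_gmt(config$gmt, universe = universe)
    query <- gene_set(c(sel$hubs, unlist(lapply(top_cx, `[[`, "members"))),
                      name = "crucial")
    enr <- ora(query, ann, alpha = config$alpha)
    enr <- kappa_grouping(enr, ann, kappa_threshold = config$kappa_threshold)
    n_groups <- attr(enr, "n_groups")
    write_tsv(as.data.frame(enr), file.path(out, "enrichment.tsv"))
  }

  # --- provenance: config, hash, summary (no timestamps: reruns must be
  # byte-identical)
  cfg_yaml <- config_as_yaml(config)
  write_lines_lf(strsplit(cfg_yaml, "\n")[[1]], file.path(out, "config.yaml"))
  summary <- list(
    package_version = as.character(packageVersion("hubpanel")),
    config_hash = config_fingerprint(cfg_yaml),
    rng_seed = config$rng_seed,
    n_lists = length(sets),
    list_sizes = lengths(sets),
    intersection_size = length(core),
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    n_components = length(part$components),
    component_sizes = part$sizes$n_nodes,
    main_nodes = igraph::vcount(main),
    main_edges = igraph::ecount(main),
    degree_cutoff = sel$degree_cutoff,
    hubs = as.character(sel$hubs),
    hub_bottlenecks = as.character(sel$hub_bottlenecks),
    n_top_stress_hits = sum(sel$hub_bottlenecks %in% sel$top_stress),
    n_top_cc_hits = sum(sel$hub_bottlenecks %in% sel$top_cc),
    n_complexes = length(cx),
    n_clusters_analyzed = length(top_cx),
    cluster_seeds = vapply(top_cx, `[[`, character(1), "seed"),
    power_law = if (!is.null(fit)) unclass(fit) else NULL,
    n_significant_terms = if (!is.null(enr)) sum(enr$significant) else NA_integer_,
    n_term_groups = n_groups
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  invisible(list(sets = sets, core = core, network = net, partition = part,
                 main = main, degree_distribution = dist, power_law = fit,
                 centrality = tab, selection = sel, complexes = cx,
                 membership = memb, enrichment = enr, summary = summary))
}
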