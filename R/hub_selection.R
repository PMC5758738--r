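#' Degree cutoff for hub calling
#'
#' `mean(degree) + sd_multiplier * sd(degree)`. The standard deviation is
#' the population form by default (denominator n): the node set analyzed is
#' the entire population under study, not a sample from a larger network.
#' Switch to the sample form with `sd_type = "sample"`.
#'
#' @param degrees named numeric vector of node degrees (>= 2 nodes).
#' @param sd_multiplier number of standard deviations above the mean
#'   (default 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The numeric cutoff.
#' @export
degree_cutoff <- function(degrees, sd_multiplier = 2,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(degrees) < 2L) stop("need >= 2 nodes for a degree cutoff", call. = FALSE)
  s <- if (sd_type == "population") pop_sd(degrees) else sd(degrees)
  mean(degrees) + sd_multiplier * s
}

#' Call hub nodes by degree cutoff
#'
#' All nodes whose degree is greater than or equal to the cutoff. The
#' boundary is inclusive: a node exactly at the cutoff is a hub (selection
#' of the "highest-degree" nodes favors inclusion); set
#' `inclusive = FALSE` for a strict boundary.
#'
#' @param table a [centrality_table()] (or data.frame with `node`, `degree`).
#' @param cutoff numeric degree cutoff, e.g. from [degree_cutoff()].
#' @param inclusive include nodes exactly at the cutoff?
#' @return A [gene_set()] of hub symbols (possibly empty, with a warning).
#' @export
select_hubs <- function(table, cutoff, inclusive = TRUE) {
  stopifnot(is.finite(cutoff))
  keep <- if (inclusive) table$degree >= cutoff else table$degree > cutoff
  if (!any(keep)) warning("degree cutoff selected no hubs", call. = FALSE)
  gene_set(table$node[keep], name = "hubs")
}

#' Top-fraction selection on a centrality metric
#'
#' The `ceiling(fraction * n)` highest-valued nodes on one metric. Ties at
#' the boundary value are all included — the set may exceed its nominal
#' size (reported via a message) — so selection never depends on an
#' arbitrary ordering among equal values.
#'
#' @param table a [centrality_table()].
#' @param metric one of `"betweenness"`, `"closeness"`, `"stress"`,
#'   `"degree"`.
#' @param fraction fraction of nodes to keep, in (0, 1\]; default 0.05
#'   (the conventional top 5 percent).
#' @return A [gene_set()] of the selected symbols.
#' @export
top_fraction <- function(table, metric = c("betweenness", "closeness",
                                           "stress", "degree"),
                         fraction = 0.05) {
  metric <- match.arg(metric)
  stopifnot(fraction > 0, fraction <= 1)
  vals <- table[[metric]]
  n_keep <- ceiling(fraction * nrow(table))
  boundary <- sort(vals, decreasing = TRUE)[n_keep]
  keep <- vals >= boundary
  if (sum(keep) > n_keep) {
    message(sprintf("top_fraction(%s): boundary tie expanded %d -> %d nodes",
                    metric, n_keep, sum(keep)))
  }
  gene_set(table$node[keep], name = paste0("top_", metric))
}

#' Hub-bottleneck intersection
#'
#' Bottlenecks are the top betweenness fraction; hub-bottlenecks are hubs
#' that are also bottlenecks — nodes both highly connected and in control
#' of many shortest paths.
#'
#' @param hubs [gene_set()] of hubs.
#' @param top_bc [gene_set()] of top-betweenness nodes.
#' @return A [gene_set()] of hub-bottleneck symbols.
#' @export
hub_bottlenecks <- function(hubs, top_bc) {
  gene_set(intersect(hubs, top_bc), name = "hub_bottlenecks")
}

#' Run the full selection rule set on a centrality table
#'
#' Applies the degree cutoff (mean + `sd_multiplier` SD), the top-fraction
#' selections on betweenness, closeness and stress, and the hub-bottleneck
#' intersection, returning everything needed for the crucial-gene report.
#'
#' @param table a [centrality_table()].
#' @param fraction top fraction per metric (default 0.05).
#' @param sd_multiplier SD multiplier for the degree cutoff (default 2).
#' @param sd_type passed to [degree_cutoff()].
#' @param inclusive passed to [select_hubs()].
#' @return An object of class `selection_result`: list with `degree_cutoff`,
#'   `hubs`, `top_bc`, `top_cc`, `top_stress`, `hub_bottlenecks`.
#' @export
select_crucial <- function(table, fraction = 0.05, sd_multiplier = 2,
                           sd_type = "population", inclusive = TRUE) {
  cutoff <- degree_cutoff(stats::setNames(table$degree, table$node),
                          sd_multiplier = sd_multiplier, sd_type = sd_type)
  hubs <- select_hubs(table, cutoff, inclusive = inclusive)
  top_bc <- top_fraction(table, "betweenness", fraction)
  structure(
    list(degree_cutoff = cutoff,
         hubs = hubs,
         top_bc = top_bc,
         top_cc = top_fraction(table, "closeness", fraction),
         top_stress = top_fraction(table, "stress", fraction),
         hub_bottlenecks = hub_bottlenecks(hubs, top_bc)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> cutoff %.3f | %d hubs | %d ",
                     "hub-bottlenecks | top sets BC/CC/stress: %d/%d/%d\n"),
              x$degree_cutoff, length(x$hubs), length(x$hub_bottlenecks),
              length(x$top_bc), length(x$top_cc), length(x$top_stress)))
  invisible(x)
}

#' Crucial-gene membership matrix
#'
#' One row per hub-bottleneck gene with logical columns recording hub
#' status, hub-bottleneck status, membership in the top-stress and
#' top-closeness sets, and membership in each detected complex — the
#' standard cross-tabulation used to report which crucial genes the dense
#' clusters capture.
#'
#' @param sel a [select_crucial()] result.
#' @param complexes optional list of complexes from [mcode()] (clusters are
#'   columns `cluster1..k`).
#' @return A data.frame with one row per hub-bottleneck; a `summary`
#'   attribute carries the per-column counts.
#' @export
membership_report <- function(sel, complexes = NULL) {
  genes <- sort(sel$hub_bottlenecks)
  mat <- data.frame(
    gene = genes,
    hub = genes %in% sel$hubs,
    hub_bottleneck = rep(TRUE, length(genes)),
    top_stress = genes %in% sel$top_stress,
    top_cc = genes %in% sel$top_cc,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(complexes)) {
    mat[[paste0("cluster", i)]] <- genes %in% complexes[[i]]$members
  }
  if (length(genes) == 0L) mat <- mat[0L, , drop = FALSE]
  rownames(mat) <- NULL
  counts <- vapply(mat[, -1L, drop = FALSE], sum, numeric(1))
  attr(mat, "summary") <- counts
  mat
}
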