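#' Connected-component decomposition
#'
#' Partitions the network into connected components, ordered by decreasing
#' node count with ties broken by the lexicographically smallest member
#' symbol (so ordering is deterministic for equal-sized components).
#'
#' @param net a [ppi_network()] igraph object.
#' @return An object of class `component_partition`: a list with
#'   `components` (list of character vectors of node names) and `sizes`
#'   (data.frame with `n_nodes`, `n_edges` per component).
#' @export
component_partition <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(net)
  groups <- split(igraph::V(net)$name, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1L))
  groups <- unname(groups[ord])
  n_edges <- vapply(groups, function(g) {
    igraph::ecount(igraph::induced_subgraph(net, g))
  }, numeric(1))
  structure(
    list(components = groups,
         sizes = data.frame(component = seq_along(groups),
                            n_nodes = lengths(groups),
                            n_edges = as.integer(n_edges))),
    class = "component_partition"
  )
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("<component_partition> %d component(s)\n", length(x$components)))
  print(x$sizes, row.names = FALSE)
  invisible(x)
}

#' Extract the main (largest) connected component
#'
#' The main component is the substrate for centrality analysis: betweenness,
#' closeness and stress are only defined within one component. Ties on
#' component size are broken by the smallest member symbol.
#'
#' @param net a [ppi_network()] igraph object.
#' @return The induced subgraph on the largest component.
#' @export
main_component <- function(net) {
  part <- component_partition(net)
  igraph::induced_subgraph(net, part$components[[1L]])
}

#' Neighborhood expansion around seed genes
#'
#' Induced subgraph on all nodes within graph distance `depth` of any seed
#' present in the network — the usual way an interaction neighborhood is
#' grown around a disease gene core. Seeds absent from the network are
#' reported via a message, not an error; at least one seed must be present.
#'
#' @param net a [ppi_network()] igraph object.
#' @param seeds a [gene_set()] or character vector of seed symbols.
#' @param depth non-negative integer BFS radius; `depth = 0` returns the
#'   induced subgraph on the seeds themselves.
#' @return The induced subgraph on the `depth`-neighborhood of the seeds.
#' @export
expand_network <- function(net, seeds, depth = 1L) {
  stopifnot(depth >= 0L)
  seeds <- toupper(as.character(seeds))
  present <- intersect(seeds, igraph::V(net)$name)
  missing <- setdiff(seeds, present)
  if (length(missing)) {
    message(sprintf("%d seed(s) absent from network: %s", length(missing),
                    paste(head(sort(missing), 5L), collapse = ", ")))
  }
  if (length(present) == 0L) stop("no seed present in network", call. = FALSE)
  d <- igraph::distances(net, v = present)
  keep <- colnames(d)[apply(d, 2L, min) <= depth]
  igraph::induced_subgraph(net, sort(keep))
}

#' Degree distribution of a network
#'
#' Counts nodes per degree value for all degrees k >= 1; zero-degree
#' (isolated) nodes are tallied separately because they cannot enter the
#' log-log power-law fit. The handshake identity
#' `sum(k * count(k)) == 2 * |E|` is asserted.
#'
#' @param net a [ppi_network()] igraph object.
#' @return A data.frame of class `degree_distribution` with columns `k` and
#'   `count`, plus an `n_isolated` attribute.
#' @export
degree_distribution <- function(net) {
  deg <- igraph::degree(net)
  n_isolated <- sum(deg == 0L)
  deg <- deg[deg > 0L]
  tab <- table(deg)
  out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  stopifnot(sum(out$k * out$count) == 2L * igraph::ecount(net))
  structure(out, n_isolated = n_isolated,
            class = c("degree_distribution", "data.frame"))
}

#' Power-law fit of a degree distribution
#'
#' Fits `count(k) = a * k^b` by ordinary least squares on the log10-log10
#' points with positive counts — the display convention of Cytoscape's
#' NetworkAnalyzer, whose fitted line is the standard visual check that an
#' interaction network is scale-free. Maximum-likelihood (Clauset-style)
#' exponent estimation is deliberately not used here; the fit mirrors what
#' network-analysis tools print alongside the degree histogram.
#'
#' @param dist a [degree_distribution()] (or data.frame with `k`, `count`).
#' @return A list of class `power_law_fit` with `a` (coefficient),
#'   `b` (exponent, negative for heavy-tailed networks), `r_squared` of the
#'   log-log regression, and `correlation` (absolute Pearson correlation of
#'   the log-log points).
#' @export
fit_power_law <- function(dist) {
  pts <- dist[dist$count > 0L & dist$k > 0L, , drop = FALSE]
  if (nrow(pts) < 3L) stop("insufficient support for fit (< 3 degrees)", call. = FALSE)
  lx <- log10(pts$k)
  ly <- log10(pts$count)
  fit <- lm(ly ~ lx)
  res <- ly - fitted(fit)
  sst <- sum((ly - mean(ly))^2)
  # flat data (all counts equal): define R2 = 1 when residuals vanish
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else as.numeric(sum(res^2) < 1e-18)
  corr <- if (sst > 0) abs(cor(lx, ly)) else 0
  structure(
    list(a = 10^unname(coef(fit)[1L]),
         b = unname(coef(fit)[2L]),
         r_squared = r2,
         correlation = corr),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> count(k) = %.4g * k^(%.4g)  R2 = %.4f  |r| = %.4f\n",
              x$a, x$b, x$r_squared, x$correlation))
  invisible(x)
}
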