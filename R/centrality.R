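#' Node centralities for hub and bottleneck ranking
#'
#' Four topological centralities drive the selection rules: raw degree,
#' betweenness, closeness and stress. All shortest paths are unweighted
#' (BFS) even when edge scores are present — ranking in this setting is
#' topological, and confidence scores are a filter, not a distance.
#' Betweenness, closeness and stress require a connected graph; compute
#' them on [main_component()].
#'
#' @name centrality
NULL

assert_connected <- function(net, what) {
  if (!igraph::is_connected(net)) {
    stop(what, " requires a connected graph; extract main_component() first",
         call. = FALSE)
  }
}

#' Degree centrality (raw degree)
#'
#' Raw counts, not normalized: the hub cutoff (mean degree plus two
#' standard deviations) operates on raw degrees.
#'
#' @param net a [ppi_network()] igraph object.
#' @return Named integer vector of node degrees.
#' @export
degree_centrality <- function(net) {
  deg <- igraph::degree(net, loops = FALSE)
  storage.mode(deg) <- "integer"
  deg
}

#' Betweenness centrality (Brandes algorithm)
#'
#' Sum over unordered node pairs (s, t), s != v != t, of the fraction of
#' shortest s-t paths passing through v. Endpoints never mediate their own
#' pairs. Unnormalized by default — top-fraction selection is invariant to
#' the normalization constant; set `normalized = TRUE` to divide by
#' (n-1)(n-2)/2.
#'
#' @param net a connected [ppi_network()] igraph object.
#' @param normalized divide by the number of pairs?
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  assert_connected(net, "betweenness")
  igraph::betweenness(net, directed = FALSE, weights = NA,
                      normalized = normalized)
}

#' Stress centrality
#'
#' For each node v, the integer count of shortest paths between unordered
#' pairs (s, t), s != v != t, that pass through v — like betweenness but
#' counting whole paths instead of per-pair fractions. Computed by a
#' Brandes-style BFS sweep: from each source s, sigma(v) counts shortest
#' s->v paths and tau(v) counts shortest-path continuations from v in the
#' BFS DAG, so sigma(v) * tau(v) is the number of shortest paths from s
#' through v; summing over sources counts every unordered pair twice.
#'
#' Pairs are counted once (unordered), matching the betweenness convention
#' so the two measures are comparable; some tools count ordered pairs and
#' report exactly twice these values.
#'
#' @param net a connected [ppi_network()] igraph object.
#' @return Named numeric vector of integer-valued stress counts.
#' @export
stress_centrality <- function(net) {
  assert_connected(net, "stress")
  n <- igraph::vcount(net)
  names_v <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  stress <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head_i <- 1L
    tail_i <- 1L
    order_visited <- integer(n)
    while (head_i <= tail_i) {
      v <- queue[head_i]
      order_visited[head_i] <- v
      head_i <- head_i + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail_i <- tail_i + 1L
          queue[tail_i] <- w
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    # tau(v): number of shortest-path continuations v -> ... -> t over all t,
    # accumulated in reverse BFS order over the shortest-path DAG
    tau <- numeric(n)
    for (i in seq.int(tail_i, 1L)) {
      v <- order_visited[i]
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] + 1L) tau[v] <- tau[v] + 1 + tau[w]
      }
      if (v != s) stress[v] <- stress[v] + sigma[v] * tau[v]
    }
  }
  stress <- stress / 2
  names(stress) <- names_v
  stress
}

#' Closeness centrality
#'
#' `(n - 1) / sum_t dist(v, t)` — the normalized closeness in (0, 1], equal
#' to 1 only for a node adjacent to every other.
#'
#' @param net a connected [ppi_network()] igraph object.
#' @return Named numeric vector of closeness values.
#' @export
closeness_centrality <- function(net) {
  assert_connected(net, "closeness")
  igraph::closeness(net, weights = NA, normalized = TRUE)
}

#' Assemble the four-centrality table
#'
#' One row per node of a connected network with degree, betweenness
#' (unnormalized), closeness and stress, sorted by degree descending then
#' symbol — the input contract for the hub-selection stage.
#'
#' @param net a connected [ppi_network()] igraph object.
#' @return A data.frame of class `centrality_table` with columns `node`,
#'   `degree`, `betweenness`, `closeness`, `stress`.
#' @export
centrality_table <- function(net) {
  assert_connected(net, "centrality table")
  nodes <- igraph::V(net)$name
  tab <- data.frame(
    node = nodes,
    degree = degree_centrality(net)[nodes],
    betweenness = betweenness_centrality(net)[nodes],
    closeness = closeness_centrality(net)[nodes],
    stress = stress_centrality(net)[nodes],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$degree, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  tab
}
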