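#' MCODE parameters
#'
#' Defaults follow the parameter set popularized by the Cytoscape MCODE
#' app: degree cutoff 2, node score cutoff 0.2, k-core 2, max depth 100,
#' haircut on, fluff off. The node score cutoff is a *fraction below the
#' seed's weight* (a neighbor joins while its weight is at least
#' `seed_weight * (1 - node_score_cutoff)`), not an absolute threshold.
#'
#' @param degree_cutoff minimum degree for a node to receive a nonzero
#'   weight (default 2).
#' @param node_score_cutoff fraction in \[0, 1) below the seed weight still
#'   admitted during expansion (default 0.2).
#' @param k_core discard complexes whose subgraph contains no k-core of
#'   this order after post-processing (default 2).
#' @param max_depth maximum BFS depth from the seed (default 100).
#' @param haircut iteratively remove members with fewer than two
#'   in-complex edges (default TRUE).
#' @param fluff add unassigned neighbors whose closed-neighborhood density
#'   exceeds `fluff_density_cutoff` (default FALSE).
#' @param fluff_density_cutoff density threshold for fluff (default 0.1).
#' @param include_loops count self-loops in neighborhood density (kept for
#'   interface completeness; networks here are simple so it has no effect).
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L, haircut = TRUE,
                         fluff = FALSE, fluff_density_cutoff = 0.1,
                         include_loops = FALSE) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff < 1,
            degree_cutoff >= 0L, k_core >= 0L, max_depth >= 0L)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut),
                 fluff = isTRUE(fluff),
                 fluff_density_cutoff = fluff_density_cutoff,
                 include_loops = isTRUE(include_loops)),
            class = "mcode_params")
}

graph_density <- function(n, m) if (n < 2L) 0 else 2 * m / (n * (n - 1L))

# highest k-core of a graph: (k_max, members) via coreness
highest_k_core <- function(g) {
  if (igraph::vcount(g) == 0L) return(list(k = 0L, members = character(0)))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, members = names(core)[core >= k])
}

#' MCODE vertex weighting
#'
#' Each node's weight is `k * density` of the highest k-core of the
#' subgraph induced by its closed neighborhood (the node plus its
#' neighbors) — the core-clustering coefficient times the core order.
#' Nodes whose degree falls below `degree_cutoff` get weight 0 and can
#' neither seed nor join a complex on their own merit.
#'
#' @param net a [ppi_network()] igraph object.
#' @param params an [mcode_params()] list.
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  w <- numeric(length(nodes))
  names(w) <- nodes
  for (i in seq_along(nodes)) {
    if (deg[i] < params$degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, nb)
    hk <- highest_k_core(sub)
    core_sub <- igraph::induced_subgraph(sub, hk$members)
    w[i] <- hk$k * graph_density(igraph::vcount(core_sub),
                                 igraph::ecount(core_sub))
  }
  w
}

# grow one complex from a seed by BFS over the weight threshold;
# returns the raw member set before post-processing
mcode_expand_seed <- function(adj, weights, seed_i, assigned, params) {
  threshold <- weights[seed_i] * (1 - params$node_score_cutoff)
  depth <- integer(length(weights))
  included <- logical(length(weights))
  included[seed_i] <- TRUE
  frontier <- seed_i
  d <- 0L
  while (length(frontier) && d < params$max_depth) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!included[w] && !assigned[w] && weights[w] >= threshold) {
          included[w] <- TRUE
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  which(included)
}

#' Detect dense complexes (MCODE-style)
#'
#' Greedy seeded expansion over [mcode_vertex_weights()]: the
#' highest-weight unassigned node seeds a complex; neighbors are included
#' breadth-first while their weight stays within `node_score_cutoff` of the
#' seed's and they are not already part of another complex. Post-processing
#' applies the haircut (iterative removal of members with fewer than two
#' in-complex edges, keeping the seed's connected component), the k-core
#' filter, and optional fluff. Complexes are scored `density * size` and
#' returned in decreasing score order (ties: larger size, then
#' lexicographically smaller seed). All tie-breaks are lexicographic, so
#' identical input yields an identical complex list.
#'
#' @param net a [ppi_network()] igraph object.
#' @param params an [mcode_params()] list.
#' @return A list of class `mcode_result`; each element is a list with
#'   `seed`, `members` (sorted character vector), `density`, `score`,
#'   `rank`.
#' @export
mcode <- function(net, params = mcode_params()) {
  nodes <- igraph::V(net)$name
  weights <- mcode_vertex_weights(net, params)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  # deterministic seed order: weight desc, then symbol
  order_seeds <- order(-weights, nodes)
  assigned <- logical(length(nodes))
  seen_seed <- logical(length(nodes))
  complexes <- list()
  for (seed_i in order_seeds) {
    if (assigned[seed_i] || seen_seed[seed_i] || weights[seed_i] <= 0) next
    seen_seed[seed_i] <- TRUE
    members_i <- mcode_expand_seed(adj, weights, seed_i, assigned, params)
    members <- nodes[members_i]
    sub <- igraph::induced_subgraph(net, members)
    if (params$haircut) {
      repeat {
        low <- igraph::V(sub)$name[igraph::degree(sub) < 2L]
        if (length(low) == 0L || igraph::vcount(sub) <= length(low)) {
          if (length(low)) sub <- igraph::induced_subgraph(sub, character(0))
          break
        }
        sub <- igraph::induced_subgraph(sub, setdiff(igraph::V(sub)$name, low))
      }
      if (!(nodes[seed_i] %in% igraph::V(sub)$name)) next
      comp <- igraph::components(sub)
      keep <- names(comp$membership)[
        comp$membership == comp$membership[[nodes[seed_i]]]]
      sub <- igraph::induced_subgraph(sub, keep)
    }
    if (igraph::vcount(sub) == 0L) next
    if (highest_k_core(sub)$k < params$k_core) next
    members <- sort(igraph::V(sub)$name)
    if (params$fluff) {
      cand <- setdiff(nodes[unique(unlist(adj[match(members, nodes)]))], members)
      cand <- cand[!assigned[match(cand, nodes)]]
      keep <- vapply(cand, function(v) {
        nb <- c(v, nodes[adj[[match(v, nodes)]]])
        s <- igraph::induced_subgraph(net, nb)
        graph_density(igraph::vcount(s), igraph::ecount(s)) >
          params$fluff_density_cutoff
      }, logical(1))
      members <- sort(union(members, cand[keep]))
      sub <- igraph::induced_subgraph(net, members)
    }
    assigned[match(members, nodes)] <- TRUE
    dens <- graph_density(igraph::vcount(sub), igraph::ecount(sub))
    complexes[[length(complexes) + 1L]] <- list(
      seed = nodes[seed_i],
      members = members,
      density = dens,
      score = dens * length(members)
    )
  }
  if (length(complexes)) {
    ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
                 -lengths(lapply(complexes, `[[`, "members")),
                 vapply(complexes, `[[`, character(1), "seed"))
    complexes <- complexes[ord]
    for (i in seq_along(complexes)) complexes[[i]]$rank <- i
  }
  structure(complexes, class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("<mcode_result> %d complex(es)\n", length(x)))
  for (cx in x) {
    cat(sprintf("  #%d seed %s: %d nodes, density %.3f, score %.3f\n",
                cx$rank, cx$seed, length(cx$members), cx$density, cx$score))
  }
  invisible(x)
}

#' Seed node of a complex
#'
#' The highest-weight vertex the complex was grown from, reported as the
#' cluster's representative gene.
#'
#' @param cx one element of an [mcode()] result.
#' @return The seed's gene symbol.
#' @export
seed_of <- function(cx) {
  if (length(cx$members) == 0L) stop("empty complex", call. = FALSE)
  cx$seed
}

#' Tabulate an MCODE result
#'
#' @param x an [mcode()] result.
#' @param ... unused.
#' @return data.frame with rank, seed, score, density, n_nodes, members.
#' @export
as.data.frame.mcode_result <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(rank = integer(0), seed = character(0),
                      score = numeric(0), density = numeric(0),
                      n_nodes = integer(0), members = character(0)))
  }
  data.frame(
    rank = vapply(x, `[[`, numeric(1), "rank"),
    seed = vapply(x, `[[`, character(1), "seed"),
    score = vapply(x, `[[`, numeric(1), "score"),
    density = vapply(x, `[[`, numeric(1), "density"),
    n_nodes = lengths(lapply(x, `[[`, "members")),
    members = vapply(x, function(cx) paste(cx$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
}
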