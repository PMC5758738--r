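#' Read a GMT gene-set annotation file
#'
#' GMT: one term per line, tab-separated — `term_id <tab> description
#' <tab> gene1 <tab> gene2 ...`. Genes are uppercased and deduplicated
#' within a term. The annotation universe defaults to the union of all
#' term genes; pass `universe` to use an explicit background instead
#' (recommended when the annotation does not cover every assayable gene).
#'
#' @param path GMT file.
#' @param universe optional character vector overriding the universe.
#' @return A list of class `annotation_set` with `terms` (named list of
#'   gene vectors), `term_names` (named character), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3L)[1L]),
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT", call. = FALSE)
  terms <- lapply(fields, function(f) sort(unique(toupper(f[-(1:2)]))))
  names(terms) <- ids
  if (any(lengths(terms) == 0L)) stop("empty term in GMT", call. = FALSE)
  term_names <- vapply(fields, `[`, character(1), 2L)
  names(term_names) <- ids
  annotation_set(terms, term_names, universe)
}

#' Construct an annotation set from in-memory gene sets
#'
#' @param terms named list of character vectors (term id -> member genes).
#' @param term_names optional named character vector of descriptions.
#' @param universe optional background gene vector; defaults to the union
#'   of all term genes. Every annotated gene must lie in the universe.
#' @return A list of class `annotation_set`.
#' @export
annotation_set <- function(terms, term_names = NULL, universe = NULL) {
  stopifnot(is.list(terms), length(terms) > 0L, !is.null(names(terms)))
  terms <- lapply(terms, function(g) sort(unique(toupper(g))))
  if (any(lengths(terms) == 0L)) stop("empty term", call. = FALSE)
  all_genes <- sort(unique(unlist(terms, use.names = FALSE)))
  universe <- if (is.null(universe)) all_genes else
    sort(unique(toupper(universe)))
  if (!all(all_genes %in% universe)) {
    stop("annotated gene(s) outside the universe", call. = FALSE)
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 universe = universe),
            class = "annotation_set")
}

#' Write an annotation set in GMT format
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @export
write_gmt <- function(ann, path) {
  ids <- names(ann$terms)
  lines <- vapply(ids, function(id) {
    paste(c(id, ann$term_names[[id]], ann$terms[[id]]), collapse = "\t")
  }, character(1))
  write_lines_lf(lines, path)
}

#' Upper-tail hypergeometric p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. The tail includes `k` itself, so `k = 0` gives exactly 1.
#'
#' @param k observed overlap (query and term).
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return The p-value in (0, 1\].
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0, k <= K, K <= N, k <= n, n <= N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene set
#'
#' Tests every annotation term for enrichment in the query with the
#' upper-tail hypergeometric test, then adjusts across terms
#' (Benjamini-Hochberg by default, Bonferroni by flag). Query genes outside
#' the universe are dropped with a reported count.
#'
#' @param query a [gene_set()] or character vector of query genes.
#' @param ann an [annotation_set()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return A data.frame of class `enrichment_result`, one row per term,
#'   sorted by p ascending: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`. The effective query is kept in the `query`
#'   attribute (used by [kappa_grouping()]).
#' @export
ora <- function(query, ann, alpha = 0.05, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  query <- sort(unique(toupper(as.character(query))))
  eff <- intersect(query, ann$universe)
  dropped <- length(query) - length(eff)
  if (dropped > 0L) {
    message(sprintf("ora: dropped %d query gene(s) outside the universe", dropped))
  }
  if (length(eff) == 0L) stop("query has no genes in the universe", call. = FALSE)
  N <- length(ann$universe)
  n <- length(eff)
  K <- lengths(ann$terms)
  k <- vapply(ann$terms, function(g) length(intersect(g, eff)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
  res <- data.frame(
    term_id = names(ann$terms),
    term_name = unname(ann$term_names[names(ann$terms)]),
    k = unname(k), K = unname(K), n = n, N = N,
    p = unname(p), q = unname(q),
    significant = unname(q <= alpha),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "query") <- eff
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# Cohen's kappa between two membership vectors (logical, same length)
cohen_kappa <- function(x, y) {
  t_n <- length(x)
  a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
  po <- (a + d) / t_n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / t_n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Group significant terms by kappa agreement
#'
#' Collapses redundant enriched terms into groups: Cohen's kappa is
#' computed between every pair of significant terms over their membership
#' vectors restricted to the query genes, term pairs with kappa at or
#' above the threshold are linked, and connected components of the link
#' graph become groups (single-linkage). Each group is labelled by its
#' most significant member term. Non-significant terms get `NA` groups.
#'
#' @param res an [ora()] result.
#' @param ann the [annotation_set()] the result was computed on.
#' @param kappa_threshold minimum kappa to link two terms (default 0.4,
#'   the conventional grouping threshold).
#' @return `res` with added columns `group` (label) and `kappa_group`
#'   (integer id); the number of groups is in the `n_groups` attribute.
#' @export
kappa_grouping <- function(res, ann, kappa_threshold = 0.4) {
  query <- attr(res, "query")
  if (is.null(query)) stop("result lacks its query attribute", call. = FALSE)
  sig <- res$term_id[res$significant]
  res$kappa_group <- NA_integer_
  res$group <- NA_character_
  if (length(sig) == 0L) {
    attr(res, "n_groups") <- 0L
    return(res)
  }
  memb <- vapply(ann$terms[sig], function(g) query %in% g,
                 logical(length(query)))
  memb <- matrix(memb, nrow = length(query))
  ns <- length(sig)
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      for (j in seq.int(i + 1L, ns)) {
        if (cohen_kappa(memb[, i], memb[, j]) >= kappa_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  # label each group by its most significant member (res is sorted by p)
  group_id <- match(roots, unique(roots[order(match(sig, res$term_id))]))
  labels <- vapply(split(seq_len(ns), group_id), function(idx) {
    sig[idx][which.min(match(sig[idx], res$term_id))]
  }, character(1))
  pos <- match(sig, res$term_id)
  res$kappa_group[pos] <- group_id
  res$group[pos] <- labels[group_id]
  attr(res, "n_groups") <- length(unique(group_id))
  res
}
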