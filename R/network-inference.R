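# Microbiota-invader networks (MIN) and co-occurrence networks (MCN):
# pairwise Spearman correlations with double-zero exclusion and FDR control,
# degree-based invader ranking, greedy modularity communities, and
# cross-experiment community matching.

#' All-pairs Spearman correlations between taxa
#'
#' For every unordered taxon pair, samples on which both taxa are zero are
#' excluded, then the tie-corrected Spearman rho and its t-approximation
#' p-value are computed on the remaining samples. P-values are adjusted by
#' Benjamini-Hochberg over all computed pairs (one shared family for both
#' the invader and the co-occurrence network). Pairs with fewer than 3
#' usable samples, or with a constant vector after exclusion, get NA rho and
#' are excluded from the networks.
#'
#' @param a an `abundance_table` (typically genus level, post-experiment
#'   samples only).
#' @param taxa taxa to correlate (subset of `colnames(a$values)`).
#' @param alpha significance level recorded for downstream edge filtering.
#' @return A data.frame of class `correlation_result` with columns
#'   `taxon_i`, `taxon_j` (i < j in `taxa` order), `rho`, `n_used`, `p`,
#'   `p_adj`, and attribute `alpha`.
#' @export
pairwise_spearman <- function(a, taxa, alpha = 0.05) {
  vals <- a$values
  missing <- setdiff(taxa, colnames(vals))
  if (length(missing) > 0)
    stop("taxa absent from table: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa")
  vals <- vals[, taxa, drop = FALSE]
  nt <- length(taxa)
  combs <- utils::combn(nt, 2)
  np <- ncol(combs)
  rho <- p <- rep(NA_real_, np)
  n_used <- integer(np)
  for (k in seq_len(np)) {
    x <- vals[, combs[1, k]]
    y <- vals[, combs[2, k]]
    keep <- !(x == 0 & y == 0)     # drop double-zero surfaces
    res <- spearman_test(x[keep], y[keep])
    rho[k] <- res$rho
    p[k] <- res$p
    n_used[k] <- res$n
  }
  out <- data.frame(taxon_i = taxa[combs[1, ]], taxon_j = taxa[combs[2, ]],
                    rho = rho, n_used = n_used, p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_result", "data.frame")
  out
}

taxon_network <- function(vertices, edges, mode) {
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_i", "taxon_j", "weight")],
    directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE))
  structure(list(graph = g, edges = edges, mode = mode,
                 isolated = vertices[igraph::degree(g)[vertices] == 0]),
            class = "taxon_network")
}

#' @export
print.taxon_network <- function(x, ...) {
  cat(x$mode, "network:", igraph::vcount(x$graph), "taxa,",
      igraph::ecount(x$graph), "edges (",
      length(x$isolated), "isolated )\n")
  invisible(x)
}

#' Build a microbiota-invader network (MIN)
#'
#' Edges are taxon pairs with significantly negative Spearman rho
#' (rho < 0 and adjusted p strictly below `alpha`); edge weight is |rho|.
#' An invader dilutes every native taxon's relative abundance, so it is
#' expected to attain the highest degree.
#'
#' @param c a `correlation_result` from [pairwise_spearman()].
#' @param alpha significance threshold (default the one stored in `c`).
#' @return A `taxon_network` with mode `"MIN"`; vertices with no edges are
#'   retained and listed in `$isolated`.
#' @export
build_min <- function(c, alpha = attr(c, "alpha")) {
  keep <- !is.na(c$rho) & c$rho < 0 & !is.na(c$p_adj) & c$p_adj < alpha
  edges <- c[keep, , drop = FALSE]
  edges$weight <- abs(edges$rho)
  taxon_network(unique(c(c$taxon_i, c$taxon_j)), edges, "MIN")
}

#' Build a microbiota co-occurrence network (MCN)
#'
#' Edges are taxon pairs with significantly positive Spearman rho; edge
#' weight is rho^3, which spreads the edge-weight distribution and yields a
#' finer community division.
#'
#' @inheritParams build_min
#' @return A `taxon_network` with mode `"MCN"`.
#' @export
build_mcn <- function(c, alpha = attr(c, "alpha")) {
  keep <- !is.na(c$rho) & c$rho > 0 & !is.na(c$p_adj) & c$p_adj < alpha
  edges <- c[keep, , drop = FALSE]
  edges$weight <- edges$rho^3
  taxon_network(unique(c(c$taxon_i, c$taxon_j)), edges, "MCN")
}

#' Rank invader candidates by MIN degree
#'
#' Each taxon is scored by its unweighted degree in the invader network;
#' the top-ranked taxon is the most probable invader. Ties are broken by
#' summed |rho| over incident edges, then lexicographically.
#'
#' @param net a `taxon_network` of mode `"MIN"`.
#' @return data.frame with columns `taxon`, `degree`, `strength`, ordered
#'   most probable invader first.
#' @export
rank_invader_candidates <- function(net) {
  stopifnot(inherits(net, "taxon_network"))
  if (net$mode != "MIN") stop("invader ranking requires a MIN")
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    warning("empty MIN: no significant negative correlations")
    return(data.frame(taxon = character(), degree = integer(),
                      strength = numeric(), stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)
  strength <- igraph::strength(g, weights = igraph::E(g)$weight)
  nm <- names(deg)
  ord <- order(-deg, -strength, nm)
  data.frame(taxon = nm[ord], degree = as.integer(deg[ord]),
             strength = as.numeric(strength[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect communities by greedy modularity optimization
#'
#' Fast-greedy agglomerative modularity maximization (Clauset-Newman-Moore)
#' on the weighted graph, as implemented in igraph.
#'
#' @param net a `taxon_network` (typically an MCN, whose weights are rho^3).
#' @return A list of class `community_partition`: `membership` (named
#'   integer vector over vertices with >= 1 neighbor) and `modularity`.
#' @export
detect_communities <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0) stop("cannot detect communities: no edges")
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  structure(list(membership = stats::setNames(igraph::membership(cl),
                                              igraph::V(g)$name),
                 modularity = max(cl$modularity)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(unique(x$membership)), "communities,",
      "modularity", round(x$modularity, 4), "\n")
  invisible(x)
}

#' Match communities across two partitions by Jaccard similarity
#'
#' Scores every cross-partition community pair by the Jaccard index of its
#' member sets, |intersection| / |union|, and reports the taxa shared by the
#' best-matching pair — the taxa "in the same community" in both
#' experiments.
#'
#' @param p1,p2 `community_partition`s (possibly over different taxon sets).
#' @return List with `pairs` (data.frame label1, label2, jaccard, sorted
#'   descending) and `best_shared` (character vector of taxa in the
#'   best-matching pair's intersection).
#' @export
match_communities <- function(p1, p2) {
  s1 <- split(names(p1$membership), p1$membership)
  s2 <- split(names(p2$membership), p2$membership)
  grid <- expand.grid(label1 = names(s1), label2 = names(s2),
                      stringsAsFactors = FALSE)
  grid$jaccard <- mapply(function(a, b) {
    length(intersect(s1[[a]], s2[[b]])) / length(union(s1[[a]], s2[[b]]))
  }, grid$label1, grid$label2)
  grid <- grid[order(-grid$jaccard, grid$label1, grid$label2), , drop = FALSE]
  rownames(grid) <- NULL
  best_shared <- if (nrow(grid) > 0 && grid$jaccard[1] > 0)
    sort(intersect(s1[[grid$label1[1]]], s2[[grid$label2[1]]]))
  else character()
  list(pairs = grid, best_shared = best_shared)
}
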