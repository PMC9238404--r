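# Surface touch network: log10-weighted touch graph, geodesic distances
# from the carrier's hands, eigencentrality, and the bipartite hand-hand
# intimacy projection used to identify each participant's "best friend".

#' Read a touch log from CSV
#'
#' Expects columns `time_s`, `surface_u`, `surface_v`. Both hands of a
#' participant are represented as a single surface.
#'
#' @param path path to the CSV file.
#' @return data.frame with the three columns, times non-decreasing.
#' @export
read_touch_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "surface_u", "surface_v")
  if (!all(need %in% names(log)))
    stop("touch log must have columns ", paste(need, collapse = ", "))
  if (any(log$surface_u == log$surface_v)) stop("self-touch record in log")
  if (is.unsorted(log$time_s)) log <- log[order(log$time_s), , drop = FALSE]
  log[, need]
}

#' Build a surface touch network from a touch log
#'
#' Vertices are surfaces; an edge joins two surfaces touched together at
#' least once, weighted by the log10-transformed touch count. Under the
#' default `"log10"` dialect a single touch gives a zero-weight edge that
#' still exists for geodesic distances; the `"log10p1"` dialect uses
#' log10(count + 1) so every edge has positive weight.
#'
#' @param log touch log data.frame (see [read_touch_log()]).
#' @param vertices optional full surface id vector (adds untouched surfaces
#'   as isolated vertices).
#' @param dialect `"log10"` (default) or `"log10p1"`.
#' @return An object of class `touch_network`: `graph` (igraph with `weight`
#'   and `count` edge attributes), `counts` (edge data.frame), `dialect`.
#' @export
build_stn <- function(log, vertices = NULL, dialect = c("log10", "log10p1")) {
  dialect <- match.arg(dialect)
  u <- pmin(log$surface_u, log$surface_v)
  v <- pmax(log$surface_u, log$surface_v)
  key <- paste(u, v, sep = "\r")
  tab <- table(key)
  edges <- if (length(tab) > 0) {
    pairs <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    data.frame(surface_u = pairs[, 1], surface_v = pairs[, 2],
               count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(surface_u = character(), surface_v = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  edges$weight <- if (dialect == "log10") log10(edges$count)
                  else log10(edges$count + 1)
  all_v <- unique(c(vertices, log$surface_u, log$surface_v))
  g <- igraph::graph_from_data_frame(
    edges[, c("surface_u", "surface_v", "weight", "count")],
    directed = FALSE,
    vertices = data.frame(name = all_v, stringsAsFactors = FALSE))
  structure(list(graph = g, counts = edges, dialect = dialect),
            class = "touch_network")
}

#' @export
print.touch_network <- function(x, ...) {
  cat("touch_network:", igraph::vcount(x$graph), "surfaces,",
      igraph::ecount(x$graph), "edges (dialect", x$dialect, ")\n")
  invisible(x)
}

#' Geodesic distance from an origin surface
#'
#' Unweighted shortest-path edge counts (breadth-first) from `origin` to
#' every surface; unreachable surfaces get +Inf.
#'
#' @param net a `touch_network`.
#' @param origin surface id, typically the carrier's hands.
#' @return Named numeric vector of distances.
#' @export
geodesic_from <- function(net, origin) {
  if (!origin %in% igraph::V(net$graph)$name)
    stop("unknown origin surface: ", origin)
  d <- igraph::distances(net$graph, v = origin, weights = NA)[1, ]
  d
}

#' Bucket geodesic distances for the proximity analysis
#'
#' Distances are grouped as 1, 2, and ">=3" (surfaces at distance 3 or more,
#' including unreachable ones). The origin itself (distance 0) gets NA.
#'
#' @param d distance vector from [geodesic_from()].
#' @return Factor with levels `"1"`, `"2"`, `">=3"`.
#' @export
bucket_distances <- function(d) {
  b <- ifelse(d == 1, "1", ifelse(d == 2, "2",
              ifelse(d >= 3, ">=3", NA_character_)))
  factor(b, levels = c("1", "2", ">=3"))
}

#' Eigenvector centrality of the touch network
#'
#' Leading-eigenvector centrality of the weighted adjacency, computed on the
#' largest connected component and normalized so the maximum score is 1;
#' vertices outside that component score 0.
#'
#' @param net a `touch_network`.
#' @param weighted use edge weights (default) or the unweighted adjacency.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
eigencentrality <- function(net, weighted = TRUE) {
  g <- net$graph
  if (igraph::ecount(g) == 0) stop("touch network has no edges")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  w <- if (weighted) igraph::E(sub)$weight else NA
  ec <- igraph::eigen_centrality(sub, weights = w)$vector
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  out[names(ec)] <- ec
  out
}

#' Bipartite intimacy projection onto hands
#'
#' Projects the surface touch network onto participant hands. For two hands
#' u and v, the intimacy is
#' W(u, v) = sum over common neighbor surfaces nbr of
#' (W(u, nbr) * W(v, nbr))^(1/4), plus the direct hand-hand edge weight
#' (0 when absent). Only non-hand surfaces are eligible common neighbors.
#'
#' @param net a `touch_network`.
#' @param hands character vector of hand surface ids.
#' @return Symmetric `participant x participant` intimacy matrix (class
#'   `intimacy_matrix`) named by hand surface id; diagonal NA.
#' @export
bipartite_project_hands <- function(net, hands) {
  g <- net$graph
  vn <- igraph::V(g)$name
  missing <- setdiff(hands, vn)
  if (length(missing) > 0)
    stop("hand surfaces absent from network: ",
         paste(missing, collapse = ", "))
  if (length(hands) < 2) stop("need at least 2 hands")
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  nbr_ids <- setdiff(vn, hands)
  nh <- length(hands)
  W <- matrix(0, nh, nh, dimnames = list(hands, hands))
  for (i in seq_len(nh - 1)) {
    for (j in (i + 1):nh) {
      u <- hands[i]; v <- hands[j]
      wu <- A[u, nbr_ids]; wv <- A[v, nbr_ids]
      common <- wu > 0 & wv > 0
      wij <- sum((wu[common] * wv[common])^(1 / 4)) + A[u, v]
      W[i, j] <- W[j, i] <- wij
    }
  }
  diag(W) <- NA
  class(W) <- c("intimacy_matrix", class(W))
  W
}

#' Best friend of a participant
#'
#' The participant v maximizing the intimacy W(u, v); ties are broken by
#' lexicographically smallest id. Returns NA with a warning when u has zero
#' intimacy with everyone.
#'
#' @param W an `intimacy_matrix` from [bipartite_project_hands()].
#' @param u row/column name of the focal participant's hand surface.
#' @return The hand surface id of the best friend, or NA.
#' @export
best_friend <- function(W, u) {
  if (!u %in% rownames(W)) stop("unknown participant: ", u)
  row <- W[u, ]
  row <- row[names(row) != u]
  if (all(row == 0, na.rm = TRUE)) {
    warning("participant ", u, " has zero intimacy with all others")
    return(NA_character_)
  }
  cand <- names(row)[which(row == max(row, na.rm = TRUE))]
  sort(cand)[1]
}
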