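# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# Bray-Curtis as sum|x-y| / sum(x+y)
oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(1, running_min)
  }
  adj
}

# average ranks computed from first principles, then the Pearson formula
oracle_avg_rank <- function(x)
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(adj)
  d
}

# leading eigenvector by power iteration on the shifted adjacency A + sI
# (the shift breaks the +/- lambda symmetry of bipartite graphs without
# changing the eigenvector)
oracle_power_iteration <- function(A, iter = 10000, tol = 1e-15) {
  s <- max(rowSums(abs(A)))
  B <- A + diag(s, nrow(A))
  v <- rep(1, nrow(A))
  for (i in seq_len(iter)) {
    w <- as.vector(B %*% v)
    w <- w / sqrt(sum(w^2))
    if (sum(abs(w - v)) < tol) break
    v <- w
  }
  v / max(v)
}

# intimacy projection by an explicit loop over every candidate neighbor
oracle_intimacy <- function(A, hands) {
  others <- setdiff(rownames(A), hands)
  W <- matrix(0, length(hands), length(hands),
              dimnames = list(hands, hands))
  for (u in hands) for (v in hands) {
    if (u == v) next
    s <- 0
    for (nbr in others) {
      if (A[u, nbr] > 0 && A[v, nbr] > 0)
        s <- s + (A[u, nbr] * A[v, nbr])^0.25
    }
    W[u, v] <- s + A[u, v]
  }
  diag(W) <- NA
  W
}

# upper beta tail by direct quadrature of the density
oracle_expected_occ <- function(P_i, N, m) {
  a <- N * P_i * m
  b <- N * (1 - P_i) * m
  lower <- stats::integrate(function(x) stats::dbeta(x, a, b), 0, 1 / N,
                            rel.tol = 1e-12, abs.tol = 1e-14)$value
  1 - lower
}

# all set partitions of 1..n (restricted growth strings), for exhaustive
# modularity maximization on tiny graphs
oracle_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, next_label) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (lab in seq_len(next_label))
      recurse(c(assign, lab), max(next_label, lab + 1))
  }
  recurse(integer(0), 1)
  out
}

oracle_max_modularity <- function(g, weights) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (p in oracle_partitions(n)) {
    q <- igraph::modularity(g, p, weights = weights)
    if (q > best) best <- q
  }
  best
}

# textbook Kruskal-Wallis H with tie correction
oracle_kruskal_h <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# tiny deterministic count table used across unit tests
make_tiny_counts <- function() {
  counts <- matrix(c(5L, 0L, 3L,
                     1L, 3L, 0L,
                     2L, 2L, 2L,
                     0L, 4L, 4L),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  meta <- data.frame(
    sample_id = paste0("s", 1:4), experiment_id = "e1",
    surface_type = c("hand", "hand", "desk", "cup"),
    owner = c("P01", "P02", "P01", "P02"),
    timepoint = "post", stringsAsFactors = FALSE)
  count_table(counts, meta)
}
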