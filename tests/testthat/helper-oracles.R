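# Brute-force oracles, independent of the package's compiled kernels.
# Everything here is plain R over adjacency matrices: repeated-neighbour BFS,
# explicit triangle loops, exhaustive partition enumeration.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (src in seq_len(n)) {
    frontier <- src
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- unique(unlist(lapply(frontier, function(u) which(adj[u, ] == 1))))
      nxt <- nxt[d[src, nxt] == Inf]
      d[src, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  vals <- d[d > 0 & is.finite(d)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    total <- total + 2 * tri / (k * (k - 1))
  }
  total / n
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    total <- total + oracle_global_eff(adj[nb, nb, drop = FALSE])
  }
  total / n
}

# all set partitions of 1..n (list of membership integer vectors)
oracle_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(adj[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

oracle_best_modularity <- function(adj) {
  best <- -Inf
  for (p in oracle_partitions(nrow(adj))) {
    q <- oracle_modularity(adj, p)
    if (q > best) best <- q
  }
  best
}

oracle_dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

# brute-force front peeling by pairwise dominance checks
oracle_fronts <- function(obj) {
  obj <- as.matrix(obj)
  alive <- rep(TRUE, nrow(obj))
  fronts <- list()
  while (any(alive)) {
    idx <- which(alive)
    f <- idx[vapply(idx, function(i) {
      !any(vapply(idx, function(j)
        j != i && oracle_dominates(obj[j, ], obj[i, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- f
    alive[f] <- FALSE
  }
  fronts
}

oracle_recovery <- function(syn, emp) {
  ut <- upper.tri(emp)
  e <- emp[ut]; s <- syn[ut]
  r1 <- sum(s == 1 & e == 1) / sum(e == 1)
  r0 <- sum(s == 0 & e == 0) / sum(e == 0)
  list(R0 = r0, R1 = r1, R = sqrt(r0 * r1))
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

random_network <- function(n, p = 0.4) binary_network(random_adjacency(n, p))

toy_geometry <- function(n, seed = 1) {
  set.seed(seed)
  region_geometry(matrix(stats::runif(n * 3, 0, 50), n, 3))
}
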