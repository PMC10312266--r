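# small named fixtures built in code

complete_net <- function(n) binary_network(1 - diag(n))

path3_net <- function() binary_network(matrix(c(0, 1, 0,
                                                1, 0, 1,
                                                0, 1, 0), 3))

triangle_net <- function() binary_network(matrix(c(0, 1, 1,
                                                   1, 0, 1,
                                                   1, 1, 0), 3))

star_net <- function(leaves = 3) {
  n <- leaves + 1
  a <- matrix(0L, n, n)
  a[1, 2:n] <- 1L; a[2:n, 1] <- 1L
  binary_network(a)
}

two_cliques_net <- function(k = 4) {
  a <- matrix(0L, 2 * k, 2 * k)
  a[1:k, 1:k] <- 1 - diag(k)
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1 - diag(k)
  binary_network(a)
}

# ring of cliques: n_cliques cliques of size k, adjacent cliques joined by
# one edge; strongly clustered yet connected
ring_of_cliques_net <- function(n_cliques = 6, k = 5) {
  n <- n_cliques * k
  a <- matrix(0L, n, n)
  for (c in seq_len(n_cliques)) {
    idx <- ((c - 1) * k + 1):(c * k)
    a[idx, idx] <- 1 - diag(k)
    nxt <- (c %% n_cliques) * k + 1
    a[c * k, nxt] <- 1L
    a[nxt, c * k] <- 1L
  }
  binary_network(a)
}
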