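#' Binary undirected network
#'
#' Constructs the basic container used throughout the package: a symmetric
#' 0/1 adjacency matrix with zero diagonal over labelled nodes. This is both
#' the genome decoded from the evolutionary algorithm and the unit of every
#' comparison and analysis.
#'
#' @param adjacency Square numeric/integer matrix of 0s and 1s; must be
#'   symmetric with zero diagonal.
#' @param node_labels Optional character vector of node names; defaults to the
#'   matrix dimnames or `V1..Vn`.
#' @return An object of class `binary_network` with elements `adjacency`
#'   (integer matrix with dimnames) and `node_labels`.
#' @export
binary_network <- function(adjacency, node_labels = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  adjacency <- matrix(as.integer(round(adjacency)), nrow(adjacency))
  if (!all(adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0L))
    stop("adjacency must have a zero diagonal")
  if (!identical(adjacency, t(adjacency)))
    stop("adjacency must be symmetric")
  n <- nrow(adjacency)
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(n))
  if (length(node_labels) != n)
    stop("node_labels length must equal the node count")
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, node_labels = as.character(node_labels)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- length(x$node_labels)
  m <- sum(x$adjacency) / 2
  cat(sprintf("binary_network: %d nodes, %d edges (density %.3f)\n",
              n, m, if (n > 1) m / (n * (n - 1) / 2) else 0))
  invisible(x)
}

n_nodes <- function(net) length(net$node_labels)

n_edges <- function(net) sum(net$adjacency) %/% 2L

#' Nodal degree vector
#'
#' @param net A [binary_network()].
#' @return Named integer vector of node degrees.
#' @export
node_degrees <- function(net) {
  d <- rowSums(net$adjacency)
  storage.mode(d) <- "integer"
  d
}

assert_network <- function(net, min_nodes = 1L) {
  if (!inherits(net, "binary_network")) stop("expected a binary_network")
  if (n_nodes(net) < min_nodes)
    stop(sprintf("network must have at least %d nodes", min_nodes))
  invisible(net)
}

# --- genome <-> adjacency -----------------------------------------------------
# Genomes are the strict upper triangle in R's column-major order; the mapping
# is fixed by upper_tri_index() and shared by the MOEA and the file writers.

upper_tri_index <- function(n) {
  idx <- which(upper.tri(matrix(0L, n, n)))
  i <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  list(i = i, j = j, length = as.integer(n * (n - 1L) / 2))
}

genome_to_adjacency <- function(genome, n) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(genome)
  adj + t(adj)
}

adjacency_to_genome <- function(adj) {
  as.integer(adj[upper.tri(adj)])
}

#' Convert a genome (upper-triangle bit vector) to a network
#'
#' @param genome 0/1 vector of length `n * (n - 1) / 2`.
#' @param n Node count.
#' @param node_labels Optional labels.
#' @return A [binary_network()].
#' @export
network_from_genome <- function(genome, n, node_labels = NULL) {
  if (length(genome) != n * (n - 1) / 2)
    stop("genome length must be n*(n-1)/2")
  binary_network(genome_to_adjacency(genome, n), node_labels)
}

# --- file formats -------------------------------------------------------------

#' Read an adjacency matrix from a delimited text file
#'
#' Accepts whitespace- or comma-delimited 0/1 matrices, with an optional
#' header row of node labels.
#'
#' @param path File path.
#' @return A [binary_network()].
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(toks))))
  tab <- utils::read.table(path, header = header, sep = sep,
                           check.names = FALSE)
  m <- as.matrix(tab)
  labels <- if (header) colnames(tab) else NULL
  binary_network(m, labels)
}

#' Write an adjacency matrix to a delimited text file
#'
#' @param net A [binary_network()].
#' @param path File path.
#' @param header Write the node labels as a header row?
#' @export
write_adjacency <- function(net, path, header = TRUE) {
  assert_network(net)
  utils::write.table(net$adjacency, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read an undirected edge list (two tab-delimited label columns)
#'
#' @param path File path.
#' @param node_labels Node universe; defaults to the sorted set of labels seen.
#' @return A [binary_network()].
#' @export
read_edge_list <- function(path, node_labels = NULL) {
  el <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(el) < 2) stop("edge list must have two columns")
  if (is.null(node_labels)) node_labels <- sort(unique(c(el[[1]], el[[2]])))
  n <- length(node_labels)
  adj <- matrix(0L, n, n, dimnames = list(node_labels, node_labels))
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    if (!(a %in% node_labels) || !(b %in% node_labels))
      stop("edge list label not in node universe")
    if (a == b) stop("self loops are not allowed")
    adj[a, b] <- 1L; adj[b, a] <- 1L
  }
  binary_network(adj, node_labels)
}

# Local RNG scope: run code under a seed without disturbing the caller's
# global RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
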