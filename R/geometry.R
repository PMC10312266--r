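#' Region geometry: centroids and pairwise distances
#'
#' Holds the region centroid coordinates (mm) and the derived pairwise
#' Euclidean distance matrix used by the wiring-cost objective and the
#' distance-binned recovery analysis.
#'
#' @param coordinates N x 3 numeric matrix of centroid positions in mm; row
#'   names (or `labels`) name the regions.
#' @param labels Optional region labels.
#' @return An object of class `region_geometry` with `coordinates`,
#'   `distance` (N x N symmetric, zero diagonal) and `labels`.
#' @export
region_geometry <- function(coordinates, labels = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must have 3 columns (x, y, z)")
  n <- nrow(coordinates)
  if (is.null(labels)) {
    labels <- rownames(coordinates)
    if (is.null(labels)) labels <- paste0("R", seq_len(n))
  }
  if (length(labels) != n) stop("labels length must match the region count")
  rownames(coordinates) <- labels
  d <- as.matrix(stats::dist(coordinates))
  dimnames(d) <- list(labels, labels)
  if (any(d[upper.tri(d)] <= 0))
    stop("region centroids must be distinct (zero pairwise distance found)")
  structure(list(coordinates = coordinates, distance = d,
                 labels = as.character(labels)),
            class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  rng <- range(x$distance[upper.tri(x$distance)])
  cat(sprintf("region_geometry: %d regions, pairwise distances %.1f-%.1f mm\n",
              nrow(x$coordinates), rng[1], rng[2]))
  invisible(x)
}

#' Read region centroid coordinates from a tab-delimited file
#'
#' Expected columns: region label, x, y, z (mm), with or without a header.
#'
#' @param path File path.
#' @return A [region_geometry()].
#' @export
read_coordinates <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(first[-1]))))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           colClasses = c("character", rep("numeric", 3)))
  coords <- as.matrix(tab[, 2:4])
  region_geometry(coords, labels = tab[[1]])
}

#' Write region centroid coordinates to a tab-delimited file
#'
#' @param geom A [region_geometry()].
#' @param path File path.
#' @export
write_coordinates <- function(geom, path) {
  tab <- data.frame(label = geom$labels, geom$coordinates)
  colnames(tab) <- c("label", "x", "y", "z")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

assert_geometry_match <- function(net, geom) {
  if (!inherits(geom, "region_geometry")) stop("expected a region_geometry")
  if (n_nodes(net) != nrow(geom$coordinates))
    stop("geometry does not match the network's node count")
  invisible(TRUE)
}
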