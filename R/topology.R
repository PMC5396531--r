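#' Convert a connectivity matrix to a connection-lengths matrix
#'
#' In a weighted structural network, stronger connections are interpreted as
#' topologically shorter: each edge length is the reciprocal of its weight.
#' Zero weights (absent connections) become `Inf`; the diagonal is 0.
#'
#' @param W Symmetric non-negative connectivity matrix.
#' @return Matrix of edge lengths with the same dimnames.
#' @export
to_length_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) stop("W must be non-negative", call. = FALSE)
  L <- 1 / W
  L[W == 0] <- Inf
  diag(L) <- 0
  L
}

#' All-pairs shortest weighted path lengths
#'
#' Dijkstra's algorithm over the edge-length matrix: the shortest weighted
#' path length between two regions is the minimum, over all paths, of the
#' summed edge lengths. Disconnected pairs remain `Inf` (a message reports
#' their count).
#'
#' @param length_matrix Edge-length matrix from [to_length_matrix()]
#'   (non-negative, `Inf` = no edge, zero diagonal).
#' @return Symmetric matrix of shortest weighted path lengths.
#' @export
shortest_path_lengths <- function(length_matrix) {
  stopifnot(is.matrix(length_matrix))
  if (any(length_matrix[is.finite(length_matrix)] < 0)) {
    stop("edge lengths must be non-negative", call. = FALSE)
  }
  A <- length_matrix
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(length_matrix)
  n_disc <- sum(!is.finite(D[upper.tri(D)]))
  if (n_disc > 0) {
    message("shortest_path_lengths: ", n_disc, " disconnected region pair(s)")
  }
  D
}

#' Shortest weighted path lengths directly from a connectivity matrix
#'
#' Convenience composition of [to_length_matrix()] and
#' [shortest_path_lengths()], typically applied to the averaged healthy
#' control network.
#'
#' @param W Symmetric non-negative connectivity matrix.
#' @return Symmetric matrix of shortest weighted path lengths.
#' @export
path_length_matrix <- function(W) {
  suppressMessages(shortest_path_lengths(to_length_matrix(W)))
}
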