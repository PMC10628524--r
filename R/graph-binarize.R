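#' Binary graph container
#'
#' Undirected simple graph stored as a 0/1 adjacency matrix with zero
#' diagonal.
#'
#' @param adjacency Square symmetric 0/1 matrix, zero diagonal.
#' @param kappa Retained-proportion threshold used to build the graph
#'   (0 when the graph was constructed directly).
#' @param source Free-text provenance note.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, kappa = 0, source = "direct") {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "double"
  n <- ncol(A)
  if (nrow(A) != n) stop("adjacency must be square", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency must be 0/1", call. = FALSE)
  if (any(A != t(A))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("diagonal must be zero", call. = FALSE)
  structure(
    list(adjacency = A, kappa = kappa, source = source),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("<binary_graph> ", ncol(x$adjacency), " nodes, ", n_edges(x),
      " edges (kappa=", x$kappa, ", ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Number of edges of a binary graph
#' @param G A [binary_graph()].
#' @return Edge count (1s above the diagonal).
#' @export
n_edges <- function(G) {
  as.integer(sum(G$adjacency[upper.tri(G$adjacency)]))
}

#' Proportional-threshold binarization
#'
#' Retains the `floor(kappa * n * (n - 1) / 2)` largest connections of a
#' weighted connectivity matrix as the edges of a binary graph, i.e. the
#' top `kappa` fraction of all possible node pairs. Flooring guarantees
#' the retained proportion never exceeds `kappa`. Ties at the threshold
#' weight are broken deterministically by weight (descending) then node
#' index pair (ascending); zero-weight pairs are never promoted to edges.
#'
#' @param W A [connectivity_matrix()] or a symmetric non-negative matrix.
#' @param kappa Proportion of connections retained, in (0, 1\]; default
#'   0.2 (the top 20%).
#' @return A [binary_graph()].
#' @export
binarize_proportional <- function(W, kappa = 0.2) {
  weights <- if (inherits(W, "connectivity_matrix")) W$weights else as.matrix(W)
  if (!(kappa > 0 && kappa <= 1)) stop("kappa must be in (0, 1]", call. = FALSE)
  n <- ncol(weights)
  if (nrow(weights) != n) stop("W must be square", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("W must be symmetric", call. = FALSE)
  }
  if (any(weights < 0)) stop("W must be non-negative", call. = FALSE)
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[upper.tri(weights)]
  if (all(w == 0)) stop("all connections are zero; nothing to rank", call. = FALSE)
  m_target <- floor(kappa * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m_target, sum(w > 0)))]
  keep <- keep[w[keep] > 0]
  A <- matrix(0, n, n)
  A[ut[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  binary_graph(A, kappa = kappa,
               source = sprintf("proportional threshold kappa=%g", kappa))
}
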