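#' Mean clustering coefficient
#'
#' For each node, the fraction of pairs of its neighbours that are
#' themselves connected: \eqn{C_i = 2 T_i / (k_i (k_i - 1))} with
#' \eqn{T_i} the number of triangles through node \eqn{i} and \eqn{k_i}
#' its degree; nodes with degree < 2 contribute \eqn{C_i = 0}. Returns
#' the mean over all nodes, a measure of functional segregation.
#'
#' @param G A [binary_graph()].
#' @return Mean clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(G) {
  stopifnot(inherits(G, "binary_graph"))
  mean(local_clustering(G$adjacency))
}

# per-node clustering coefficients from the adjacency matrix
local_clustering <- function(A) {
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) # closed 3-walks at i = 2 * triangles at i
  ci <- numeric(length(deg))
  ok <- deg >= 2
  ci[ok] <- tri[ok] / (deg[ok] * (deg[ok] - 1))
  ci
}

#' Characteristic path length over connected pairs
#'
#' Mean shortest-path length (in edges) over all ordered node pairs at
#' finite distance. Disconnected pairs are excluded from both numerator
#' and denominator, avoiding infinite path lengths in graphs with more
#' than one component; isolated nodes contribute no pairs.
#'
#' @param G A [binary_graph()] with at least one edge.
#' @return Characteristic path length L (>= 1).
#' @export
characteristic_path_length <- function(G) {
  stopifnot(inherits(G, "binary_graph"))
  D <- hop_distances(G$adjacency)
  off <- row(D) != col(D)
  fin <- is.finite(D) & off
  if (!any(fin)) stop("graph has no connected node pairs", call. = FALSE)
  mean(D[fin])
}

# all-pairs unweighted shortest-path lengths by repeated boolean matrix
# products; Inf marks disconnected pairs
hop_distances <- function(A) {
  n <- ncol(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  Bk <- A > 0
  k <- 1L
  while (k < n) {
    k <- k + 1L
    Bk <- (Bk %*% A) > 0
    upd <- Bk & !is.finite(D)
    if (!any(upd)) break
    D[upd] <- k
  }
  D
}

#' Small-worldness from normalized clustering and path length
#'
#' \deqn{SW = (C / C_{rand}) / (L / L_{rand})}
#' where the null values are ensemble means over degree-preserving
#' rewired random graphs. Random graphs score about 1; small-world graphs
#' (high clustering, short paths) score above 1.
#'
#' @param C,L Observed mean clustering coefficient and characteristic
#'   path length.
#' @param C_rand,L_rand Null-ensemble means.
#' @return The small-worldness ratio.
#' @export
small_worldness <- function(C, L, C_rand, L_rand) {
  vals <- c(C = C, L = L, C_rand = C_rand, L_rand = L_rand)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("non-positive input(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  (C / C_rand) / (L / L_rand)
}

#' Eyes-state reactivity of a network measure
#'
#' Relative difference of a measure between the eyes-open and eyes-closed
#' conditions, `(EO - EC) / (EO + EC)`; bounded by \[-1, 1\] when both
#' values are positive, positive when the measure is larger with eyes
#' open.
#'
#' @param sw_eo,sw_ec Values under the two conditions (typically
#'   small-worldness).
#' @return The reactivity value.
#' @export
reactivity <- function(sw_eo, sw_ec) {
  denom <- sw_eo + sw_ec
  if (!is.finite(denom) || denom == 0) {
    stop("sw_eo + sw_ec must be nonzero", call. = FALSE)
  }
  (sw_eo - sw_ec) / denom
}
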