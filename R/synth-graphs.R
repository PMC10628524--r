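#' Generate a benchmark graph with known metric behaviour
#'
#' Standard graph families used as fixtures for the metric layer:
#' `"complete"`, `"star"`, `"path"`, `"lattice"` (ring lattice, each node
#' tied to its `k` nearest neighbours; `k` must be even), `"random"`
#' (Erdős–Rényi with mean degree `k`), and `"smallworld"`
#' (Watts–Strogatz rewiring of a ring lattice with probability `p`; odd
#' `k` is rounded down to the nearest even neighbourhood size). Random
#' and small-world graphs are redrawn until connected.
#'
#' @param kind Graph family.
#' @param n Number of nodes (>= 3).
#' @param k Mean degree (lattice/random/smallworld).
#' @param p Rewiring probability (smallworld only; default 0.1).
#' @param seed Integer seed.
#' @return A [binary_graph()].
#' @export
generate_benchmark_graph <- function(kind = c("lattice", "random",
                                              "smallworld", "complete",
                                              "star", "path"),
                                     n, k = NULL, p = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (!is.null(k) && k >= n) stop("k must be < n", call. = FALSE)
  g <- withr_seed(seed, {
    switch(kind,
      complete = igraph::make_full_graph(n),
      star = igraph::make_star(n, mode = "undirected"),
      path = igraph::make_ring(n, circular = FALSE),
      lattice = {
        if (is.null(k)) stop("lattice requires k", call. = FALSE)
        if (k %% 2 != 0) {
          stop("ring lattice requires even k (got ", k, ")", call. = FALSE)
        }
        igraph::make_lattice(n, nei = k / 2, periodic = TRUE)
      },
      random = {
        if (is.null(k)) stop("random requires k", call. = FALSE)
        redraw_until_connected(function() {
          igraph::sample_gnp(n, k / (n - 1))
        })
      },
      smallworld = {
        if (is.null(k)) stop("smallworld requires k", call. = FALSE)
        nei <- floor(k / 2)
        if (nei < 1) stop("k too small for a small-world graph", call. = FALSE)
        redraw_until_connected(function() {
          igraph::sample_smallworld(1, n, nei, p)
        })
      }
    )
  })
  g <- igraph::simplify(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  binary_graph(A, kappa = 0, source = paste0("benchmark:", kind))
}

redraw_until_connected <- function(draw, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    g <- draw()
    if (igraph::is_connected(g)) return(g)
  }
  stop("failed to draw a connected graph in ", max_tries, " tries",
       call. = FALSE)
}
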