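#' Degree-preserving rewiring of a binary graph
#'
#' Randomizes a graph by repeated double-edge swaps: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b), rejecting any swap that would
#' create a self-loop or a duplicate edge. The degree sequence is
#' preserved exactly while all other structure is destroyed.
#'
#' Two accounting modes are provided, because "rewiring iterations" is
#' ambiguous across the literature: `"per_edge"` attempts
#' `iter_per_edge * m` swaps for a graph with `m` edges (default
#' multiplier 10, so attempted swaps are at least ten times the edge
#' count); `"total"` runs until exactly `total_swaps` swaps have been
#' accepted (capped at 100 times that many attempts).
#'
#' @param G A [binary_graph()].
#' @param iter_per_edge Swap attempts per edge in `"per_edge"` mode.
#' @param mode `"per_edge"` (default) or `"total"`.
#' @param total_swaps Accepted-swap budget in `"total"` mode (default
#'   1000).
#' @return A rewired [binary_graph()] with identical degree sequence.
#'   Uses the current RNG state; seed it for reproducibility.
#' @export
rewire_graph <- function(G, iter_per_edge = 10, mode = c("per_edge", "total"),
                         total_swaps = 1000) {
  stopifnot(inherits(G, "binary_graph"))
  mode <- match.arg(mode)
  A <- G$adjacency
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) stop("graph needs at least 2 edges to rewire", call. = FALSE)
  E <- ut # m x 2, each row an edge (i < j not required after swaps)
  if (mode == "per_edge") {
    n_att <- ceiling(iter_per_edge * m)
    e1 <- sample.int(m, n_att, replace = TRUE)
    e2 <- sample.int(m, n_att, replace = TRUE)
    flip <- stats::runif(n_att) < 0.5
    for (t in seq_len(n_att)) {
      i <- e1[t]; j <- e2[t]
      if (i == j) next
      a <- E[i, 1L]; b <- E[i, 2L]
      c_ <- E[j, 1L]; d <- E[j, 2L]
      if (flip[t]) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == c_ || a == d || b == c_ || b == d) next
      if (A[a, d] > 0 || A[c_, b] > 0) next
      A[a, b] <- 0; A[b, a] <- 0; A[c_, d] <- 0; A[d, c_] <- 0
      A[a, d] <- 1; A[d, a] <- 1; A[c_, b] <- 1; A[b, c_] <- 1
      E[i, ] <- c(a, d); E[j, ] <- c(c_, b)
    }
  } else {
    accepted <- 0L
    attempts <- 0L
    max_att <- 100L * total_swaps
    while (accepted < total_swaps && attempts < max_att) {
      attempts <- attempts + 1L
      ij <- sample.int(m, 2L, replace = TRUE)
      i <- ij[1L]; j <- ij[2L]
      if (i == j) next
      a <- E[i, 1L]; b <- E[i, 2L]
      c_ <- E[j, 1L]; d <- E[j, 2L]
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == c_ || a == d || b == c_ || b == d) next
      if (A[a, d] > 0 || A[c_, b] > 0) next
      A[a, b] <- 0; A[b, a] <- 0; A[c_, d] <- 0; A[d, c_] <- 0
      A[a, d] <- 1; A[d, a] <- 1; A[c_, b] <- 1; A[b, c_] <- 1
      E[i, ] <- c(a, d); E[j, ] <- c(c_, b)
      accepted <- accepted + 1L
    }
    if (accepted < total_swaps) {
      stop("graph too small or dense to reach ", total_swaps,
           " accepted swaps", call. = FALSE)
    }
  }
  binary_graph(A, kappa = G$kappa, source = paste0(G$source, " + rewired"))
}

#' Null-model ensemble means of C and L
#'
#' Generates `n_null` degree-preserving rewired versions of a graph and
#' returns the ensemble means of the clustering coefficient and the
#' characteristic path length, used to normalize the observed metrics in
#' the small-worldness ratio.
#'
#' @param G A [binary_graph()] with at least 2 independent edges.
#' @param n_null Ensemble size (default 1000).
#' @param iter_per_edge,mode,total_swaps Passed to [rewire_graph()].
#' @param seed Integer seed making the ensemble reproducible.
#' @return A list with `C_rand`, `L_rand` (ensemble means), `C_rand_sd`,
#'   `L_rand_sd`, `n_null`, `seed`, and `mode`.
#' @export
rewire_null_ensemble <- function(G, n_null = 1000, iter_per_edge = 10,
                                 mode = c("per_edge", "total"),
                                 total_swaps = 1000, seed = 1L) {
  stopifnot(inherits(G, "binary_graph"))
  mode <- match.arg(mode)
  if (n_edges(G) < 2L) {
    stop("graph needs at least 2 edges for a null ensemble", call. = FALSE)
  }
  Cs <- numeric(n_null)
  Ls <- numeric(n_null)
  withr_seed(seed, {
    for (b in seq_len(n_null)) {
      Gb <- rewire_graph(G, iter_per_edge = iter_per_edge, mode = mode,
                         total_swaps = total_swaps)
      Cs[b] <- clustering_coefficient(Gb)
      Ls[b] <- characteristic_path_length(Gb)
    }
  })
  list(C_rand = mean(Cs), L_rand = mean(Ls),
       C_rand_sd = stats::sd(Cs), L_rand_sd = stats::sd(Ls),
       n_null = n_null, seed = as.integer(seed), mode = mode)
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Full per-subject, per-band graph metric record
#'
#' Binarizes the eyes-open and eyes-closed connectivity matrices of one
#' subject and band, computes observed and null-normalized metrics for
#' both, and the eyes-state reactivity of small-worldness.
#'
#' @param W_eo,W_ec [connectivity_matrix()] objects for the two
#'   conditions (same subject and band).
#' @param kappa Proportional threshold (default 0.2).
#' @param n_null Null-ensemble size (default 1000).
#' @param seed Integer seed for the null ensembles.
#' @param iter_per_edge,mode Passed to [rewire_graph()].
#' @return A two-row tibble (one row per condition) with columns
#'   `subject_id`, `condition`, `band`, `C`, `L`, `C_rand`, `L_rand`,
#'   `C_norm`, `L_norm`, `sw`, `reactivity`, `kappa`, `n_null`, `seed`.
#' @export
metrics_for_subject <- function(W_eo, W_ec, kappa = 0.2, n_null = 1000,
                                seed = 1L, iter_per_edge = 10,
                                mode = "per_edge") {
  stopifnot(inherits(W_eo, "connectivity_matrix"),
            inherits(W_ec, "connectivity_matrix"))
  if (!identical(W_eo$band$band, W_ec$band$band)) {
    stop("EO and EC matrices are from different bands", call. = FALSE)
  }
  if (!identical(W_eo$subject_id, W_ec$subject_id)) {
    stop("EO and EC matrices are from different subjects", call. = FALSE)
  }
  one <- function(W, cond_seed) {
    G <- binarize_proportional(W, kappa = kappa)
    C <- clustering_coefficient(G)
    L <- characteristic_path_length(G)
    nul <- rewire_null_ensemble(G, n_null = n_null, seed = cond_seed,
                                iter_per_edge = iter_per_edge, mode = mode)
    tibble::tibble(
      subject_id = W$subject_id, condition = W$condition,
      band = W$band$band, C = C, L = L,
      C_rand = nul$C_rand, L_rand = nul$L_rand,
      C_norm = C / nul$C_rand, L_norm = L / nul$L_rand,
      sw = small_worldness(C, L, nul$C_rand, nul$L_rand),
      kappa = kappa, n_null = n_null, seed = cond_seed
    )
  }
  # null seed is shared by the two conditions (keyed on subject and band
  # only), so identical EO/EC matrices normalize identically
  null_seed <- stage_seed(seed, "null",
                          paste0(W_eo$subject_id, "_", W_eo$band$band))
  res <- dplyr::bind_rows(one(W_eo, null_seed), one(W_ec, null_seed))
  sw_eo <- res$sw[res$condition == "EO"]
  sw_ec <- res$sw[res$condition == "EC"]
  res$reactivity <- reactivity(sw_eo, sw_ec)
  res
}
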