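# independent brute-force oracles for the graph metrics

# clustering: explicit neighbour-pair enumeration per node
oracle_clustering <- function(A) {
  n <- ncol(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + (A[nb[a], nb[b]] > 0)
      }
    }
    ci[i] <- 2 * links / (k * (k - 1))
  }
  mean(ci)
}

# path length: Floyd-Warshall over all pairs, averaging finite
# off-diagonal distances only
oracle_path_length <- function(A) {
  n <- ncol(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  vals <- D[row(D) != col(D)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# direct PLI evaluation for a pair of phase vectors
oracle_pli <- function(p1, p2) {
  d <- p1 - p2
  w <- atan2(sin(d), cos(d))
  abs(mean(sign(w)))
}

# random symmetric 0/1 adjacency with given edge probability
random_adjacency <- function(n, p_edge) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1, p_edge)
  A + t(A)
}

# battery of small graphs (n <= 8) with known and awkward topologies,
# including disconnected cases
graph_battery <- function(seed = 202) {
  out <- list(
    path3 = rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
    k4 = 1 - diag(4),
    star5 = {
      A <- matrix(0, 5, 5); A[1, 2:5] <- 1; A + t(A)
    },
    two_k2 = {
      A <- matrix(0, 4, 4); A[1, 2] <- 1; A[3, 4] <- 1; A + t(A)
    },
    triangle_plus_isolate = {
      A <- matrix(0, 4, 4); A[1, 2] <- A[1, 3] <- A[2, 3] <- 1; A + t(A)
    },
    k3_k3 = {
      A <- matrix(0, 6, 6)
      A[1, 2] <- A[1, 3] <- A[2, 3] <- 1
      A[4, 5] <- A[4, 6] <- A[5, 6] <- 1
      A + t(A)
    }
  )
  withr::with_seed(seed, {
    k <- 0
    repeat {
      n <- sample(4:8, 1)
      A <- random_adjacency(n, stats::runif(1, 0.15, 0.8))
      if (sum(A) == 0) next
      k <- k + 1
      out[[paste0("rand", k)]] <- A
      if (k >= 60) break
    }
  })
  out
}

# helper to make a two-channel phase epoch with a prescribed wrapped
# phase-difference sequence (channel 2 held at 0)
phase_pair <- function(dphi, band = band_definition("alpha")) {
  phase_epoch(cbind(dphi, rep(0, length(dphi))), band = band)
}
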