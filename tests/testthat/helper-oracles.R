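# Independent oracles used across the network tests: exhaustive simple-path
# enumeration for the six centrality metrics, and an adjacency-matrix-power
# oracle for shortest-path counts.  Deliberately written without BFS or any
# code shared with the package internals.

# Random simple undirected graph as an adjacency matrix with node names.
random_adjacency <- function(n, edge_prob = 0.3) {
  A <- matrix(0L, n, n)
  upper <- which(upper.tri(A))
  A[upper] <- rbinom(length(upper), 1L, edge_prob)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
  A
}

graph_from_adjacency <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  gene_graph(rownames(A),
             data.frame(from = rownames(A)[idx[, 1L]],
                        to = rownames(A)[idx[, 2L]],
                        stringsAsFactors = FALSE))
}

# All simple paths from s to t by depth-first extension.
enumerate_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  extend <- function(path) {
    tip <- path[length(path)]
    if (tip == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(A[tip, ] > 0)) {
      if (!(nxt %in% path)) extend(c(path, nxt))
    }
  }
  extend(s)
  out
}

# Exhaustive-enumeration centralities: distances and shortest-path counts
# come from listing every simple path; betweenness and stress from counting
# interior vertices of the minimal-length paths.
oracle_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, dim = c(n, n, n))   # [s, t, v]: shortest s-t paths via v
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- enumerate_simple_paths(A, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, integer(1L)) - 1L
      d <- min(lens)
      shortest <- paths[lens == d]
      D[s, t] <- d
      sigma[s, t] <- length(shortest)
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        for (v in interior) through[s, t, v] <- through[s, t, v] + 1
      }
    }
  }
  betweenness <- numeric(n); stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      for (t in seq(s + 1L, n)) {
        if (v == s || v == t || sigma[s, t] == 0) next
        stress[v] <- stress[v] + through[s, t, v]
        betweenness[v] <- betweenness[v] + through[s, t, v] / sigma[s, t]
      }
    }
  }
  clustering <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2L) return(0)
    pairs <- utils::combn(nb, 2L)
    links <- sum(A[cbind(pairs[1L, ], pairs[2L, ])])
    2 * links / (length(nb) * (length(nb) - 1L))
  }, numeric(1L))
  closeness <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) return(0)
    length(reach) / sum(D[v, reach])
  }, numeric(1L))
  nc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0L) return(0)
    mean(deg[nb])
  }, numeric(1L))
  list(degree = unname(deg), clustering = clustering, closeness = closeness,
       betweenness = betweenness, neighborhood_connectivity = nc,
       stress = stress, distance = D, npaths = sigma)
}

# Matrix-power shortest-path oracle: the number of walks of length equal to
# the geodesic distance is the number of shortest paths.
power_path_counts <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  P <- diag(n)
  for (len in seq_len(n)) {
    P <- P %*% A
    newly <- is.infinite(D) & P > 0
    D[newly] <- len
    S[newly] <- P[newly]
  }
  list(distance = D, npaths = S)
}
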