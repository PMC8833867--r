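# Gene network construction, trimming, the six centrality metrics and the
# sum-rank hub score.

#' Construct a simple undirected gene graph
#'
#' @param nodes Character vector of node (gene) identifiers.
#' @param edges Data frame with columns `from`, `to` and optionally `weight`;
#'   may be empty.  Self-loops are rejected, duplicate/reversed edges are
#'   collapsed, and every endpoint must appear in `nodes`.
#' @return An object of class `gene_graph` with components `nodes` and
#'   `edges` (canonical form: `from < to`, one row per edge).
#' @export
gene_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_input("duplicate node identifiers")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    weight <- if ("weight" %in% colnames(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
    g <- gene_graph_from_edges(as.character(edges$from), as.character(edges$to),
                               weight, nodes = nodes)
    return(g)
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

# Shared edge canonicalization for gene_graph() and read_edge_list().
gene_graph_from_edges <- function(from, to, weight, nodes = NULL) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop_input("edge weights must be positive")
  }
  loops <- from == to
  if (any(loops)) stop_input("self-loop on node %s", from[which(loops)[1L]])
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(from = a[first], to = b[first], weight = weight[first],
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(a, b)))
  } else {
    missing <- setdiff(c(a, b), nodes)
    if (length(missing)) stop_input("edge endpoint not in node set: %s", missing[1L])
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_degrees <- function(graph) {
  deg <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    tab <- table(c(graph$edges$from, graph$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Build a co-expression graph by correlation thresholding
#'
#' An edge connects two genes when the absolute Pearson correlation of their
#' normalized expression across samples reaches `min_abs_corr`; the absolute
#' correlation is stored as the edge weight.  Genes with zero variance across
#' samples cannot be correlated and are excluded with a warning.
#'
#' @param normalized Numeric matrix of normalized expression
#'   (genes x samples), with at least 3 samples.
#' @param genes Character vector of gene identifiers to include (must be rows
#'   of `normalized`).
#' @param min_abs_corr Edge threshold, strictly between 0 and 1.
#' @return A `gene_graph` over `genes` (zero-variance genes dropped).
#' @export
build_coexpression_graph <- function(normalized, genes, min_abs_corr) {
  if (!is_real_scalar(min_abs_corr) || min_abs_corr <= 0 || min_abs_corr >= 1) {
    stop_input("min_abs_corr must lie strictly between 0 and 1")
  }
  if (ncol(normalized) < 3L) stop_input("need at least 3 samples to correlate")
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing)) stop_input("gene(s) absent from matrix: %s", missing[1L])
  mat <- normalized[genes, , drop = FALSE]
  v <- apply(mat, 1L, var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d zero-variance gene(s) from the co-expression graph",
                    sum(v == 0)), call. = FALSE)
    mat <- mat[v > 0, , drop = FALSE]
  }
  keep <- rownames(mat)
  if (length(keep) < 2L) return(gene_graph(keep))
  cc <- abs(cor(t(mat)))
  cc[lower.tri(cc, diag = TRUE)] <- 0
  hit <- which(cc >= min_abs_corr, arr.ind = TRUE)
  edges <- data.frame(from = keep[hit[, 1L]], to = keep[hit[, 2L]],
                      weight = cc[hit], stringsAsFactors = FALSE)
  gene_graph(keep, edges)
}

#' Trim weakly connected nodes from a graph
#'
#' Named nodes in `excluded_ids` are removed first; then, in a single pass,
#' every node whose degree in the post-exclusion graph is 0 or 1 is removed
#' together with its incident edges.  Because the pass is not iterated, a
#' node whose degree only drops to 1 as a *consequence* of the trim is kept
#' (set `iterate = TRUE` for the 2-core alternative).
#'
#' @param graph A `gene_graph`.
#' @param excluded_ids Character vector of node identifiers to drop before
#'   degree trimming (e.g. named non-coding RNAs).
#' @param iterate If `TRUE`, repeat the degree pass until it is stable
#'   (the 2-core plus nothing else).  Default `FALSE`: one pass.
#' @return The trimmed `gene_graph`.
#' @export
trim_graph <- function(graph, excluded_ids = character(), iterate = FALSE) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- subgraph_drop(graph, intersect(excluded_ids, graph$nodes))
  repeat {
    weak <- names(which(graph_degrees(g) <= 1L))
    g <- subgraph_drop(g, weak)
    if (!iterate || length(weak) == 0L) break
  }
  g
}

subgraph_drop <- function(graph, drop) {
  if (length(drop) == 0L) return(graph)
  nodes <- setdiff(graph$nodes, drop)
  edges <- graph$edges[graph$edges$from %in% nodes & graph$edges$to %in% nodes, ,
                       drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

#' All-pairs shortest-path distances and path counts
#'
#' Breadth-first search from every node under the unweighted interpretation
#' (every edge counts 1; weights are provenance only).  For each ordered pair
#' the geodesic distance and the number of distinct shortest paths are
#' returned; `d(u,u) = 0` and `sigma(u,u) = 1`, and unreachable pairs carry
#' infinite distance with zero paths.
#'
#' @param graph A `gene_graph`.
#' @return A list with square matrices `distance` and `npaths`, indexed by
#'   node identifier.
#' @export
all_pairs_shortest_paths <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  n <- length(graph$nodes)
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  D <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  S <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
            sigma[w] <- sigma[w] + sigma[v]
          } else if (dist[w] == dist[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  list(distance = D, npaths = S)
}

#' Compute the six node centrality metrics
#'
#' For every node: degree; local clustering coefficient
#' `2 * triangles / (deg * (deg - 1))` (0 when degree < 2); closeness
#' restricted to the node's connected component,
#' `(|C| - 1) / sum of distances` (0 for isolated nodes); betweenness as the
#' unnormalized sum over unordered pairs (endpoints excluded) of the fraction
#' of shortest paths through the node; neighborhood connectivity (mean degree
#' of neighbors, 0 if isolated); and stress, the count of shortest paths over
#' unordered pairs passing through the node.
#'
#' @param graph A simple undirected `gene_graph`.
#' @return A data frame with one row per node and columns `gene_id`,
#'   `degree`, `clustering`, `closeness`, `betweenness`,
#'   `neighborhood_connectivity`, `stress`.
#' @export
compute_centralities <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  n <- length(graph$nodes)
  if (n == 0L) {
    return(data.frame(gene_id = character(), degree = integer(),
                      clustering = numeric(), closeness = numeric(),
                      betweenness = numeric(),
                      neighborhood_connectivity = numeric(),
                      stress = numeric(), stringsAsFactors = FALSE))
  }
  A <- graph_adjacency(graph)
  deg <- rowSums(A)
  triangles <- diag(A %*% A %*% A) / 2
  clustering <- ifelse(deg >= 2, 2 * triangles / (deg * (deg - 1)), 0)
  nc <- ifelse(deg > 0, as.vector(A %*% deg) / deg, 0)

  sp <- all_pairs_shortest_paths(graph)
  D <- sp$distance; S <- sp$npaths
  reach <- is.finite(D)
  comp_size <- rowSums(reach)          # includes the node itself
  dist_sum <- rowSums(ifelse(reach, D, 0))
  closeness <- ifelse(comp_size > 1, (comp_size - 1) / dist_sum, 0)

  betweenness <- numeric(n)
  stress <- numeric(n)
  upper <- upper.tri(matrix(0, n, n))
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    through[v, ] <- FALSE
    through[, v] <- FALSE
    paths_v <- outer(S[, v], S[v, ])   # sigma_sv * sigma_vt
    use <- through & upper
    if (any(use)) {
      stress[v] <- sum(paths_v[use])
      betweenness[v] <- sum(paths_v[use] / S[use])
    }
  }
  data.frame(gene_id = graph$nodes, degree = as.integer(deg),
             clustering = clustering, closeness = closeness,
             betweenness = betweenness, neighborhood_connectivity = nc,
             stress = stress, stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate centralities into sum rank scores
#'
#' Each of the six metrics is ranked in descending order (rank 1 = largest
#' value) with fractional average ranks for ties, and the six ranks are
#' summed per node.  A low sum rank score marks a gene that is highly placed
#' across all metrics -- the operational definition of a hub.
#'
#' @param centralities Data frame from [compute_centralities()].
#' @return A data frame with the six per-metric rank columns (suffix
#'   `_rank`) and `sum_rank_score`, one row per node.
#' @export
sum_rank_scores <- function(centralities) {
  metrics <- c("degree", "clustering", "closeness", "betweenness",
               "neighborhood_connectivity", "stress")
  if (!all(c("gene_id", metrics) %in% colnames(centralities))) {
    stop_input("centrality table is missing required columns")
  }
  if (nrow(centralities) == 0L) stop_input("centrality table has no rows")
  ranks <- vapply(metrics, function(m) frac_rank_desc(centralities[[m]]),
                  numeric(nrow(centralities)))
  ranks <- matrix(ranks, nrow = nrow(centralities),
                  dimnames = list(NULL, paste0(metrics, "_rank")))
  out <- data.frame(gene_id = centralities$gene_id, ranks,
                    sum_rank_score = rowSums(ranks),
                    stringsAsFactors = FALSE)
  out
}

#' Order genes into a hub report
#'
#' Rows are ordered by ascending sum rank score; ties are broken by
#' descending fold change, then ascending gene identifier, so the report
#' order is total and deterministic.  Genes without a fold change are dropped
#' with a warning.
#'
#' @param rank_scores Data frame from [sum_rank_scores()].
#' @param fold_changes Named numeric vector of per-gene fold changes (from
#'   [fold_changes()]).
#' @return A data frame with columns `gene_id`, `sum_rank_score`,
#'   `fold_change`, sorted into hub order.
#' @export
prioritize_hubs <- function(rank_scores, fold_changes) {
  fc <- fold_changes[rank_scores$gene_id]
  missing <- is.na(fc)
  if (any(missing)) {
    warning(sprintf("dropping %d node(s) without a fold change", sum(missing)),
            call. = FALSE)
  }
  out <- data.frame(gene_id = rank_scores$gene_id[!missing],
                    sum_rank_score = rank_scores$sum_rank_score[!missing],
                    fold_change = unname(fc[!missing]),
                    stringsAsFactors = FALSE)
  out[order(out$sum_rank_score, -out$fold_change, out$gene_id,
            method = "radix"), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
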