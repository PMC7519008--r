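#' Construct a network from an edge matrix
#'
#' Builds the undirected simple-graph container used throughout the package.
#' Node ids are 0-based contiguous integers. Self-loops are rejected;
#' duplicate and reversed-duplicate edges are collapsed.
#'
#' @param edges two-column integer matrix of edges (0-based node ids), or a
#'   zero-row matrix for an empty graph.
#' @param n_nodes number of nodes; defaults to `max(edges) + 1`.
#' @param m,m0 optional Barabasi-Albert provenance metadata (attachment
#'   parameter and initial node count); `NULL` for imported networks.
#' @return an object of class `ising_network` with fields `n_nodes`, `edges`
#'   (canonicalized, sorted, 0-based), `degree`, `m`, `m0` and an internal
#'   adjacency structure.
#' @examples
#' net <- network_from_edges(rbind(c(0, 1), c(1, 2), c(2, 0)))
#' net$degree
#' @export
network_from_edges <- function(edges, n_nodes = NULL, m = NULL, m0 = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && any(edges < 0)) stop("node ids must be non-negative")
  if (is.null(n_nodes)) {
    if (nrow(edges) == 0) stop("n_nodes must be given for an edgeless network")
    n_nodes <- max(edges) + 1L
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1) stop("n_nodes must be positive")
  if (nrow(edges) > 0) {
    if (any(edges >= n_nodes)) stop("edge endpoint exceeds n_nodes - 1")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    lo <- pmin(edges[, 1], edges[, 2])
    hi <- pmax(edges[, 1], edges[, 2])
    key <- as.double(lo) * n_nodes + hi
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
    o <- order(lo, hi)
    edges <- cbind(lo[o], hi[o])
  }
  degree <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = n_nodes)
  # CSR adjacency for O(degree) neighbour lookups
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  o <- order(from, to)
  structure(list(
    n_nodes = n_nodes,
    edges = edges,
    degree = as.integer(degree),
    m = if (is.null(m)) NULL else as.integer(m),
    m0 = if (is.null(m0)) NULL else as.integer(m0),
    adj_idx = as.integer(to[o]),
    adj_ptr = c(0L, cumsum(as.integer(degree)))
  ), class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  cat(sprintf("<ising_network> %d nodes, %d edges, mean degree %.3f\n",
              x$n_nodes, nrow(x$edges), mean_degree(x)))
  if (!is.null(x$m))
    cat(sprintf("  Barabasi-Albert: m = %d, m0 = %d\n", x$m, x$m0))
  invisible(x)
}

neighbors_of <- function(network, i) {
  # i is a 0-based node id
  lo <- network$adj_ptr[i + 1L]
  hi <- network$adj_ptr[i + 2L]
  if (hi == lo) integer(0) else network$adj_idx[(lo + 1L):hi]
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Grows a network by linear growth and preferential attachment: `m0`
#' initially unconnected nodes, then one node at a time, each attaching `m`
#' distinct edges to existing nodes with probability proportional to their
#' current degree. When every candidate still has degree zero (the first
#' growth step), targets are chosen uniformly at random without replacement.
#' The result is a simple undirected graph with exactly `m * (n_nodes - m0)`
#' edges and a power-law degree tail.
#'
#' @param n_nodes network size N.
#' @param m edges attached by each new node.
#' @param m0 initial number of (unconnected) nodes; defaults to `m`.
#'   Requires `m <= m0 < n_nodes`.
#' @param seed integer seed; identical seeds give identical edge sets.
#' @return an `ising_network` with `m`/`m0` metadata.
#' @examples
#' net <- ba_network(100, m = 5, seed = 1)
#' nrow(net$edges) # 5 * 95
#' @export
ba_network <- function(n_nodes, m, m0 = m, seed = 1L) {
  n_nodes <- as.integer(n_nodes); m <- as.integer(m); m0 <- as.integer(m0)
  if (m < 1) stop("invalid parameter: m must be >= 1")
  if (m > m0) stop("invalid parameter: m must satisfy m <= m0")
  if (m0 >= n_nodes) stop("invalid parameter: m0 must satisfy m0 < n_nodes")
  n_new <- n_nodes - m0
  e_from <- integer(m * n_new)
  e_to <- integer(m * n_new)
  local_seed(seed, {
    deg <- integer(n_nodes)
    pos <- 0L
    for (v in seq.int(m0, n_nodes - 1L)) {
      w <- deg[seq_len(v)]
      targets <- if (sum(w) == 0L) {
        sample.int(v, m) - 1L
      } else {
        sample.int(v, m, prob = w) - 1L
      }
      idx <- pos + seq_len(m)
      e_from[idx] <- v
      e_to[idx] <- targets
      deg[v + 1L] <- deg[v + 1L] + m
      deg[targets + 1L] <- deg[targets + 1L] + 1L
      pos <- pos + m
    }
  })
  network_from_edges(cbind(e_from, e_to), n_nodes = n_nodes, m = m, m0 = m0)
}

#' Mean degree of a network
#'
#' Returns `(1/N) * sum(k_i)`. For a Barabasi-Albert network this is
#' approximately `2 m` (exactly `2 m (N - m0) / N`).
#'
#' @param network an `ising_network`.
#' @return the mean degree.
#' @export
mean_degree <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  mean(network$degree)
}

#' Ensemble-expected adjacency entry of a Barabasi-Albert network
#'
#' For the annealed (ensemble-averaged) adjacency of a BA network,
#' `<A_ij> = p_ij = k_i k_j / (2 m N)`, clipped to `[0, 1]`.
#'
#' @param network an `ising_network` generated with known `m`.
#' @param i,j 0-based node ids, `i != j` elementwise (vectorized).
#' @return the connection probabilities `p_ij`.
#' @export
expected_adjacency <- function(network, i, j) {
  stopifnot(inherits(network, "ising_network"))
  if (is.null(network$m))
    stop("missing metadata: network has no attachment parameter m")
  if (any(i == j)) stop("expected_adjacency requires i != j")
  if (any(i < 0 | i >= network$n_nodes | j < 0 | j >= network$n_nodes))
    stop("node id out of range")
  p <- network$degree[i + 1L] * network$degree[j + 1L] /
    (2 * network$m * network$n_nodes)
  pmin(1, pmax(0, p))
}

#' Degree statistics and power-law tail exponent
#'
#' Reports the exact mean and maximum degree, plus a maximum-likelihood
#' estimate (continuous approximation, evaluated above `k_min` with the usual
#' half-integer shift for integer data) of the degree-distribution tail
#' exponent gamma. The exponent is omitted (`NA`) for networks with fewer
#' than 100 nodes or with a degenerate degree distribution.
#'
#' @param network an `ising_network`.
#' @param k_min lower cutoff for the tail fit; defaults to the network's `m`
#'   (which excludes the non-power-law head) or to the median degree for
#'   imported networks.
#' @return a list with `mean_degree`, `max_degree`, `tail_exponent`
#'   (possibly `NA`), `k_min` and `n_tail`.
#' @export
degree_statistics <- function(network, k_min = NULL) {
  stopifnot(inherits(network, "ising_network"))
  if (is.null(k_min)) {
    k_min <- if (!is.null(network$m)) network$m else max(1L, stats::median(network$degree))
  }
  out <- list(mean_degree = mean(network$degree),
              max_degree = if (network$n_nodes > 0) max(network$degree) else NA_integer_,
              tail_exponent = NA_real_, k_min = k_min, n_tail = 0L)
  x <- network$degree[network$degree >= k_min]
  out$n_tail <- length(x)
  degenerate <- length(unique(x)) < 2L || all(x == k_min)
  if (network$n_nodes >= 100 && length(x) >= 10 && !degenerate) {
    # continuous MLE with the standard -1/2 shift for integer observations
    out$tail_exponent <- 1 + length(x) / sum(log(x / (k_min - 0.5)))
  }
  class(out) <- "degree_stats"
  out
}

#' @export
print.degree_stats <- function(x, ...) {
  cat(sprintf("mean degree %.3f, max degree %d\n", x$mean_degree, x$max_degree))
  if (is.na(x$tail_exponent)) {
    cat("tail exponent: omitted (small or degenerate degree distribution)\n")
  } else {
    cat(sprintf("tail exponent gamma = %.3f (MLE, k_min = %d, n = %d)\n",
                x$tail_exponent, as.integer(x$k_min), x$n_tail))
  }
  invisible(x)
}

#' Read / write a plain-text edge list
#'
#' The format is one edge per line, two whitespace-separated non-negative
#' integer node ids (0-based); lines starting with `#` are comments. A
#' `# nodes: N` comment, written by [write_edge_list()], preserves trailing
#' isolated nodes. Duplicate lines and reversed duplicates are collapsed;
#' self-loops are rejected.
#'
#' @param path file path.
#' @return `read_edge_list()` returns an `ising_network`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  n_meta <- NULL
  meta <- grep("^#\\s*nodes:", lines, value = TRUE)
  if (length(meta) > 0)
    n_meta <- as.integer(sub("^#\\s*nodes:\\s*", "", meta[1]))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0 && is.null(n_meta))
    stop("edge list is empty and has no '# nodes:' header")
  ij <- matrix(0L, nrow = length(idx), ncol = 2)
  for (r in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[r]]), "\\s+")[[1]]
    if (length(tok) != 2 || anyNA(suppressWarnings(as.integer(tok))))
      stop(sprintf("parse error at line %d: expected two integer columns, got '%s'",
                   idx[r], lines[idx[r]]))
    v <- as.integer(tok)
    if (v[1] == v[2])
      stop(sprintf("validation error at line %d: self-loop %d %d", idx[r], v[1], v[2]))
    ij[r, ] <- v
  }
  n_nodes <- if (!is.null(n_meta)) n_meta else max(ij) + 1L
  network_from_edges(ij, n_nodes = n_nodes)
}

#' @param network an `ising_network`.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ising_network"))
  writeLines(c(sprintf("# nodes: %d", network$n_nodes),
               sprintf("%d %d", network$edges[, 1], network$edges[, 2])),
             path)
  invisible(path)
}

#' Read / write GraphML
#'
#' Thin wrappers over igraph's GraphML support; only nodes and edges are
#' kept, attributes are ignored on read.
#'
#' @param path file path.
#' @return `read_graphml()` returns an `ising_network`; `write_graphml()`
#'   returns `path` invisibly.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = FALSE)
  network_from_edges(el - 1L, n_nodes = igraph::vcount(g))
}

#' @param network an `ising_network`.
#' @rdname read_graphml
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "ising_network"))
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (nrow(network$edges) > 0)
    g <- igraph::add_edges(g, as.vector(t(network$edges)) + 1L)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
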