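# small reference graphs built in code

triangle_net <- function() network_from_edges(rbind(c(0, 1), c(1, 2), c(0, 2)))

path_net <- function(n) network_from_edges(cbind(0:(n - 2), 1:(n - 1)))

star_net <- function(n) network_from_edges(cbind(0L, seq_len(n - 1)))

single_edge_net <- function() network_from_edges(rbind(c(0, 1)))

isolated_net <- function(n = 1) network_from_edges(matrix(integer(0), ncol = 2),
                                                   n_nodes = n)

ring_net <- function(n) network_from_edges(cbind(0:(n - 1), c(1:(n - 1), 0)))

# Erdos-Renyi-ish random simple graph, for property tests
random_net <- function(n, p = 0.3, seed = 1) {
  pairs <- t(combn(n, 2)) - 1L
  set.seed(seed)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  network_from_edges(pairs[keep, , drop = FALSE], n_nodes = n)
}

random_gene_state <- function(n, seed = 1) {
  set.seed(seed)
  spins(sample(0:1, n, replace = TRUE), "gene")
}
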