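#' Spin configurations
#'
#' A spin configuration is a length-N vector of node states in one of two
#' conventions: `"gene"` (states 0/1, inactive/active gene) or `"classical"`
#' (states -1/+1).
#'
#' @param states integer vector of states in the convention's alphabet.
#' @param convention `"gene"` or `"classical"`.
#' @return an integer vector of class `spins` with a `convention` attribute.
#' @examples
#' s <- spins(c(1, 0, 1), "gene")
#' order_parameter(s)
#' @export
spins <- function(states, convention = c("gene", "classical")) {
  convention <- match.arg(convention)
  states <- as.integer(states)
  ok <- if (convention == "gene") all(states %in% c(0L, 1L))
        else all(states %in% c(-1L, 1L))
  if (!ok) stop(sprintf("states outside the %s alphabet", convention))
  structure(states, convention = convention, class = "spins")
}

#' @export
print.spins <- function(x, ...) {
  cat(sprintf("<spins: %s convention, N = %d, M = %.4f>\n",
              attr(x, "convention"), length(x), order_parameter(x)))
  invisible(x)
}

spin_convention <- function(state) attr(state, "convention")

#' All-active / all-inactive gene configurations
#' @param n_nodes number of nodes.
#' @return a gene-convention `spins` vector.
#' @export
all_active <- function(n_nodes) spins(rep(1L, n_nodes), "gene")

#' @rdname all_active
#' @export
all_inactive <- function(n_nodes) spins(rep(0L, n_nodes), "gene")

#' Model parameters
#'
#' Coupling constant J (sign selects ferromagnetic J > 0 or
#' antiferromagnetic J < 0 behaviour), uniform external field h, and
#' temperature T with k_B = 1, so beta = 1/T. T = 0 is handled as the
#' deterministic beta -> Inf limit.
#'
#' @param J coupling constant.
#' @param h external field.
#' @param T non-negative temperature.
#' @return an object of class `ising_params` with fields `J`, `h`, `T`, `beta`.
#' @export
model_params <- function(J, h = 0, T = 1) {
  if (T < 0) stop("invalid parameter: T must be >= 0")
  structure(list(J = as.double(J), h = as.double(h), T = as.double(T),
                 beta = if (T > 0) 1 / T else Inf),
            class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat(sprintf("<ising_params> J = %g, h = %g, T = %g (beta = %g)\n",
              x$J, x$h, x$T, x$beta))
  invisible(x)
}

check_state_network <- function(state, network) {
  if (!inherits(state, "spins")) stop("state must be a spins vector")
  if (length(state) != network$n_nodes)
    stop(sprintf("dimension error: configuration length %d != n_nodes %d",
                 length(state), network$n_nodes))
}

#' Hamiltonian of the modified Ising model
#'
#' `H = -(1/2) sum_ij J A_ij s_i s_j - h sum_i s_i`, where the ordered
#' double sum with the 1/2 factor reduces to a single sum over the edges of
#' the (symmetric) adjacency. Valid in either spin convention.
#'
#' @param state a `spins` configuration.
#' @param network an `ising_network` of matching size.
#' @param params an `ising_params` object.
#' @return the energy (a scalar).
#' @examples
#' tri <- network_from_edges(rbind(c(0, 1), c(1, 2), c(0, 2)))
#' hamiltonian(all_active(3), tri, model_params(J = 1, h = 0)) # -3
#' @export
hamiltonian <- function(state, network, params) {
  check_state_network(state, network)
  s <- as.double(unclass(state))
  e <- network$edges
  coup <- if (nrow(e) > 0) sum(s[e[, 1] + 1L] * s[e[, 2] + 1L]) else 0
  -params$J * coup - params$h * sum(s)
}

#' Order parameter
#'
#' `M = (1/N) sum_i s_i`: the fraction of active genes in the gene
#' convention (in `[0, 1]`), the magnetization per spin in the classical
#' convention (in `[-1, 1]`).
#'
#' @param state a `spins` configuration.
#' @return the mean state.
#' @export
order_parameter <- function(state) {
  if (length(state) == 0) stop("empty configuration")
  mean(unclass(state))
}

#' Single-flip energy difference
#'
#' Energy change `H(state with node i flipped) - H(state)`, computed in
#' O(degree(i)) from the node's local field.
#'
#' @param state a `spins` configuration.
#' @param network an `ising_network` of matching size.
#' @param params an `ising_params` object.
#' @param i 0-based node id to flip.
#' @return the energy difference.
#' @export
delta_energy <- function(state, network, params, i) {
  check_state_network(state, network)
  i <- as.integer(i)
  if (i < 0 || i >= network$n_nodes) stop("index error: invalid node id")
  s <- unclass(state)
  cur <- s[i + 1L]
  new <- if (spin_convention(state) == "gene") 1L - cur else -cur
  nb <- neighbors_of(network, i)
  nb_sum <- if (length(nb) > 0) sum(s[nb + 1L]) else 0
  -(params$J * nb_sum + params$h) * (new - cur)
}

#' Map a gene-type configuration to classical spins
#'
#' Elementwise `s' = 2 (s - 1/2)`: 0 -> -1, 1 -> +1.
#'
#' @param state a gene-convention `spins` configuration.
#' @return the classical-convention `spins` configuration.
#' @export
map_spins <- function(state) {
  if (!inherits(state, "spins") || spin_convention(state) != "gene")
    stop("convention error: map_spins expects a gene-convention configuration")
  spins(2L * unclass(state) - 1L, "classical")
}

#' Exact mapping of the 0/1 model onto the classical Ising model
#'
#' Substituting `s = (s' + 1)/2` into the gene-type Hamiltonian gives a
#' classical +-1 Ising model with renormalized coupling `J' = J/4`, a
#' node-dependent local field `h'_i = h/2 + (J/4) k_i` (nonzero even at
#' h = 0 - the signature of the asymmetric spin alphabet), and an additive
#' constant `E0 = -(J/4) |edges| - N h / 2`, such that for every
#' configuration `H_gene(s) = H_classical(s') + E0` exactly, and hence
#' `Z_gene = exp(-beta E0) * Z_classical`. The identity is verified by
#' enumeration in [verify_mapping()].
#'
#' @param network an `ising_network`.
#' @param params gene-convention `ising_params`.
#' @return an object of class `mapped_model` with fields `J_prime`,
#'   `h_prime` (length-N vector), `E0`, and the originating `J`, `h`.
#' @export
map_to_classical <- function(network, params) {
  stopifnot(inherits(network, "ising_network"), inherits(params, "ising_params"))
  structure(list(
    J_prime = params$J / 4,
    h_prime = params$h / 2 + (params$J / 4) * network$degree,
    E0 = -(params$J / 4) * nrow(network$edges) - network$n_nodes * params$h / 2,
    J = params$J, h = params$h
  ), class = "mapped_model")
}

#' @export
print.mapped_model <- function(x, ...) {
  cat(sprintf("<mapped_model> J' = %g, E0 = %g, h' in [%g, %g]\n",
              x$J_prime, x$E0, min(x$h_prime), max(x$h_prime)))
  invisible(x)
}

#' Hamiltonian of the mapped classical model
#'
#' `H = -(1/2) sum_ij J' A_ij s'_i s'_j - sum_i h'_i s'_i` for a classical
#' configuration under the local fields of a [map_to_classical()] model.
#'
#' @param mapped a `mapped_model`.
#' @param state a classical-convention `spins` configuration.
#' @param network the `ising_network` the model was mapped on.
#' @return the energy (without the additive constant `E0`).
#' @export
mapped_hamiltonian <- function(mapped, state, network) {
  stopifnot(inherits(mapped, "mapped_model"))
  check_state_network(state, network)
  if (spin_convention(state) != "classical")
    stop("convention error: mapped_hamiltonian expects classical spins")
  s <- as.double(unclass(state))
  e <- network$edges
  coup <- if (nrow(e) > 0) sum(s[e[, 1] + 1L] * s[e[, 2] + 1L]) else 0
  -mapped$J_prime * coup - sum(mapped$h_prime * s)
}

#' Serialize spin configurations as single-column text
#'
#' One state per line; the convention is recorded in a `# convention:`
#' comment on the first line.
#'
#' @param state a `spins` configuration.
#' @param path file path.
#' @return `write_spins()` returns `path` invisibly; `read_spins()` returns
#'   the `spins` vector.
#' @export
write_spins <- function(state, path) {
  stopifnot(inherits(state, "spins"))
  writeLines(c(sprintf("# convention: %s", spin_convention(state)),
               sprintf("%d", unclass(state))), path)
  invisible(path)
}

#' @rdname write_spins
#' @export
read_spins <- function(path) {
  lines <- readLines(path)
  conv <- "gene"
  meta <- grep("^#\\s*convention:", lines, value = TRUE)
  if (length(meta) > 0) conv <- trimws(sub("^#\\s*convention:\\s*", "", meta[1]))
  vals <- as.integer(lines[!grepl("^\\s*(#|$)", lines)])
  spins(vals, conv)
}
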