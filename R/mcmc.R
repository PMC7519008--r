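#' Heat-bath conditional probability of the active state
#'
#' Probability that a node is resampled to state 1 given its local field
#' `h + J * sum_j A_ij s_j`: `1 / (1 + exp(-beta * local_field))`. This is
#' the conditional Boltzmann distribution of a single gene-type spin, and
#' its annealed average is exactly the right-hand side of the central
#' mean-field equation.
#'
#' @param local_field the local field at the node (vectorized).
#' @param beta inverse temperature, `>= 0` (may be `Inf`).
#' @return probability of state 1.
#' @examples
#' heat_bath_probability(0, beta = 5) # 0.5 by symmetry
#' @export
heat_bath_probability <- function(local_field, beta) {
  if (any(beta < 0)) stop("invalid parameter: beta must be >= 0")
  x <- beta * local_field
  p <- plogis(x)
  p[is.nan(x)] <- 0.5 # beta = Inf with zero local field
  p
}

#' Metropolis acceptance draw
#'
#' Accepts a proposed flip with probability `min(1, exp(-beta * delta_E))`;
#' moves with `delta_E <= 0` are always accepted. At `beta = Inf` (T = 0)
#' only strictly downhill moves are accepted (ties rejected).
#'
#' @param delta_E energy difference(s) of the proposed flip.
#' @param beta inverse temperature, `>= 0` (may be `Inf`).
#' @return logical vector of acceptances (consumes random numbers).
#' @export
metropolis_accept <- function(delta_E, beta) {
  if (any(beta < 0)) stop("invalid parameter: beta must be >= 0")
  if (is.infinite(beta)) return(delta_E < 0)
  delta_E <= 0 | runif(length(delta_E)) < exp(-beta * delta_E)
}

#' Monte Carlo chain schedule
#'
#' One MC step is one attempted update of one uniformly chosen node, so the
#' defaults (2e4 equilibration + 3e4 sampling steps) give an average of
#' `(2e4 + 3e4)/N` attempted flips per spin: 10 for the reference network
#' size N = 5e3. Samples are recorded at the end of every `sample_every`-th
#' sampling step.
#'
#' @param n_equilibration unrecorded steps before sampling.
#' @param n_sampling recorded steps.
#' @param sample_every thinning interval (default 1: sample every step).
#' @param kernel `"heat_bath"` (default) or `"metropolis"`.
#' @param seed integer seed for the chain's random stream.
#' @return an object of class `chain_schedule`.
#' @export
chain_schedule <- function(n_equilibration = 20000L, n_sampling = 30000L,
                           sample_every = 1L,
                           kernel = c("heat_bath", "metropolis"), seed = 1L) {
  kernel <- match.arg(kernel)
  if (n_equilibration < 0) stop("n_equilibration must be >= 0")
  if (n_sampling < 1) stop("n_sampling must be >= 1")
  if (sample_every < 1) stop("sample_every must be >= 1")
  structure(list(n_equilibration = as.integer(n_equilibration),
                 n_sampling = as.integer(n_sampling),
                 sample_every = as.integer(sample_every),
                 kernel = kernel, seed = as.integer(seed)),
            class = "chain_schedule")
}

#' Attempted flips per spin implied by a schedule
#'
#' @param schedule a `chain_schedule`.
#' @param n_nodes network size N.
#' @return `(n_equilibration + n_sampling) / n_nodes`.
#' @export
flips_per_spin <- function(schedule, n_nodes) {
  (schedule$n_equilibration + schedule$n_sampling) / n_nodes
}

#' Run a single-spin-flip Monte Carlo chain
#'
#' Simulates the gene-type (0/1) model on a network in a heat bath at
#' temperature T: `n_equilibration` unrecorded steps followed by
#' `n_sampling` recorded steps, the updated node drawn uniformly at random
#' each step. The default initial configuration is all-active for J > 0 and
#' all-inactive for J < 0 (the low-temperature equilibria of the two
#' couplings at h = 0).
#'
#' @param network an `ising_network`.
#' @param params an `ising_params` object.
#' @param schedule a `chain_schedule`; its `seed` fixes the random stream,
#'   so identical inputs reproduce identical samples bit-for-bit.
#' @param init optional gene-convention `spins` initial configuration.
#' @return an object of class `chain_result`: `samples_M` (one order
#'   parameter per recorded sample), `mean_M`, `std_error_M` (batch means,
#'   20 batches, to blunt autocorrelation), `final_config`,
#'   `acceptance_rate` (fraction of state-changing updates for heat-bath,
#'   of accepted proposals for Metropolis).
#' @examples
#' net <- ba_network(100, m = 2, seed = 1)
#' res <- run_chain(net, model_params(J = 1, h = 0, T = 0.5),
#'                  chain_schedule(2000, 3000, seed = 7))
#' res$mean_M
#' @export
run_chain <- function(network, params, schedule = chain_schedule(), init = NULL) {
  stopifnot(inherits(network, "ising_network"),
            inherits(params, "ising_params"),
            inherits(schedule, "chain_schedule"))
  if (network$n_nodes < 1) stop("empty network")
  if (is.null(init)) {
    init <- if (params$J > 0) all_active(network$n_nodes)
            else all_inactive(network$n_nodes)
  }
  if (!inherits(init, "spins") || spin_convention(init) != "gene")
    stop("init must be a gene-convention spins configuration")
  check_state_network(init, network)
  raw <- local_seed(schedule$seed,
    run_chain_cpp(network$adj_ptr, network$adj_idx, unclass(init),
                  params$J, params$h, params$beta,
                  schedule$n_equilibration, schedule$n_sampling,
                  schedule$sample_every,
                  if (schedule$kernel == "heat_bath") 0L else 1L))
  samples <- raw$samples_M
  structure(list(samples_M = samples,
                 mean_M = mean(samples),
                 std_error_M = batch_means_se(samples),
                 final_config = spins(raw$final_state, "gene"),
                 acceptance_rate = raw$acceptance_rate,
                 params = params, schedule = schedule,
                 n_nodes = network$n_nodes),
            class = "chain_result")
}

# standard error of the chain mean from 20 contiguous batch means
batch_means_se <- function(x, n_batches = 20L) {
  n <- length(x)
  if (n < 2L * n_batches) return(sd(x) / sqrt(n))
  k <- n %/% n_batches
  bm <- colMeans(matrix(x[seq_len(k * n_batches)], nrow = k))
  sd(bm) / sqrt(n_batches)
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "<chain_result> N = %d, %s kernel, J = %g, h = %g, T = %g\n  mean M = %.4f (se %.2g), acceptance %.3f, %d samples\n",
    x$n_nodes, x$schedule$kernel, x$params$J, x$params$h, x$params$T,
    x$mean_M, x$std_error_M, x$acceptance_rate, length(x$samples_M)))
  invisible(x)
}

#' Export chain samples to CSV with a JSON sidecar
#'
#' Writes columns `step, M` to `path` and the run metadata (parameters,
#' schedule, seed) to `<path>.json`.
#'
#' @param result a `chain_result`.
#' @param path CSV output path.
#' @return `path` invisibly.
#' @export
write_chain_csv <- function(result, path) {
  stopifnot(inherits(result, "chain_result"))
  df <- data.frame(step = seq_along(result$samples_M) * result$schedule$sample_every,
                   M = result$samples_M)
  write.csv(df, path, row.names = FALSE)
  meta <- list(J = result$params$J, h = result$params$h, T = result$params$T,
               n_nodes = result$n_nodes,
               schedule = unclass(result$schedule),
               mean_M = result$mean_M, std_error_M = result$std_error_M,
               acceptance_rate = result$acceptance_rate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
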