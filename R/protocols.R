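# Experiment protocols over ensembles of network realizations: temperature
# sweeps, field sweeps, hysteresis loops and critical-field scans.

new_sweep_result <- function(control_name, control_values, M, J, h = NULL,
                             T = NULL, extra = list()) {
  structure(c(list(control_name = control_name,
                   control_values = control_values,
                   M_per_realization = M,
                   M_mean = colMeans(M),
                   M_stderr = apply(M, 2, sd) / sqrt(nrow(M)),
                   n_realizations = nrow(M),
                   J = J, h = h, T = T),
              extra),
            class = "sweep_result")
}

#' Assemble a sweep result from precomputed order parameters
#'
#' Mostly useful for testing estimators such as
#' [estimate_critical_field()] on synthetic curves.
#'
#' @param control_name `"temperature"` or `"field"`.
#' @param control_values sorted vector of control-parameter values.
#' @param M matrix of order parameters, one row per realization, one column
#'   per control value (a vector is treated as a single realization).
#' @return a `sweep_result`.
#' @export
as_sweep_result <- function(control_name = c("temperature", "field"),
                            control_values, M) {
  control_name <- match.arg(control_name)
  if (is.vector(M)) M <- matrix(M, nrow = 1)
  stopifnot(ncol(M) == length(control_values))
  new_sweep_result(control_name, control_values, M, J = NA_real_)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep, %d points x %d realizations (J = %g)\n",
              x$control_name, length(x$control_values), x$n_realizations, x$J))
  df <- data.frame(x$control_values, M_mean = x$M_mean, M_stderr = x$M_stderr)
  names(df)[1] <- x$control_name
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x$control_values) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  logx <- if (x$control_name == "temperature" && all(x$control_values > 0)) "x" else ""
  graphics::plot(x$control_values, x$M_mean, type = "b", pch = 16, log = logx,
                 ylim = c(0, 1), xlab = x$control_name,
                 ylab = "order parameter M", ...)
  graphics::arrows(x$control_values, x$M_mean - x$M_stderr,
                   x$control_values, x$M_mean + x$M_stderr,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

resolve_init <- function(init, J, n_nodes) {
  if (inherits(init, "spins")) return(init)
  switch(match.arg(init, c("default", "inactive", "active")),
         default = if (J > 0) all_active(n_nodes) else all_inactive(n_nodes),
         inactive = all_inactive(n_nodes),
         active = all_active(n_nodes))
}

sweep_ensemble <- function(control_name, control_values, point_params,
                           n_nodes, m, n_realizations, schedule, master_seed,
                           init, J) {
  M <- matrix(NA_real_, nrow = n_realizations, ncol = length(control_values))
  for (r in seq_len(n_realizations)) {
    net <- ba_network(n_nodes, m, seed = derive_seed(master_seed, r, 0L))
    init_r <- resolve_init(init, J, n_nodes)
    for (ci in seq_along(control_values)) {
      sched <- schedule
      sched$seed <- derive_seed(master_seed, r, ci)
      res <- run_chain(net, point_params(control_values[ci]), sched,
                       init = init_r)
      M[r, ci] <- res$mean_M
    }
  }
  M
}

#' Temperature sweep over an ensemble of network realizations
#'
#' For each of `n_realizations` freshly generated Barabasi-Albert networks
#' and each temperature, runs an independent equilibrium chain from the
#' convention-default initial state (all-active for J > 0, all-inactive for
#' J < 0, overridable) and collects the equilibrium order parameter.
#'
#' @param T_grid ascending vector of positive temperatures.
#' @param J,h model parameters.
#' @param n_nodes,m Barabasi-Albert parameters (one fresh network per
#'   realization).
#' @param n_realizations ensemble size (default 20).
#' @param schedule a `chain_schedule` (its seed is overridden per chain).
#' @param master_seed master seed; realization r uses network seed
#'   `derive_seed(master_seed, r, 0)` and per-point chain seeds from the
#'   same stream, so the full result is reproducible bit-for-bit.
#' @param init initial state: `"default"`, `"inactive"`, `"active"`, or a
#'   `spins` vector.
#' @return a `sweep_result` with `control_name = "temperature"`.
#' @export
temperature_sweep <- function(T_grid, J = 1, h = 0, n_nodes = 5000, m = 5,
                              n_realizations = 20,
                              schedule = chain_schedule(), master_seed = 1,
                              init = "default") {
  if (is.unsorted(T_grid) || any(T_grid <= 0))
    stop("T_grid must be positive and ascending")
  M <- sweep_ensemble("temperature", T_grid,
                      function(T) model_params(J, h, T),
                      n_nodes, m, n_realizations, schedule, master_seed,
                      init, J)
  new_sweep_result("temperature", T_grid, M, J = J, h = h,
                   extra = list(n_nodes = n_nodes, m = m,
                                master_seed = master_seed))
}

#' Field sweep at fixed temperature
#'
#' Independent equilibrium chain per (realization, field value): no state is
#' carried between field values (contrast [hysteresis_loop()]), so each
#' point measures the branch pinned by the initial state.
#'
#' @param h_grid ascending vector of field values.
#' @param J coupling constant.
#' @param T fixed temperature.
#' @inheritParams temperature_sweep
#' @return a `sweep_result` with `control_name = "field"`.
#' @export
field_sweep <- function(h_grid, J = 1, T = 0.1, n_nodes = 5000, m = 5,
                        n_realizations = 20, schedule = chain_schedule(),
                        master_seed = 1, init = "default") {
  if (is.unsorted(h_grid)) stop("h_grid must be sorted ascending")
  M <- sweep_ensemble("field", h_grid,
                      function(h) model_params(J, h, T),
                      n_nodes, m, n_realizations, schedule, master_seed,
                      init, J)
  new_sweep_result("field", h_grid, M, J = J, T = T,
                   extra = list(n_nodes = n_nodes, m = m,
                                master_seed = master_seed))
}

#' Hysteresis loop under a slow field sweep
#'
#' Drives the field from `h_start` to `h_end` and back on a fixed network,
#' carrying the final spin configuration of each chain into the next field
#' value (the only protocol with state memory). The enclosed area
#' `|contour integral of M dh|` (trapezoid rule along both branches) is the
#' hysteresis signature of the first-order transition; it vanishes at high
#' temperature.
#'
#' @param network a fixed `ising_network`.
#' @param J coupling constant.
#' @param T temperature.
#' @param h_start,h_end endpoints of the field ramp (forward branch runs
#'   h_start -> h_end, backward branch retraces the reversed grid).
#' @param n_points number of field values per branch, `>= 2`.
#' @param schedule per-point `chain_schedule` (seed overridden per point).
#' @param seed master seed for the loop.
#' @param init initial configuration at `h_start`; default all-active if
#'   `h_start > 0`, else all-inactive (a stable start far from the
#'   transition).
#' @return an object of class `hysteresis_loop`: `h_forward`, `M_forward`,
#'   `h_backward`, `M_backward`, `loop_area`.
#' @export
hysteresis_loop <- function(network, J, T, h_start = 10, h_end = -10,
                            n_points = 81, schedule = chain_schedule(),
                            seed = 1, init = NULL) {
  stopifnot(inherits(network, "ising_network"))
  if (n_points < 2) stop("n_points must be >= 2")
  h_f <- seq(h_start, h_end, length.out = n_points)
  h_b <- rev(h_f)
  if (is.null(init))
    init <- if (h_start > 0) all_active(network$n_nodes)
            else all_inactive(network$n_nodes)
  state <- init
  run_branch <- function(h_values, stream) {
    M <- numeric(length(h_values))
    for (ci in seq_along(h_values)) {
      sched <- schedule
      sched$seed <- derive_seed(seed, stream, ci)
      res <- run_chain(network, model_params(J, h_values[ci], T), sched,
                       init = state)
      M[ci] <- res$mean_M
      state <<- res$final_config
    }
    M
  }
  M_f <- run_branch(h_f, 1L)
  M_b <- run_branch(h_b, 2L)
  area <- abs(trapz_(h_f, M_f) + trapz_(h_b, M_b))
  structure(list(h_forward = h_f, M_forward = M_f,
                 h_backward = h_b, M_backward = M_b,
                 loop_area = area, J = J, T = T,
                 n_nodes = network$n_nodes),
            class = "hysteresis_loop")
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("<hysteresis_loop> J = %g, T = %g, h from %g to %g (%d points): loop area %.4g\n",
              x$J, x$T, x$h_forward[1], x$h_forward[length(x$h_forward)],
              length(x$h_forward), x$loop_area))
  invisible(x)
}

#' @export
plot.hysteresis_loop <- function(x, ...) {
  graphics::plot(x$h_forward, x$M_forward, type = "l", col = "grey50",
                 ylim = c(0, 1), xlab = "external field h",
                 ylab = "order parameter M", ...)
  graphics::lines(x$h_backward, x$M_backward, col = "black")
  graphics::legend("topleft", legend = c("forward", "backward"),
                   col = c("grey50", "black"), lty = 1, bty = "n")
  invisible(x)
}

# h at which a branch last crosses 0.5 (for branch-separation diagnostics)
branch_crossing <- function(h, M) {
  below <- M < 0.5
  idx <- which(below[-1] != below[-length(below)])
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (M[i + 1] == M[i]) return(h[i])
  h[i] + (0.5 - M[i]) / (M[i + 1] - M[i]) * (h[i + 1] - h[i])
}

#' Estimate the critical field from a field sweep
#'
#' Returns the field at which the ensemble-mean order parameter first
#' crosses 0.5 from below as h ascends, linearly interpolated between the
#' bracketing grid points (an exact grid hit returns that grid value, ties
#' broken toward the lower h).
#'
#' @param sweep a `sweep_result` with `control_name = "field"`.
#' @return the estimated critical field.
#' @examples
#' sw <- as_sweep_result("field", c(-1, 0, 1, 2), c(0, 0, 1, 1))
#' estimate_critical_field(sw) # 0.5
#' @export
estimate_critical_field <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$control_name != "field")
    stop("estimate_critical_field requires a field sweep")
  h <- sweep$control_values
  M <- sweep$M_mean
  above <- M >= 0.5
  i <- which(above & c(FALSE, !above[-length(above)]))
  if (length(i) == 0)
    stop("no transition: M_mean does not cross 0.5 from below")
  i <- i[1]
  if (M[i] == 0.5) return(h[i])
  h[i - 1] + (0.5 - M[i - 1]) / (M[i] - M[i - 1]) * (h[i] - h[i - 1])
}

#' Monte Carlo critical-field scan against the mean-field law
#'
#' For each value of the varied parameter (coupling J, attachment parameter
#' m, or network size N), measures the activation transition: field sweeps
#' with antiferromagnetic coupling of magnitude J started from the
#' all-inactive state and ascending h (the estimator must pin one branch of
#' a history-dependent system, and this is the activation branch), then the
#' first 0.5-crossing of the ensemble-mean curve. Each row pairs the Monte
#' Carlo estimate with the analytic mean-field line `h_c = J * m`.
#'
#' @param vary `"J"`, `"m"` or `"N"`.
#' @param values ascending vector of values for the varied parameter.
#' @param J,m,n_nodes fixed values of the non-varied parameters.
#' @param T temperature of the sweeps.
#' @param h_grid field grid; default `seq(-1, 1.5 * J * m + 1, length.out = 41)`
#'   per scan value.
#' @param n_realizations ensemble size per sweep.
#' @param schedule a `chain_schedule`.
#' @param master_seed master seed.
#' @return a data.frame of class `hc_scan` with columns `value`, `h_c_mc`,
#'   `h_c_analytic`.
#' @export
critical_field_scan <- function(vary = c("J", "m", "N"), values, J = 1, m = 5,
                                n_nodes = 1000, T = 0.1, h_grid = NULL,
                                n_realizations = 20,
                                schedule = chain_schedule(), master_seed = 1) {
  vary <- match.arg(vary)
  if (is.unsorted(values)) stop("values must be ascending")
  rows <- lapply(seq_along(values), function(vi) {
    v <- values[vi]
    Jv <- if (vary == "J") v else J
    mv <- if (vary == "m") as.integer(v) else m
    Nv <- if (vary == "N") as.integer(v) else n_nodes
    grid <- if (is.null(h_grid)) seq(-1, 1.5 * Jv * mv + 1, length.out = 41)
            else h_grid
    sw <- field_sweep(grid, J = -abs(Jv), T = T, n_nodes = Nv, m = mv,
                      n_realizations = n_realizations, schedule = schedule,
                      master_seed = derive_seed(master_seed, vi, 0L),
                      init = "inactive")
    data.frame(value = v, h_c_mc = estimate_critical_field(sw),
               h_c_analytic = critical_field(abs(Jv), mv))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hc_scan", "data.frame")
  attr(out, "vary") <- vary
  out
}

#' Export sweep results to tidy CSV
#'
#' Writes a summary CSV (control value, `M_mean`, `M_stderr`) to
#' `path_summary` and, optionally, a long-format per-realization CSV
#' (realization, control value, M) to `path_points`.
#'
#' @param sweep a `sweep_result`.
#' @param path_summary summary CSV path.
#' @param path_points optional per-realization CSV path.
#' @return `path_summary` invisibly.
#' @export
write_sweep_csv <- function(sweep, path_summary, path_points = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  summary_df <- data.frame(sweep$control_values, M_mean = sweep$M_mean,
                           M_stderr = sweep$M_stderr)
  names(summary_df)[1] <- sweep$control_name
  write.csv(summary_df, path_summary, row.names = FALSE)
  if (!is.null(path_points)) {
    pts <- expand.grid(realization = seq_len(sweep$n_realizations),
                       control = sweep$control_values)
    names(pts)[2] <- sweep$control_name
    pts$M <- as.vector(sweep$M_per_realization)
    write.csv(pts, path_points, row.names = FALSE)
  }
  invisible(path_summary)
}

#' Export a hysteresis loop to CSV
#'
#' Long format: columns `branch` (`forward`/`backward`), `h`, `M`.
#'
#' @param loop a `hysteresis_loop`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_hysteresis_csv <- function(loop, path) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  df <- data.frame(
    branch = rep(c("forward", "backward"),
                 c(length(loop$h_forward), length(loop$h_backward))),
    h = c(loop$h_forward, loop$h_backward),
    M = c(loop$M_forward, loop$M_backward))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
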