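#' Solve the central mean-field equation by damped fixed-point iteration
#'
#' The mean-field self-consistency equation of the gene-type model on a
#' given degree sequence is
#' `M = f(M) = (1/N) sum_i 1 / (1 + exp(-beta (h + J M k_i)))`;
#' antiferromagnetic coupling is obtained by passing `J < 0` (which flips
#' the sign in the exponent). The solver iterates
#' `M <- (1 - lambda) M + lambda f(M)` from `start_M` until
#' `|M - f(M)| < tol`. Because `f` maps `[0, 1]` into `(0, 1)`, every
#' iterate stays in `[0, 1]`. Plain iteration can 2-cycle when `f` is steep
#' (strong antiferromagnetic coupling at low T), so the damping factor is
#' halved whenever the residual stalls, which restores convergence of the
#' monotone map.
#'
#' For ferromagnetic coupling at low temperature the equation has up to two
#' stable solutions; `start_M` selects the branch (see [mf_branch_scan()]).
#'
#' @param degree_sequence integer vector of node degrees `k_i` (use the
#'   degrees of an actual generated network).
#' @param J coupling constant (sign selects ferro/antiferromagnetic).
#' @param h external field.
#' @param T temperature, `> 0` (may be `Inf`, where `f` is identically 1/2).
#' @param start_M initial iterate in `[0, 1]`.
#' @param damping initial damping factor lambda.
#' @param tol convergence tolerance on `|M - f(M)|`.
#' @param max_iter iteration cap.
#' @return an object of class `mf_solution`: `M`, `start_M`, `n_iterations`,
#'   `converged`, `residual`.
#' @examples
#' net <- ba_network(1000, m = 5, seed = 1)
#' mf_fixed_point(net$degree, J = 1, h = 0, T = 0.001, start_M = 0.9)$M # -> 1
#' @export
mf_fixed_point <- function(degree_sequence, J, h, T, start_M = 0.5,
                           damping = 0.5, tol = 1e-10, max_iter = 1e5) {
  if (length(degree_sequence) == 0) stop("empty degree sequence")
  if (T <= 0)
    stop("invalid parameter: T must be > 0 (use the analytic limits for T = 0)")
  if (start_M < 0 || start_M > 1) stop("start_M must be in [0, 1]")
  beta <- 1 / T
  k <- as.double(degree_sequence)
  f <- function(M) mean(plogis(beta * (h + J * M * k)))
  M <- start_M
  lam <- damping
  best <- Inf
  stall <- 0L
  converged <- FALSE
  res <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fM <- f(M)
    res <- abs(M - fM)
    if (res < tol) { converged <- TRUE; M <- fM; res <- abs(M - f(M)); break }
    if (res < best * (1 - 1e-3)) {
      best <- res; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 50L) { lam <- max(lam / 2, 1e-4); stall <- 0L; best <- res }
    }
    M <- (1 - lam) * M + lam * fM
  }
  structure(list(M = M, start_M = start_M, n_iterations = it,
                 converged = converged, residual = res,
                 J = J, h = h, T = T),
            class = "mf_solution")
}

#' @export
print.mf_solution <- function(x, ...) {
  cat(sprintf("<mf_solution> M = %.8g (start %.3g, J = %g, h = %g, T = %g): %s after %d iterations, residual %.3g\n",
              x$M, x$start_M, x$J, x$h, x$T,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$residual))
  invisible(x)
}

#' High-temperature closed form for the mean-field order parameter
#'
#' For `T >> 1`, Taylor expansion of the central mean-field equation gives
#' `M ~ (1/2) (2 + beta h) / (2 -+ beta J m)`, with the minus sign in the
#' denominator for ferromagnetic and the plus sign for antiferromagnetic
#' coupling (the sign that makes M increase with J in the ferromagnetic
#' case, consistent with expanding the logistic around 1/2).
#'
#' @param J coupling magnitude.
#' @param m Barabasi-Albert attachment parameter (mean degree / 2).
#' @param h external field.
#' @param T temperature, `> 0`.
#' @param coupling `"ferromagnetic"` or `"antiferromagnetic"`.
#' @return the approximate order parameter.
#' @export
mf_high_T_approx <- function(J, m, h = 0, T,
                             coupling = c("ferromagnetic", "antiferromagnetic")) {
  coupling <- match.arg(coupling)
  if (T <= 0) stop("invalid parameter: T must be > 0")
  beta <- 1 / T
  denom <- if (coupling == "ferromagnetic") 2 - beta * J * m else 2 + beta * J * m
  if (abs(denom) < 1e-12)
    stop("singular approximation: denominator 2 -+ beta*J*m vanishes")
  0.5 * (2 + beta * h) / denom
}

#' Mean-field critical field
#'
#' The first-order activation transition of the mean-field model sits at
#' `h_c = J * m`: setting the mapped model's ensemble-averaged local field
#' to zero, `h_c/2 - (J/4) k_bar = 0` with `k_bar = 2 m`, gives `h_c = J m`
#' - linear in both the coupling and the attachment parameter.
#'
#' @param J coupling constant.
#' @param m Barabasi-Albert attachment parameter, `>= 1`.
#' @return `J * m` (vectorized).
#' @examples
#' critical_field(J = 1, m = 5) # 5
#' @export
critical_field <- function(J, m) {
  if (any(m < 1)) stop("invalid parameter: m must be >= 1")
  J * m
}

#' Two-branch mean-field scan over the external field
#'
#' Solves the mean-field equation at every field value from both canonical
#' starts, `start_M = 0` (low branch) and `start_M = 1` (high branch). A
#' field value is flagged bistable when the branches differ by more than
#' 0.5; the bistable window and the branch discontinuities are the
#' mean-field signature of the first-order transition and of hysteresis.
#'
#' @param degree_sequence node degrees `k_i`.
#' @param J coupling constant.
#' @param T temperature, `> 0`.
#' @param h_grid ascending vector of field values.
#' @return a data.frame of class `mf_branch_scan` with columns `h`, `M_low`,
#'   `M_high`, `bistable`, and attributes `jump_low` / `jump_high`: the h
#'   (midpoint of the bracketing grid interval) at which each branch jumps
#'   by more than 0.5 between adjacent grid points (`NA` if no jump).
#' @export
mf_branch_scan <- function(degree_sequence, J, T, h_grid) {
  if (is.unsorted(h_grid)) stop("h_grid must be sorted ascending")
  M_low <- vapply(h_grid, function(h)
    mf_fixed_point(degree_sequence, J, h, T, start_M = 0)$M, numeric(1))
  M_high <- vapply(h_grid, function(h)
    mf_fixed_point(degree_sequence, J, h, T, start_M = 1)$M, numeric(1))
  out <- data.frame(h = h_grid, M_low = M_low, M_high = M_high,
                    bistable = abs(M_high - M_low) > 0.5)
  jump_of <- function(M) {
    if (length(M) < 2) return(NA_real_)
    d <- abs(diff(M))
    i <- which.max(d)
    if (d[i] > 0.5) (h_grid[i] + h_grid[i + 1]) / 2 else NA_real_
  }
  attr(out, "jump_low") <- jump_of(M_low)
  attr(out, "jump_high") <- jump_of(M_high)
  class(out) <- c("mf_branch_scan", "data.frame")
  out
}

#' Export a mean-field branch scan to CSV
#'
#' Columns `h, M_low, M_high, bistable`.
#'
#' @param scan an `mf_branch_scan`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_branch_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "mf_branch_scan"))
  write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.mf_branch_scan <- function(x, ...) {
  graphics::plot(x$h, x$M_high, type = "l", lty = 1, ylim = c(0, 1),
                 xlab = "external field h", ylab = "order parameter M", ...)
  graphics::lines(x$h, x$M_low, lty = 2)
  graphics::legend("topleft", legend = c("high branch (start M = 1)",
                                         "low branch (start M = 0)"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
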