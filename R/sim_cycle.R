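#' Simulate chemomechanical-cycle dwell times (Gillespie realization)
#'
#' Realizes the serial cycle of a \code{\link{rate_scheme}} as a
#' continuous-time Markov chain: the motor visits each cycle state in order
#' and dwells an exponential time with that state's total exit rate. The mean
#' total cycle period converges to \code{1/analytic_kcat(scheme)}.
#'
#' @param scheme A \code{rate_scheme}, or a named numeric vector of state exit
#'   rates (1/s) for an arbitrary serial loop.
#' @param n_cycles Number of complete cycles to realize (>= 1).
#' @param seed Integer seed; the realization is bit-reproducible.
#' @param atp,adp Nucleotide concentrations (uM) passed to
#'   \code{\link{cycle_rates}} when \code{scheme} is a \code{rate_scheme}.
#' @return A data.frame with columns \code{cycle}, \code{state},
#'   \code{dwell_s}, of \code{n_cycles * n_states} rows, plus attribute
#'   \code{t_cycle_analytic}.
#' @export
simulate_cycle_dwells <- function(scheme, n_cycles, seed, atp = 4000, adp = 0) {
  stopifnot(n_cycles >= 1)
  rates <- if (inherits(scheme, "rate_scheme")) {
    cycle_rates(scheme, atp = atp, adp = adp)
  } else {
    stopifnot(is.numeric(scheme), length(scheme) >= 1, all(is.finite(scheme)))
    if (is.null(names(scheme))) names(scheme) <- paste0("S", seq_along(scheme))
    scheme
  }
  if (any(rates <= 0))
    stop("absorbing state: state '", names(rates)[which(rates <= 0)[1]],
         "' has zero total exit rate")
  set.seed(as.integer(seed))
  ns <- length(rates)
  # one rexp draw per (cycle, state) visit, state-major order within cycle
  dwell <- stats::rexp(n_cycles * ns, rate = rep(rates, times = n_cycles))
  out <- data.frame(
    cycle = rep(seq_len(n_cycles), each = ns),
    state = rep(names(rates), times = n_cycles),
    dwell_s = dwell,
    stringsAsFactors = FALSE
  )
  attr(out, "t_cycle_analytic") <- sum(1 / rates)
  out
}

#' Sample a discrete-time Markov state trajectory
#'
#' Fixture generator for Markov state model estimation: samples a trajectory
#' from a known row-stochastic transition matrix so that empirical transition
#' frequencies converge to the matrix.
#'
#' @param T_mat Row-stochastic square matrix (rows sum to 1 within 1e-10).
#' @param n_steps Trajectory length (number of states emitted).
#' @param seed Integer seed.
#' @param init Initial state (1-based); default sampled uniformly.
#' @return Integer vector of 1-based state labels, class
#'   \code{state_trajectory}, with the true matrix in attribute \code{T_true}.
#' @export
make_state_trajectory <- function(T_mat, n_steps, seed, init = NULL) {
  T_mat <- as.matrix(T_mat)
  n <- nrow(T_mat)
  stopifnot(ncol(T_mat) == n, n >= 1, n_steps >= 1)
  if (any(abs(rowSums(T_mat) - 1) > 1e-10))
    stop("rows of the transition matrix must sum to 1 within 1e-10")
  if (any(T_mat < 0)) stop("transition probabilities must be nonnegative")
  set.seed(as.integer(seed))
  s <- integer(n_steps)
  s[1] <- if (is.null(init)) sample.int(n, 1) else as.integer(init)
  if (n_steps > 1) {
    # inverse-CDF sampling with precomputed row CDFs
    cdf <- t(apply(T_mat, 1, cumsum))
    u <- stats::runif(n_steps - 1)
    for (t in 2:n_steps) {
      s[t] <- findInterval(u[t - 1], cdf[s[t - 1], ], left.open = TRUE) + 1L
    }
  }
  structure(s, class = "state_trajectory", T_true = T_mat, n_states = n)
}
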