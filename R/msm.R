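#' Count state-to-state transitions at a lag
#'
#' Sliding-window counts: for each trajectory and each time t,
#' \code{C[s_t, s_{t+lag}]} is incremented. Trajectories are never
#' concatenated, so no spurious cross-trajectory pairs are counted.
#'
#' @param trajs A \code{state_trajectory}, an integer vector (1-based state
#'   labels), or a list of either.
#' @param lag Lag in strides (>= 1).
#' @param n_states Number of states; default the maximum label observed.
#' @return Integer count matrix (n_states x n_states).
#' @export
count_transitions <- function(trajs, lag, n_states = NULL) {
  if (!is.list(trajs)) trajs <- list(trajs)
  stopifnot(lag >= 1)
  labs <- unlist(lapply(trajs, as.integer))
  if (is.null(n_states)) n_states <- max(labs)
  if (any(labs < 1 | labs > n_states))
    stop("state labels must lie in 1..n_states")
  C <- matrix(0L, n_states, n_states)
  for (s in trajs) {
    s <- as.integer(s)
    L <- length(s)
    if (L < lag + 1) stop("trajectory shorter than lag + 1")
    from <- s[seq_len(L - lag)]
    to <- s[seq_len(L - lag) + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + as.matrix(tab)
  }
  unname(C)
}

#' Estimate a transition matrix with a 1/n pseudocount prior
#'
#' Adds a pseudocount of \code{1/n} (n = number of states) to every element
#' of the count matrix and row-normalizes. The pseudocount guarantees strict
#' positivity and hence ergodicity; no detailed-balance constraint is
#' imposed. The equilibrium distribution is the leading left eigenvector of
#' the transition matrix, normalized to sum to 1.
#'
#' @param counts Square nonnegative count matrix.
#' @param lag Lag (strides) the counts were taken at, stored in the model.
#' @param stride_time Physical time per stride (arbitrary units; default 1).
#' @return A list of class \code{transition_model}: \code{counts}, \code{T}
#'   (row-stochastic), \code{lag}, \code{stride_time}, \code{pi}
#'   (equilibrium), \code{eigenvalues} (by decreasing magnitude),
#'   \code{timescales} (implied timescales, in time units; Inf where the
#'   eigenvalue magnitude reaches 1), \code{reversible_spectrum} (FALSE when
#'   complex eigenvalues were reported by magnitude).
#' @export
estimate_transition_matrix <- function(counts, lag = 1, stride_time = 1) {
  C <- as.matrix(counts)
  n <- nrow(C)
  if (n == 0) stop("zero-state model")
  stopifnot(ncol(C) == n, all(C >= 0))
  T_mat <- C + 1 / n
  T_mat <- T_mat / rowSums(T_mat)

  ev <- eigen(t(T_mat))
  ord <- order(Mod(ev$values), -seq_along(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]
  pi_vec <- Re(ev$vectors[, ord[1]])
  pi_vec <- pi_vec / sum(pi_vec)

  mags <- Mod(vals)
  complex_present <- any(abs(Im(vals)) > 1e-12)
  if (complex_present)
    warning("complex eigenvalues reported by magnitude (non-reversible chain)")
  ts <- ifelse(mags[-1] >= 1 - 1e-12, Inf,
               -lag * stride_time / log(mags[-1]))
  structure(list(counts = C, T = T_mat, lag = lag, stride_time = stride_time,
                 pi = pi_vec, eigenvalues = vals,
                 timescales = sort(ts, decreasing = TRUE),
                 reversible_spectrum = !complex_present),
            class = "transition_model")
}

#' Implied timescales across lags
#'
#' For each lag, estimates the transition matrix (with the 1/n pseudocount)
#' and reports \code{t_i(tau) = -tau / ln |lambda_i(tau)|} for the non-unit
#' eigenvalues. Lag-independence (a plateau) of the curves indicates the
#' chain is Markovian at that resolution.
#'
#' @param trajs As in \code{\link{count_transitions}}.
#' @param lags Integer vector of at least 2 lags.
#' @param n_states Number of states; default the maximum observed label.
#' @param n_timescales How many timescales to report (default n_states - 1).
#' @param stride_time Physical time per stride.
#' @return A data.frame with columns \code{lag}, \code{index},
#'   \code{timescale}; attribute \code{plateau_rel_change} gives, per
#'   timescale index, the relative change between the last two lags.
#' @export
implied_timescales <- function(trajs, lags, n_states = NULL,
                               n_timescales = NULL, stride_time = 1) {
  if (length(lags) < 2) stop("need at least 2 lags")
  if (!is.list(trajs)) trajs <- list(trajs)
  if (is.null(n_states)) n_states <- max(unlist(lapply(trajs, max)))
  if (is.null(n_timescales)) n_timescales <- n_states - 1
  rows <- lapply(sort(lags), function(tau) {
    mod <- estimate_transition_matrix(
      count_transitions(trajs, tau, n_states), lag = tau,
      stride_time = stride_time)
    ts <- mod$timescales[seq_len(min(n_timescales, length(mod$timescales)))]
    data.frame(lag = tau, index = seq_along(ts), timescale = ts)
  })
  out <- do.call(rbind, rows)
  last2 <- sort(lags)[length(lags) - 1:0]
  rel <- vapply(unique(out$index), function(i) {
    v <- out$timescale[out$index == i & out$lag %in% last2]
    if (any(!is.finite(v))) return(NA_real_)
    abs(diff(v)) / mean(v)
  }, 0)
  attr(out, "plateau_rel_change") <- rel
  out
}
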