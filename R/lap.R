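#' Solve the linear assignment problem
#'
#' Minimum-cost assignment of rows to columns by the shortest-augmenting-path
#' (Jonker-Volgenant style) algorithm with dual potentials, O(n^2 m).
#' Infinite entries mark forbidden assignments.
#'
#' @param cost Numeric cost matrix with \code{nrow(cost) <= ncol(cost)}.
#' @return A list: \code{assignment} (column assigned to each row) and
#'   \code{cost} (total assigned cost).
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(list(assignment = integer(0), cost = 0))
  stopifnot(n <= m)
  big <- max(cost[is.finite(cost)], 1) * n * 1e6
  a <- cost
  a[!is.finite(a)] <- big

  # column index 1 is a virtual column; real columns are 2..m+1
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)            # row assigned to each column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1
    minv <- rep(Inf, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)
      cur <- a[i0, free - 1] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0) assignment[p[j]] <- j - 1
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
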